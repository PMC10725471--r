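toy_ca <- function() build_toy_fold(ca_only = TRUE)

rand_rigid <- function(X) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  sweep(X %*% t(R), 2, runif(3, -10, 10), `+`)
}

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  P <- matrix(rnorm(15), 5, 3)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(Rz), 2, c(1, 2, 3), `+`)
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(fit$transform(Q), P, tolerance = 1e-9)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches the quaternion-method oracle", {
  set.seed(2)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    P <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 3), n, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, quat_superpose(P, Q)$rmsd,
                 tolerance = 1e-8)
  }
})

test_that("collinear point sets are flagged degenerate", {
  P <- cbind(0:3, 0, 0)
  Q <- sweep(P, 2, c(5, 5, 5), `+`)
  fit <- kabsch_superpose(P, Q)
  expect_true(fit$degenerate)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
})

test_that("RMSD series is zero for identical frames and matches per-frame oracle", {
  base <- toy_ca()
  xyz <- as.matrix(base$atoms[, c("x", "y", "z")])
  coords <- array(rep(xyz, 4), c(nrow(xyz), 3, 4))
  meta <- base$atoms[, c("atom_name", "residue_name", "residue_number",
                         "chain_id", "element")]
  ens <- as_ensemble(coords, atoms = meta)
  expect_equal(rmsd_series(ens), rep(0, 4), tolerance = 1e-9)

  sim <- sim_ensemble(base, n_frames = 5, base_amplitude = 0.2, seed = 9)
  rs <- rmsd_series(sim$ensemble)
  oracle <- vapply(1:5, function(f) {
    quat_superpose(sim$ensemble$coords[, , 1],
                   sim$ensemble$coords[, , f])$rmsd
  }, numeric(1))
  expect_equal(rs, oracle, tolerance = 1e-8)

  one <- as_ensemble(coords[, , 1, drop = FALSE], atoms = meta)
  expect_equal(rmsd_series(one), 0)
})

test_that("RMSF recovers planted fluctuation amplitudes", {
  base <- toy_ca()
  # identical frames -> zero RMSF
  sim0 <- sim_ensemble(base, n_frames = 3, base_amplitude = 0, seed = 1)
  expect_equal(unname(rmsf_per_residue(sim0$ensemble)),
               rep(0, 60), tolerance = 1e-12)

  # two frames, one atom displaced by d -> RMSF d/2 for that atom
  # (reference frame pinned on the unmoved atoms)
  xyz <- as.matrix(base$atoms[, c("x", "y", "z")])
  co <- array(rep(xyz, 2), c(nrow(xyz), 3, 2))
  co[5, 1, 2] <- co[5, 1, 2] + 0.8
  meta <- base$atoms[, c("atom_name", "residue_name", "residue_number",
                         "chain_id", "element")]
  ens2 <- as_ensemble(co, atoms = meta)
  r2 <- rmsf_per_residue(ens2, sel = NULL, fit_sel = setdiff(1:60, 5))
  expect_equal(unname(r2[5]), 0.4, tolerance = 1e-9)

  # planted sigma on one residue, others fixed: closed form sigma * sqrt(3)
  amp <- c(`85` = 0.2)
  sim <- sim_ensemble(build_toy_fold(), n_frames = 2000, amplitude = amp,
                      base_amplitude = 0, seed = 4)
  r <- rmsf_per_residue(sim$ensemble)
  expect_equal(unname(r["85"]), 0.2 * sqrt(3), tolerance = 0.05)
  expect_error(rmsf_per_residue(as_ensemble(co[, , 1, drop = FALSE],
                                            atoms = meta)), "2 frames")
})

test_that("delta RMSF is the elementwise relative change", {
  apo <- c(`1` = 0.2, `2` = 0.4)
  expect_equal(delta_rmsf(apo, apo), c(`1` = 0, `2` = 0))
  expect_equal(delta_rmsf(1.5 * apo, apo), c(`1` = 0.5, `2` = 0.5))
  expect_error(delta_rmsf(c(`1` = 1, `2` = 1), c(`1` = 1, `2` = 0)),
               "residue 2")
})

test_that("distance series handles atoms and centroids", {
  meta <- data.frame(atom_name = c("CA", "CA", "NH1", "NH2"),
                     residue_name = c("ALA", "ALA", "ARG", "ARG"),
                     residue_number = c(1L, 2L, 3L, 3L),
                     chain_id = "A", element = c("C", "C", "N", "N"))
  co <- array(0, c(4, 3, 2))
  co[2, 1, ] <- 3                      # atom 2 at (3,0,0), both frames
  co[3, , ] <- c(10, 1, 0)             # NH1
  co[4, , ] <- c(10, -1, 0)            # NH2 -> centroid (10,0,0)
  ens <- as_ensemble(co, atoms = meta)
  expect_equal(distance_series(ens, list(residue = 1), list(residue = 2)),
               c(3, 3))
  d <- distance_series(ens, list(residue = 1),
                       list(residue = 3, atom = c("NH1", "NH2")))
  expect_equal(d, c(10, 10))
  set.seed(5)
  sim <- sim_ensemble(toy_ca(), n_frames = 4, base_amplitude = 0.3,
                      seed = 5)
  d2 <- distance_series(sim$ensemble, list(residue = 21),
                        list(residue = 145))
  i1 <- which(sim$ensemble$atoms$residue_number == 21)
  i2 <- which(sim$ensemble$atoms$residue_number == 145)
  oracle <- vapply(1:4, function(f) {
    sqrt(sum((sim$ensemble$coords[i1, , f] -
                sim$ensemble$coords[i2, , f])^2))
  }, numeric(1))
  expect_equal(d2, oracle, tolerance = 1e-12)
  expect_error(distance_series(sim$ensemble, list(residue = 9999),
                               list(residue = 21)), "selection")
})

test_that("Heron area equals the cross-product area", {
  expect_equal(heron_area(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), 6)
  expect_equal(heron_area(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)
  set.seed(6)
  for (i in 1:1000) {
    p <- matrix(rnorm(9, sd = 5), 3, 3)
    h <- heron_area(p[1, ], p[2, ], p[3, ])
    cr <- cross_area(p[1, ], p[2, ], p[3, ])
    expect_equal(h, cr, tolerance = 1e-9)
  }
})

test_that("canonical-site area sums two triangles over the frames", {
  # unit square scaled to side 10, split along the diagonal v1-v3
  meta <- data.frame(atom_name = "CA", residue_name = "ALA",
                     residue_number = 1:4, chain_id = "A", element = "C")
  sq <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  co <- array(rep(t(sq), 3), c(3, 4, 3))  # wrong orientation on purpose
  co <- aperm(co, c(2, 1, 3))
  ens <- as_ensemble(co, atoms = meta)
  res <- canonical_site_area(ens, vertices = c(1, 2, 3, 4))
  expect_equal(res$series, rep(100, 3))
  expect_equal(res$mean, 100)

  # identical ensembles give zero percent change
  expect_equal(area_percent_change(res$mean, res$mean), 0)
  # the decomposition is symmetric in the shared edge: swapping the two
  # off-diagonal vertices leaves the area unchanged
  res2 <- canonical_site_area(ens, vertices = c(1, 4, 3, 2))
  expect_equal(res2$series, res$series)
})

test_that("ensemble metrics are invariant under a global rigid transform", {
  sim <- sim_ensemble(toy_ca(), n_frames = 6, base_amplitude = 0.1,
                      seed = 8)
  ens <- sim$ensemble
  # one common rigid transform applied to every frame
  set.seed(99)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  tr <- runif(3, -10, 10)
  co2 <- ens$coords
  for (f in 1:6) {
    co2[, , f] <- sweep(ens$coords[, , f] %*% t(R), 2, tr, `+`)
  }
  ens2 <- as_ensemble(co2, atoms = ens$atoms)
  expect_equal(rmsd_series(ens2), rmsd_series(ens), tolerance = 1e-6)
  expect_equal(rmsf_per_residue(ens2), rmsf_per_residue(ens),
               tolerance = 1e-6)
  a1 <- canonical_site_area(ens)
  a2 <- canonical_site_area(ens2)
  expect_equal(a2$series, a1$series, tolerance = 1e-6)
})

test_that("superposition agrees with an independent structural package", {
  skip_if_not_installed("bio3d")
  set.seed(12)
  P <- matrix(rnorm(30, sd = 4), 10, 3)
  Q <- matrix(rnorm(30, sd = 4), 10, 3)
  ours <- kabsch_superpose(P, Q)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(P)),
                                            mobile = as.vector(t(Q))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3,
                                        byrow = TRUE) - P)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("array-file ensembles round-trip", {
  sim <- sim_ensemble(toy_ca(), n_frames = 3, base_amplitude = 0.1,
                      seed = 2)
  f <- tempfile(fileext = ".txt")
  flat <- t(vapply(1:3, function(fr) {
    as.vector(t(sim$ensemble$coords[, , fr]))
  }, numeric(60 * 3)))
  write.table(flat, f, row.names = FALSE, col.names = FALSE)
  back <- read_ensemble_array(f, sim$ensemble$atoms)
  expect_equal(back$coords, sim$ensemble$coords, tolerance = 1e-12)
})
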