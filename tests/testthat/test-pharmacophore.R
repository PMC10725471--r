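make_model_subset <- function(model, idx) {
  f <- model$features[idx, ]
  ligand_conformer("SELF", data.frame(kind = f$kind, x = f$x, y = f$y,
                                      z = f$z, stringsAsFactors = FALSE))
}

test_that("model building places typed features at atom-set centroids", {
  fold <- build_toy_fold()
  model <- build_pharmacophore(fold)
  expect_equal(nrow(model$features), 9L)
  expect_setequal(unique(model$features$kind),
                  c("hydrophobic", "aromatic", "positive", "negative",
                    "donor", "acceptor"))
  expect_true(all(as.matrix(stats::dist(
    model$features[, c("x", "y", "z")])) [upper.tri(diag(9))] > 0))

  expect_error(build_pharmacophore(fold, data.frame()), "empty")

  spec1 <- data.frame(residue_number = 85L, kind = "hydrophobic")
  spec1$atoms <- list("CA")
  m1 <- build_pharmacophore(fold, spec1)
  ca <- select_atoms(fold, 85, atom = "CA")
  expect_equal(unlist(m1$features[1, c("x", "y", "z")]), ca[1, ],
               ignore_attr = TRUE)

  pos <- build_pharmacophore(fold,
    {s <- bax_interface_features(); s[s$kind == "positive", ]})
  guan <- select_atoms(fold, 109, atom = c("NH1", "NH2", "CZ"))
  expect_equal(as.numeric(pos$features[1, c("x", "y", "z")]),
               unname(colMeans(guan)))
})

test_that("a conformer copied from the model self-matches exactly", {
  model <- build_pharmacophore(build_toy_fold())
  kinds <- model$features$kind
  idx <- c(which(kinds == "hydrophobic")[1:3],
           which(kinds == "aromatic")[1], which(kinds == "donor")[1])
  self <- make_model_subset(model, idx)

  maps <- enumerate_correspondences(model, self)
  has_identity <- any(vapply(maps, function(m) {
    nrow(m) == 5 && all(sort(m[, "model"]) == sort(idx)) &&
      all(m[, "ligand"] == match(m[, "model"], idx))
  }, logical(1)))
  expect_true(has_identity)

  res <- match_conformer(model, self)
  expect_true(res$passed)
  expect_equal(res$n_matched, 5L)
  expect_equal(res$alignment_rmsd, 0, tolerance = 1e-9)
  expect_equal(res$fit_score, 5, tolerance = 1e-9)
})

test_that("distance-incompatible conformers yield no correspondences", {
  model <- build_pharmacophore(build_toy_fold())
  kinds <- model$features$kind
  idx <- c(which(kinds == "hydrophobic")[1:3],
           which(kinds == "aromatic")[1], which(kinds == "donor")[1])
  f <- model$features[idx, ]
  # stretch all pairwise distances by ~10 A: move points apart radially
  ctr <- colMeans(as.matrix(f[, c("x", "y", "z")]))
  pts <- as.matrix(f[, c("x", "y", "z")])
  pts <- sweep(sweep(pts, 2, ctr), 1, 1 + 10 / sqrt(rowSums(
    sweep(pts, 2, ctr)^2)), `*`)
  far <- ligand_conformer("FAR", data.frame(kind = f$kind, x = pts[, 1],
                                            y = pts[, 2], z = pts[, 3]))
  expect_length(enumerate_correspondences(model, far, tolerance = 2), 0L)
  expect_false(match_conformer(model, far)$passed)
})

test_that("matching is invariant to rigid transforms of the conformer", {
  model <- build_pharmacophore(build_toy_fold())
  lib <- sim_conformer_library(model, n_active = 2, n_decoy = 1,
                               jitter = 0.2, seed = 11)
  set.seed(42)
  for (cf in lib$conformers) {
    r0 <- match_conformer(model, cf)
    r1 <- match_conformer(model, rigid_transform_conformer(cf))
    expect_equal(r1$passed, r0$passed)
    expect_equal(r1$n_matched, r0$n_matched)
    if (r0$passed) {
      expect_equal(r1$alignment_rmsd, r0$alignment_rmsd,
                   tolerance = 1e-6)
    }
  }
})

test_that("matcher agrees with the exhaustive brute-force oracle", {
  set.seed(7)
  for (i in 1:60) {
    inst <- random_instance(sample(4:6, 1), sample(4:6, 1),
                            kinds = c("hydrophobic", "donor", "acceptor"))
    got <- match_conformer(inst$model, inst$conformer)
    want <- brute_match(inst$model, inst$conformer)
    expect_equal(got$passed, want$passed)
    expect_equal(got$n_matched, as.integer(want$n_matched))
    if (want$passed) {
      expect_equal(got$alignment_rmsd, want$rmsd, tolerance = 1e-8)
    }
  }
})

test_that("enumeration equals brute-force mapping enumeration", {
  # every injective kind-compatible distance-consistent mapping must be
  # found exactly once
  set.seed(13)
  for (i in 1:10) {
    inst <- random_instance(5, 5, kinds = c("hydrophobic", "donor"),
                            box = 4)
    tol <- 1.0
    maps <- enumerate_correspondences(inst$model, inst$conformer,
                                      tolerance = tol, min_size = 4)
    keys <- vapply(maps, function(m) paste(t(m), collapse = ","),
                   character(1))
    expect_false(anyDuplicated(keys) > 0)
    # oracle: filter all combinations x permutations by the same bound
    Pm <- as.matrix(inst$model$features[, c("x", "y", "z")])
    Pl <- as.matrix(inst$conformer$features[, c("x", "y", "z")])
    dm <- as.matrix(dist(Pm)); dl <- as.matrix(dist(Pl))
    mk <- inst$model$features$kind; lk <- inst$conformer$features$kind
    want <- character(0)
    for (k in 4:5) {
      for (ms in utils::combn(5, k, simplify = FALSE)) {
        for (ls in utils::combn(5, k, simplify = FALSE)) {
          for (lp in perms(ls)) {
            if (!all(mk[ms] == lk[lp])) next
            ok <- TRUE
            for (a in 1:(k - 1)) for (b in (a + 1):k) {
              if (abs(dm[ms[a], ms[b]] - dl[lp[a], lp[b]]) > 2 * tol) {
                ok <- FALSE
              }
            }
            if (ok) want <- c(want,
                              paste(rbind(ms, lp), collapse = ","))
          }
        }
      }
    }
    expect_setequal(keys, want)
  }
})

test_that("library screening ranks planted actives above decoys", {
  model <- build_pharmacophore(build_toy_fold())
  lib <- sim_conformer_library(model, n_active = 5, n_decoy = 45,
                               jitter = 0.1, seed = 3)
  tab <- screen_library(model, lib$conformers, top_k = 50)
  actives <- lib$truth$id[lib$truth$active]
  expect_setequal(tab$ligand_id[1:5], actives)
  expect_true(all(tab$passed[1:5]))
  expect_false(any(tab$passed[-(1:5)]))
  # top_k larger than the library returns the full table
  expect_equal(nrow(screen_library(model, lib$conformers, top_k = 500)),
               50L)
  expect_equal(nrow(screen_library(model, lib$conformers, top_k = 3)), 3L)
  # deterministic for fixed inputs
  tab2 <- screen_library(model, lib$conformers, top_k = 50)
  expect_identical(tab, tab2)
  expect_equal(nrow(screen_library(model, list(), top_k = 10)), 0L)
})

test_that("composition rule constrains which mappings can win", {
  model <- build_pharmacophore(build_toy_fold())
  kinds <- model$features$kind
  # 4 hydrophobic features only: fails the aromatic requirement
  idx <- which(kinds == "hydrophobic")[1:4]
  hydro <- make_model_subset(model, idx)
  expect_false(match_conformer(model, hydro)$passed)
  # same conformer passes under a rule with no aromatic requirement
  loose <- composition_rule(min_matched = 4, required_hydrophobic = 3,
                            required_aromatic = 0)
  expect_true(match_conformer(model, hydro, rule = loose)$passed)
})

test_that("model YAML and conformer TSV round-trip", {
  model <- build_pharmacophore(build_toy_fold())
  f <- tempfile(fileext = ".yaml")
  write_pharmacophore(model, f)
  m2 <- read_pharmacophore(f)
  expect_equal(m2$features$kind, model$features$kind)
  expect_equal(m2$features$x, model$features$x, tolerance = 1e-9)
  expect_equal(m2$tolerance, model$tolerance)
  expect_equal(unclass(m2$rule), unclass(model$rule))

  lib <- sim_conformer_library(model, n_active = 2, n_decoy = 2, seed = 1)
  tsv <- tempfile(fileext = ".tsv")
  write_conformer_library(lib$conformers, tsv)
  back <- read_conformer_library(tsv)
  expect_equal(length(back), 4L)
  expect_equal(back[[1]]$features$x, lib$conformers[[1]]$features$x,
               tolerance = 1e-9)
})
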