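# Independent oracles used to cross-check the package's implementations.
# Nothing here calls the code path it checks.

# all permutations of a vector (small n only)
perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Horn's quaternion method: optimal rotation/RMSD of Q onto P
quat_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Qc) %*% Pc
  K <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]
  ), 4, 4, byrow = TRUE)
  eig <- eigen(K, symmetric = TRUE)
  lmax <- eig$values[1]
  q <- eig$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  rmsd <- sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lmax)) / nrow(P))
  list(rotation = R, rmsd = rmsd,
       transform = function(X) sweep(sweep(X, 2, cq) %*% t(R), 2, cp, `+`))
}

# cross-product triangle area: |AB x AC| / 2
cross_area <- function(p1, p2, p3) {
  ab <- p2 - p1; ac <- p3 - p1
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  sqrt(sum(cr^2)) / 2
}

# Exhaustive pharmacophore matcher: enumerates every injective,
# kind-compatible mapping of size >= rule$min_matched (combinations x
# permutations), superposes with the quaternion method, and applies the
# same validity criteria (post-alignment paired distances <= tolerance,
# composition rule). Returns passed / n_matched / best rmsd / best score.
brute_match <- function(model, conformer, tolerance = model$tolerance,
                        rule = model$rule) {
  polar <- c("donor", "acceptor", "positive", "negative")
  ok_rule <- function(kinds) {
    n <- length(kinds)
    req_polar <- if (n >= 5) rule$required_polar_5 else rule$required_polar_4
    n >= rule$min_matched &&
      sum(kinds == "hydrophobic") >= rule$required_hydrophobic &&
      sum(kinds == "aromatic") >= rule$required_aromatic &&
      sum(kinds %in% polar) >= req_polar
  }
  Pm <- as.matrix(model$features[, c("x", "y", "z")])
  Pl <- as.matrix(conformer$features[, c("x", "y", "z")])
  mk <- model$features$kind
  lk <- conformer$features$kind
  nm <- nrow(Pm); nl <- nrow(Pl)
  best <- NULL
  for (k in seq(rule$min_matched, min(nm, nl))) {
    if (k > nm || k > nl) next
    msubs <- utils::combn(nm, k, simplify = FALSE)
    for (ms in msubs) {
      if (!ok_rule(mk[ms])) next
      for (ls in utils::combn(nl, k, simplify = FALSE)) {
        for (lp in perms(ls)) {
          if (!all(mk[ms] == lk[lp])) next
          fit <- quat_superpose(Pm[ms, , drop = FALSE],
                                Pl[lp, , drop = FALSE])
          aligned <- fit$transform(Pl[lp, , drop = FALSE])
          pd <- sqrt(rowSums((aligned - Pm[ms, , drop = FALSE])^2))
          if (any(pd > tolerance)) next
          score <- k - fit$rmsd / tolerance
          if (is.null(best) || score > best$score + 1e-12 ||
              (abs(score - best$score) <= 1e-12 &&
               fit$rmsd < best$rmsd)) {
            best <- list(score = score, rmsd = fit$rmsd, n = k)
          }
        }
      }
    }
  }
  if (is.null(best)) {
    list(passed = FALSE, n_matched = 0L, rmsd = NA_real_, score = -Inf)
  } else {
    list(passed = TRUE, n_matched = best$n, rmsd = best$rmsd,
         score = best$score)
  }
}

# random small pharmacophore instance (model + conformer) for oracle tests
random_instance <- function(n_model, n_lig, kinds = NULL, box = 8,
                            rule = composition_rule(
                              min_matched = 4, required_hydrophobic = 0,
                              required_aromatic = 0, required_polar_4 = 0,
                              required_polar_5 = 0),
                            tolerance = 1.0) {
  all_kinds <- c("hydrophobic", "aromatic", "positive", "negative",
                 "donor", "acceptor")
  if (is.null(kinds)) kinds <- all_kinds
  mk <- sample(kinds, n_model, replace = TRUE)
  lk <- sample(kinds, n_lig, replace = TRUE)
  mf <- data.frame(kind = mk,
                   x = runif(n_model, 0, box), y = runif(n_model, 0, box),
                   z = runif(n_model, 0, box),
                   source_tag = paste0("m", seq_len(n_model)),
                   stringsAsFactors = FALSE)
  model <- baxdm:::new_pharmacophore(mf, tolerance, rule)
  lf <- data.frame(kind = lk,
                   x = runif(n_lig, 0, box), y = runif(n_lig, 0, box),
                   z = runif(n_lig, 0, box), stringsAsFactors = FALSE)
  list(model = model, conformer = ligand_conformer("L1", lf))
}

# random rigid transform applied to a conformer
rigid_transform_conformer <- function(conformer) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  tr <- runif(3, -15, 15)
  pts <- as.matrix(conformer$features[, c("x", "y", "z")]) %*% t(R)
  pts <- sweep(pts, 2, tr, `+`)
  f <- conformer$features
  f$x <- pts[, 1]; f$y <- pts[, 2]; f$z <- pts[, 3]
  ligand_conformer(conformer$id, f)
}

# grid-search oracle for the one-site fit: profile kd on a fine log grid,
# solving (bmax, baseline) analytically per kd by linear least squares
grid_one_site <- function(conc, resp, kd_grid =
                            10^seq(log10(min(conc) / 10),
                                   log10(max(conc) * 10),
                                   length.out = 4000)) {
  best_rss <- Inf; best_kd <- NA
  for (kd in kd_grid) {
    f <- conc / (kd + conc)
    co <- stats::lm.fit(cbind(f, 1), resp)$coefficients
    rss <- sum((resp - co[1] * f - co[2])^2)
    if (rss < best_rss) { best_rss <- rss; best_kd <- kd }
  }
  best_kd
}

# grid-search oracle for the constrained 4PL IC50 (h profiled per ic50)
grid_ic50 <- function(conc, resp, top, bottom,
                      ic50_grid = 10^seq(log10(min(conc) / 10),
                                         log10(max(conc) * 10),
                                         length.out = 2000),
                      h_grid = seq(0.2, 5, by = 0.02)) {
  best_rss <- Inf; best_ic50 <- NA
  for (ic50 in ic50_grid) {
    for (h in h_grid) {
      pred <- bottom + (top - bottom) / (1 + (conc / ic50)^h)
      rss <- sum((resp - pred)^2)
      if (rss < best_rss) { best_rss <- rss; best_ic50 <- ic50 }
    }
  }
  best_ic50
}

# minimal hand-written PDB fixture: 3 atoms of a lysine, single model
lysine_fixture <- function() {
  paste(
    "ATOM      1  N   LYS A  21      11.104  13.207   2.100  1.00  0.00           N",
    "ATOM      2  CA  LYS A  21      12.560  13.300   2.200  1.00  0.00           C",
    "ATOM      3  NZ  LYS A  21      15.250  14.100   3.300  1.00  0.00           N",
    sep = "\n")
}
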