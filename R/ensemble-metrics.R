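# Rigid superposition and conformational-ensemble analytics: RMSD series,
# per-residue RMSF and its relative change on ligand binding, residue-pair
# distance series, and the two-triangle Heron decomposition of the
# canonical-site area.

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation that minimize the RMSD of `Q`
#' onto `P` (SVD of the cross-covariance; a reflection in the optimum is
#' corrected by flipping the smallest singular direction). Collinear point
#' sets leave the rotation about the common axis undetermined; these are
#' flagged degenerate and handled translation-only.
#'
#' @param P,Q Numeric n x 3 matrices (n >= 3) of matched points.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3), `rmsd` (Angstrom), `degenerate` (logical) and `transform`,
#'   a function mapping an m x 3 matrix into the frame of `P`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L) {
    stop("P and Q must be matched n x 3 matrices")
  }
  if (nrow(P) < 3L) stop("superposition requires at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  C <- crossprod(Qc, Pc)
  sv <- svd(C)
  scale0 <- max(sv$d[1L], sqrt(sum(Pc^2) * sum(Qc^2)), .Machine$double.eps)
  degenerate <- sv$d[2L] < 1e-10 * scale0
  if (degenerate) {
    R <- diag(3)
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  Qfit <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Qfit - Pc)^2)))
  transform <- function(X) {
    X <- as.matrix(X)
    sweep(sweep(X, 2L, cq) %*% t(R), 2L, cp, `+`)
  }
  list(rotation = R, translation = cp - as.vector(cq %*% t(R)),
       rmsd = rmsd, degenerate = degenerate, transform = transform)
}

#' Build a conformational ensemble
#'
#' An ensemble is a stack of frames sharing one atom table. It can be built
#' from a multi-model structure ([parse_pdb()]) — each model becomes a frame
#' — or from a coordinate array plus an atom-metadata data.frame.
#'
#' @param x A `"bax_structure"`, or a numeric array of dimension
#'   `c(n_atoms, 3, n_frames)`.
#' @param atoms Atom metadata (data.frame with at least `atom_name` and
#'   `residue_number`); required when `x` is an array.
#' @param frame_times Optional numeric vector of frame times (ns).
#' @return Object of class `"conformation_ensemble"`: list with `coords`
#'   (n_atoms x 3 x n_frames array), `atoms`, `n_frames`, `frame_times`.
#' @export
as_ensemble <- function(x, atoms = NULL, frame_times = NULL) {
  if (inherits(x, "bax_structure")) {
    per_model <- split(seq_len(nrow(x$atoms)), x$atoms$model_index)
    n <- lengths(per_model)
    if (length(unique(n)) != 1L) {
      stop("models differ in atom count; cannot form an ensemble")
    }
    a1 <- x$atoms[per_model[[1L]], c("atom_name", "residue_name",
                                     "residue_number", "chain_id", "element")]
    for (m in seq_along(per_model)[-1L]) {
      am <- x$atoms[per_model[[m]], ]
      if (!identical(am$atom_name, a1$atom_name) ||
          !identical(am$residue_number, a1$residue_number)) {
        stop("atom order differs between models; cannot form an ensemble")
      }
    }
    coords <- array(NA_real_, c(n[[1L]], 3L, length(per_model)))
    for (m in seq_along(per_model)) {
      coords[, , m] <- as.matrix(x$atoms[per_model[[m]], c("x", "y", "z")])
    }
    atoms <- a1
    rownames(atoms) <- NULL
  } else {
    coords <- x
    if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L) {
      stop("coordinate array must have dimension c(n_atoms, 3, n_frames)")
    }
    if (is.null(atoms)) stop("atom metadata required with a coordinate array")
    if (nrow(atoms) != dim(coords)[1L]) {
      stop("atom metadata rows must match the array's first dimension")
    }
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates in ensemble")
  structure(
    list(coords = coords, atoms = as.data.frame(atoms),
         n_frames = dim(coords)[3L], frame_times = frame_times),
    class = "conformation_ensemble"
  )
}

#' Read an ensemble from a whitespace-delimited frame array file
#'
#' The file holds one row per frame with `3 * n_atoms` numbers
#' (x1 y1 z1 x2 y2 z2 ...); atom metadata comes from a sidecar data.frame.
#'
#' @param file Path to the array file.
#' @param atoms Atom metadata data.frame (see [as_ensemble()]).
#' @return A `"conformation_ensemble"`.
#' @export
read_ensemble_array <- function(file, atoms) {
  m <- as.matrix(utils::read.table(file, header = FALSE))
  n_atoms <- nrow(atoms)
  if (ncol(m) != 3L * n_atoms) {
    stop("array file has ", ncol(m), " columns; expected ", 3L * n_atoms)
  }
  coords <- array(NA_real_, c(n_atoms, 3L, nrow(m)))
  for (f in seq_len(nrow(m))) {
    coords[, , f] <- matrix(m[f, ], ncol = 3L, byrow = TRUE)
  }
  as_ensemble(coords, atoms = atoms)
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("<conformation_ensemble> ", dim(x$coords)[1L], " atoms x ",
      x$n_frames, " frames\n", sep = "")
  invisible(x)
}

# n x 3 coordinate matrix of selected atoms in one frame
frame_coords <- function(ensemble, idx, f) {
  matrix(ensemble$coords[idx, , f], ncol = 3L)
}

# Resolve a selection on the shared atom table -> integer atom indices.
# `sel` is NULL (all atoms), an integer vector of row indices, an atom-name
# string such as "CA", or list(residue = <int>, atom = <names|"sidechain">).
ensemble_select <- function(ensemble, sel) {
  a <- ensemble$atoms
  if (is.null(sel)) return(seq_len(nrow(a)))
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.character(sel) && length(sel) >= 1L && !is.list(sel)) {
    idx <- which(a$atom_name %in% sel)
    if (length(idx) == 0L) stop("selection error: no atoms named ",
                                paste(sel, collapse = "/"))
    return(idx)
  }
  if (is.list(sel)) {
    idx <- which(a$residue_number %in% sel$residue)
    if (length(idx) == 0L) {
      stop("selection error: residue ", paste(sel$residue, collapse = ","),
           " not in ensemble")
    }
    atom <- if (is.null(sel$atom)) "CA" else sel$atom
    if (identical(atom, "sidechain")) {
      keep <- !(a$atom_name[idx] %in% .backbone_atoms) &
        !.is_hydrogen(a$atom_name[idx], a$element[idx])
    } else {
      keep <- a$atom_name[idx] %in% atom
    }
    idx <- idx[keep]
    if (length(idx) == 0L) {
      stop("selection error: residue ", paste(sel$residue, collapse = ","),
           " has no atoms matching ", paste(atom, collapse = "/"))
    }
    return(idx)
  }
  stop("unsupported selection")
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is rigidly superposed onto the reference frame on the
#' selection and the RMSD reported on the same selection.
#'
#' @param ensemble A `"conformation_ensemble"`.
#' @param reference_frame Frame index used as reference (default 1).
#' @param sel Selection (see Details of [rmsf_per_residue()]); default all
#'   atoms.
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L, sel = NULL) {
  idx <- ensemble_select(ensemble, sel)
  ref <- frame_coords(ensemble, idx, reference_frame)
  vapply(seq_len(ensemble$n_frames), function(f) {
    kabsch_superpose(ref, frame_coords(ensemble, idx, f))$rmsd
  }, numeric(1))
}

#' Per-residue RMSF over an ensemble
#'
#' Frames are superposed onto the unfitted mean structure (one pass, on
#' the `fit_sel` atoms — by default the whole structure, so a single
#' mobile residue cannot drag the frame of reference), the mean is
#' recomputed from the fitted frames, and
#' `RMSF_i = sqrt(mean_f |x_i(f) - xbar_i|^2)` is reported per selected
#' atom, labelled by residue number. The default reporting selection is
#' the C-alpha trace, the conventional residue proxy.
#'
#' @param ensemble A `"conformation_ensemble"` with >= 2 frames.
#' @param sel Reporting selection resolved on the shared atom table:
#'   `NULL`, atom name(s), integer indices, or `list(residue=, atom=)`.
#' @param fit_sel Selection used for the superposition (default `NULL`,
#'   all atoms).
#' @return Named numeric vector of RMSF (Angstrom), names = residue numbers.
#' @export
rmsf_per_residue <- function(ensemble, sel = "CA", fit_sel = NULL) {
  if (ensemble$n_frames < 2L) stop("RMSF requires at least 2 frames")
  idx <- ensemble_select(ensemble, sel)
  fidx <- ensemble_select(ensemble, fit_sel)
  m0 <- apply(ensemble$coords[fidx, , , drop = FALSE], c(1L, 2L), mean)
  fitted <- array(NA_real_, c(length(idx), 3L, ensemble$n_frames))
  for (f in seq_len(ensemble$n_frames)) {
    k <- kabsch_superpose(m0, frame_coords(ensemble, fidx, f))
    fitted[, , f] <- k$transform(frame_coords(ensemble, idx, f))
  }
  m1 <- apply(fitted, c(1L, 2L), mean)
  dev2 <- sweep(fitted, c(1L, 2L), m1)^2
  rmsf <- sqrt(apply(dev2, 1L, mean) * 3)
  names(rmsf) <- ensemble$atoms$residue_number[idx]
  rmsf
}

#' Relative change in per-residue RMSF on ligand binding
#'
#' Elementwise `(bound - apo) / apo`, the standard unitless measure of a
#' ligand-induced change in residue dynamics. Following the replicate
#' convention of averaged apo simulations, `rmsf_apo` is typically the mean
#' RMSF over apo replicates.
#'
#' @param rmsf_bound,rmsf_apo Named numeric vectors over the same residues.
#' @return Named numeric vector of relative changes.
#' @export
delta_rmsf <- function(rmsf_bound, rmsf_apo) {
  if (length(rmsf_bound) != length(rmsf_apo) ||
      !identical(names(rmsf_bound), names(rmsf_apo))) {
    stop("bound and apo RMSF vectors must cover the same residues")
  }
  zero <- which(rmsf_apo <= 0)
  if (length(zero)) {
    stop("apo RMSF is zero at residue ",
         paste(names(rmsf_apo)[zero], collapse = ", "),
         "; relative change undefined")
  }
  (rmsf_bound - rmsf_apo) / rmsf_apo
}

#' Residue-pair distance series
#'
#' Euclidean distance per frame between two selections; multi-atom
#' selections are reduced to their centroid (e.g. a guanidinium group or a
#' ligand moiety).
#'
#' @param ensemble A `"conformation_ensemble"`.
#' @param sel1,sel2 Selections (see [rmsf_per_residue()]).
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
distance_series <- function(ensemble, sel1, sel2) {
  i1 <- ensemble_select(ensemble, sel1)
  i2 <- ensemble_select(ensemble, sel2)
  vapply(seq_len(ensemble$n_frames), function(f) {
    p <- colMeans(frame_coords(ensemble, i1, f))
    q <- colMeans(frame_coords(ensemble, i2, f))
    sqrt(sum((p - q)^2))
  }, numeric(1))
}

#' Triangle area by Heron's formula
#'
#' Area from the three side lengths via the semiperimeter,
#' `sqrt(s (s-a) (s-b) (s-c))`; a radicand driven slightly negative by
#' rounding on near-degenerate triangles is clamped to zero.
#'
#' @param p1,p2,p3 Numeric 3-vectors (Angstrom).
#' @return Area in square Angstrom.
#' @export
heron_area <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  s <- (a + b + cc) / 2
  rad <- s * (s - a) * (s - b) * (s - cc)
  sqrt(max(rad, 0))
}

#' Canonical-site area series over an ensemble
#'
#' The opening of the C-terminal canonical groove is quantified as the sum
#' of two triangles spanned by four residues (defaults: C-alpha of K189,
#' V91, T85 and M79, decomposed as K189-V91-T85 + K189-M79-T85), each area
#' by [heron_area()].
#'
#' @param ensemble A `"conformation_ensemble"`.
#' @param vertices Length-4 list of selections or a numeric vector of four
#'   residue numbers in the order (v1, v2, v3, v4); the triangles are
#'   (v1,v2,v3) and (v1,v4,v3). Default `c(189, 91, 85, 79)`.
#' @param atom Atom name used when `vertices` are residue numbers.
#' @return List with `series` (area per frame, square Angstrom) and `mean`.
#' @export
canonical_site_area <- function(ensemble, vertices = c(189L, 91L, 85L, 79L),
                                atom = "CA") {
  if (length(vertices) != 4L) stop("four vertices required")
  sels <- lapply(seq_len(4L), function(i) {
    v <- if (is.list(vertices)) vertices[[i]] else
      list(residue = vertices[[i]], atom = atom)
    ensemble_select(ensemble, v)
  })
  series <- vapply(seq_len(ensemble$n_frames), function(f) {
    pts <- lapply(sels, function(idx) colMeans(frame_coords(ensemble, idx, f)))
    heron_area(pts[[1L]], pts[[2L]], pts[[3L]]) +
      heron_area(pts[[1L]], pts[[4L]], pts[[3L]])
  }, numeric(1))
  list(series = series, mean = mean(series))
}

#' Percent change between two mean areas
#'
#' `100 * (bound - apo) / apo`; with replicate simulations, pass the mean of
#' per-ensemble means for each condition.
#'
#' @param mean_apo,mean_bound Mean canonical-site areas (square Angstrom).
#' @return Percent change (positive = opening).
#' @export
area_percent_change <- function(mean_apo, mean_bound) {
  if (mean_apo <= 0) stop("apo area must be positive")
  100 * (mean_bound - mean_apo) / mean_apo
}
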