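# Seeded generators for every input the analysis stages read: peak lists
# with planted perturbed residues, ensembles with planted fluctuation
# profiles and area changes, binding isotherms, melt-curve pairs, dose
# matrices, SEC elution profiles, depolarization traces and active/decoy
# conformer libraries. Each generator is a pure function of its arguments
# (seed included) and returns a machine-readable `truth` element for
# recovery checks.

# run `code` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- toy fold -------------------------------------------------------------

.sidechain_templates <- list(
  ALA = list(CB = c(1.53, 0, 0)),
  VAL = list(CB = c(1.53, 0, 0), CG1 = c(2.3, 0.9, 0.4),
             CG2 = c(2.3, -0.9, 0.4)),
  LEU = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3),
             CD1 = c(3.6, 0.9, 0.5), CD2 = c(3.6, -0.9, 0.5)),
  THR = list(CB = c(1.53, 0, 0), OG1 = c(2.2, 0.9, 0.3),
             CG2 = c(2.3, -0.9, 0.4)),
  GLN = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3), CD = c(4.0, 0, 0.5),
             OE1 = c(4.7, 0.9, 0.6), NE2 = c(4.7, -0.9, 0.7)),
  ASP = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3),
             OD1 = c(3.5, 0.9, 0.4), OD2 = c(3.5, -0.9, 0.4)),
  ARG = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3), CD = c(4.0, 0, 0.5),
             NE = c(5.2, 0, 0.6), CZ = c(6.4, 0, 0.7),
             NH1 = c(7.1, 0.9, 0.8), NH2 = c(7.1, -0.9, 0.8)),
  LYS = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3), CD = c(4.0, 0, 0.5),
             CE = c(5.2, 0, 0.6), NZ = c(6.4, 0, 0.7)),
  MET = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3), SD = c(4.0, 0, 0.5),
             CE = c(5.2, 0, 0.6)),
  PHE = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3),
             CD1 = c(3.5, 1.2, 0.4), CD2 = c(3.5, -1.2, 0.4),
             CE1 = c(4.9, 1.2, 0.5), CE2 = c(4.9, -1.2, 0.5),
             CZ = c(5.6, 0, 0.6)),
  TYR = list(CB = c(1.53, 0, 0), CG = c(2.8, 0, 0.3),
             CD1 = c(3.5, 1.2, 0.4), CD2 = c(3.5, -1.2, 0.4),
             CE1 = c(4.9, 1.2, 0.5), CE2 = c(4.9, -1.2, 0.5),
             CZ = c(5.6, 0, 0.6), OH = c(7.0, 0, 0.7))
)

.toy_residue_names <- function() {
  h1 <- 20:49
  h2 <- c(79L, 82L, 85L, 88L, 91L, 94L, 97L, 100L, 104L, 109L, 113L, 118L,
          123L, 128L, 134L, 138L, 141L, 145L, 149L, 153L, 157L, 160L, 164L,
          168L, 172L, 176L, 180L, 183L, 186L, 189L)
  named <- c(`21` = "LYS", `24` = "ALA", `25` = "LEU", `28` = "GLN",
             `45` = "LEU", `46` = "ALA", `47` = "LEU", `48` = "ASP",
             `79` = "MET", `85` = "THR", `91` = "VAL", `109` = "ARG",
             `134` = "ARG", `141` = "LEU", `145` = "ARG", `164` = "TYR",
             `172` = "THR", `176` = "PHE", `189` = "LYS")
  resno <- c(h1, h2)
  resname <- rep("ALA", length(resno))
  hit <- match(as.character(resno), names(named))
  resname[!is.na(hit)] <- named[hit[!is.na(hit)]]
  data.frame(residue_number = resno, residue_name = resname,
             stringsAsFactors = FALSE)
}

#' Build the 60-residue helical-hairpin toy fold
#'
#' A deterministic two-helix coordinate set used by the generators and
#' examples in place of a downloaded structure. Residue numbers cover
#' 20-190 sparsely so the named residues of the dimer interface, trigger
#' site and canonical site (K21, Q28, L45-D48, M79, T85, V91, R109, R134,
#' R145, Y164, T172, F176, K189, ...) exist with full heavy-atom
#' sidechains; all other positions are alanine. The geometry is an
#' idealized backbone with schematic sidechain placements: selections
#' resolve and distances are well-conditioned, but the fold is synthetic
#' and carries no physical meaning.
#'
#' @param ca_only If `TRUE`, keep only the C-alpha trace.
#' @return A `"bax_structure"` with one model.
#' @export
build_toy_fold <- function(ca_only = FALSE) {
  res <- .toy_residue_names()
  n <- nrow(res)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    in_h1 <- i <= 30L
    j <- if (in_h1) i else i - 30L
    theta <- j * 100 * pi / 180
    r <- 2.3
    axis_x <- if (in_h1) 0 else 10
    z <- if (in_h1) 1.5 * j else 1.5 * (31 - j)
    ca <- c(axis_x + r * cos(theta), r * sin(theta), z)
    u <- c(cos(theta), sin(theta), 0)            # outward radial
    if (!in_h1) u <- -u                           # point away from partner
    t_hat <- if (in_h1) c(0, 0, 1) else c(0, 0, -1)
    v <- c(u[2L] * t_hat[3L] - u[3L] * t_hat[2L],
           u[3L] * t_hat[1L] - u[1L] * t_hat[3L],
           u[1L] * t_hat[2L] - u[2L] * t_hat[1L])
    place <- function(local) ca + local[1L] * u + local[2L] * v +
      local[3L] * t_hat
    add <- function(name, pos, element) {
      serial <<- serial + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        serial = serial, atom_name = name,
        residue_name = res$residue_name[i],
        residue_number = res$residue_number[i], chain_id = "A",
        x = pos[1L], y = pos[2L], z = pos[3L], element = element,
        model_index = 1L, stringsAsFactors = FALSE)
    }
    add("N", place(c(-0.8, 0.9, -0.5)), "N")
    add("CA", ca, "C")
    add("C", place(c(-0.8, -0.9, 0.5)), "C")
    add("O", place(c(-1.4, -1.5, 0.8)), "O")
    if (!ca_only && res$residue_name[i] != "GLY") {
      tmpl <- .sidechain_templates[[res$residue_name[i]]]
      for (nm in names(tmpl)) {
        add(nm, place(tmpl[[nm]]),
            substr(gsub("[0-9]", "", nm), 1L, 1L))
      }
    }
  }
  atoms <- do.call(rbind, rows)
  if (ca_only) atoms <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_models = 1L, source_id = "toy_fold"),
            class = "bax_structure")
}

# --- peak lists -----------------------------------------------------------

#' Simulate an HSQC peak-list pair with planted perturbations
#'
#' Reference shifts are drawn uniformly in realistic amide windows
#' (1H 6.5-9.5 ppm, 15N 105-130 ppm); the bound list adds Gaussian noise
#' and, on the planted residues, fixed offsets with random sign. A
#' fraction of residues is removed from both lists, standing in for
#' prolines and overlapped or missing peaks.
#'
#' @param n_residues Number of residues (>= 10), numbered from
#'   `first_residue`.
#' @param planted Residue numbers receiving the planted offset.
#' @param offset_H,offset_N Planted offsets (ppm); defaults are 5x the
#'   noise SDs.
#' @param noise_sd_H,noise_sd_N Gaussian noise SDs (ppm) on the bound
#'   list.
#' @param absent_frac Fraction of non-planted residues marked absent
#'   (dropped from the bound list, so they classify as `"absent"`).
#' @param first_residue First residue number.
#' @param seed RNG seed.
#' @return List with `ref`, `bound` (peak lists) and `truth` (planted and
#'   absent residues, offsets).
#' @export
sim_peak_lists <- function(n_residues = 150L, planted = integer(0),
                           offset_H = 0.025, offset_N = 0.125,
                           noise_sd_H = 0.005, noise_sd_N = 0.025,
                           absent_frac = 0.05, first_residue = 2L,
                           seed = 1L) {
  if (n_residues < 10L) stop("need at least 10 residues")
  residues <- seq(first_residue, length.out = n_residues)
  if (!all(planted %in% residues)) {
    stop("planted residues must be a subset of the residue range")
  }
  planted_csp <- 0.5 * sqrt(offset_H^2 + (offset_N / 5)^2)
  noise_csp <- 0.5 * sqrt(noise_sd_H^2 + (noise_sd_N / 5)^2)
  if (length(planted) && planted_csp <= noise_csp) {
    warning("planted offset at or below the noise scale; ",
            "perturbations are undetectable by design")
  }
  with_seed(seed, {
    dH <- stats::runif(n_residues, 6.5, 9.5)
    dN <- stats::runif(n_residues, 105, 130)
    ref <- peak_list(data.frame(residue = residues, delta_H_ppm = dH,
                                delta_N_ppm = dN), label = "ref")
    sgn <- sample(c(-1, 1), n_residues, replace = TRUE)
    is_planted <- residues %in% planted
    bH <- dH + stats::rnorm(n_residues, 0, noise_sd_H) +
      ifelse(is_planted, sgn * offset_H, 0)
    bN <- dN + stats::rnorm(n_residues, 0, noise_sd_N) +
      ifelse(is_planted, sgn * offset_N, 0)
    bound <- peak_list(data.frame(residue = residues, delta_H_ppm = bH,
                                  delta_N_ppm = bN), label = "bound")
    candidates <- residues[!is_planted]
    n_absent <- round(absent_frac * length(candidates))
    absent <- sort(sample(candidates, n_absent))
    # dropped from the bound list only, so they surface as class "absent"
    bound <- peak_list(bound[!bound$residue %in% absent, ],
                       label = "bound")
    list(ref = ref, bound = bound,
         truth = list(planted = planted, absent = absent,
                      offset_H = offset_H, offset_N = offset_N,
                      planted_csp = planted_csp))
  })
}

# --- ensembles ------------------------------------------------------------

#' Simulate a conformational ensemble with planted dynamics
#'
#' Frames are the base structure plus isotropic per-atom Gaussian
#' displacements whose SD is set per residue by `amplitude` (Angstrom per
#' coordinate); the closed-form RMSF of a residue with amplitude `s` is
#' `s * sqrt(3)`. When `area_percent` is given, the four canonical-site
#' vertex residues are scaled about their common centroid by
#' `sqrt(1 + area_percent / 100)` in every frame, which multiplies every
#' vertex pairwise distance by that factor and hence the two-triangle site
#' area by exactly `1 + area_percent / 100`.
#'
#' @param base A single-model `"bax_structure"` (default
#'   [build_toy_fold()]).
#' @param n_frames Number of frames (>= 2).
#' @param amplitude Either a single SD applied to all residues or a named
#'   vector keyed by residue number (Angstrom); unnamed residues get
#'   `base_amplitude`.
#' @param base_amplitude Default per-coordinate SD (Angstrom).
#' @param area_percent Optional target percent change of the
#'   canonical-site area.
#' @param area_vertices Residue numbers of the four site vertices.
#' @param seed RNG seed.
#' @return List with `ensemble` (a `"conformation_ensemble"`) and `truth`
#'   (expected per-residue RMSF and the area scale factor).
#' @export
sim_ensemble <- function(base = build_toy_fold(), n_frames = 100L,
                         amplitude = NULL, base_amplitude = 0.05,
                         area_percent = NULL,
                         area_vertices = c(189L, 91L, 85L, 79L),
                         seed = 1L) {
  if (n_frames < 2L) stop("need at least 2 frames")
  atoms <- base$atoms[base$atoms$model_index == 1L, , drop = FALSE]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  resno <- atoms$residue_number
  sd_per_res <- stats::setNames(
    rep(base_amplitude, length(unique(resno))),
    as.character(sort(unique(resno))))
  if (!is.null(amplitude)) {
    if (is.null(names(amplitude))) {
      sd_per_res[] <- amplitude
    } else {
      sd_per_res[names(amplitude)] <- amplitude
    }
  }
  sd_atom <- sd_per_res[as.character(resno)]
  if (!is.null(area_percent)) {
    s <- sqrt(1 + area_percent / 100)
    v_idx <- which(resno %in% area_vertices & atoms$atom_name == "CA")
    if (length(v_idx) != 4L) stop("area vertices not all present")
    centroid <- colMeans(xyz[v_idx, , drop = FALSE])
    for (rn in area_vertices) {
      ridx <- which(resno == rn)
      ca <- xyz[which(resno == rn & atoms$atom_name == "CA"), ]
      shift <- (s - 1) * (ca - centroid)
      xyz[ridx, ] <- sweep(xyz[ridx, , drop = FALSE], 2L, shift, `+`)
    }
  } else {
    s <- 1
  }
  coords <- with_seed(seed, {
    out <- array(NA_real_, c(nrow(xyz), 3L, n_frames))
    for (f in seq_len(n_frames)) {
      out[, , f] <- xyz + stats::rnorm(length(xyz), 0, sd_atom)
    }
    out
  })
  meta <- atoms[, c("atom_name", "residue_name", "residue_number",
                    "chain_id", "element")]
  rownames(meta) <- NULL
  list(
    ensemble = as_ensemble(coords, atoms = meta),
    truth = list(
      expected_rmsf = sd_per_res * sqrt(3),
      area_scale = s^2,
      area_percent = if (is.null(area_percent)) 0 else area_percent
    )
  )
}

# --- isotherms ------------------------------------------------------------

#' Simulate a one-site binding isotherm
#'
#' Log-spaced titration bracketing the dissociation constant by at least
#' `span`-fold on each side, with multiplicative Gaussian noise of the
#' stated coefficient of variation.
#'
#' @param kd True dissociation constant (nM).
#' @param bmax,baseline Curve amplitude and offset.
#' @param n_points Number of titration points (>= 5).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param span Fold-range on each side of `kd` (>= 10).
#' @param seed RNG seed.
#' @return List with `concentration`, `response` and `truth`.
#' @export
sim_isotherm <- function(kd, bmax = 1, baseline = 0, n_points = 12L,
                         noise_cv = 0.03, span = 30, seed = 1L) {
  if (kd <= 0) stop("kd must be positive")
  if (n_points < 5L) stop("need at least 5 points")
  if (span < 10) stop("titration must bracket kd by at least 10x")
  conc <- 10^seq(log10(kd / span), log10(kd * span),
                 length.out = n_points)
  mu <- bmax * conc / (kd + conc) + baseline
  response <- with_seed(seed, mu * (1 + stats::rnorm(n_points, 0, noise_cv)))
  list(concentration = conc, response = response,
       truth = list(kd = kd, bmax = bmax, baseline = baseline))
}

# --- melt curves ----------------------------------------------------------

#' Simulate a control/treated thermal-shift curve pair
#'
#' Two-state Boltzmann melts sampled at the eight-point cellular
#' thermal-shift gradient (50, 52.1, 55.4, 59.4, 64.9, 69.2, 72.1, 74
#' degC) plus the 25 degC anchor, with multiplicative noise. The treated
#' melting point is `tm_control - delta_tm` (destabilization positive).
#'
#' @param tm_control Control melting temperature (degC).
#' @param delta_tm Planted destabilization (degC).
#' @param k Transition slope (degC).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param temperatures Sampling temperatures.
#' @param seed RNG seed.
#' @return List with `control`, `treated` (data.frames `temperature`,
#'   `signal`) and `truth`.
#' @export
sim_melt_curves <- function(tm_control = 62, delta_tm = 4.5, k = 2,
                            noise_cv = 0.02,
                            temperatures = c(25, 50, 52.1, 55.4, 59.4,
                                             64.9, 69.2, 72.1, 74),
                            seed = 1L) {
  tm_treated <- tm_control - delta_tm
  if (tm_control >= max(temperatures) || tm_treated <= min(temperatures)) {
    stop("melting points must lie inside the temperature span")
  }
  boltz <- function(T, tm) 100 / (1 + exp((T - tm) / k))
  with_seed(seed, {
    noisy <- function(tm) {
      mu <- boltz(temperatures, tm)
      data.frame(temperature = temperatures,
                 signal = mu * (1 + stats::rnorm(length(mu), 0, noise_cv)))
    }
    list(control = noisy(tm_control), treated = noisy(tm_treated),
         truth = list(tm_control = tm_control, tm_treated = tm_treated,
                      delta_tm = delta_tm, k = k))
  })
}

# --- dose matrices --------------------------------------------------------

#' Simulate a dose-combination effect matrix
#'
#' Single-agent effects follow Hill curves
#' `f(d) = d^h / (ic50^h + d^h)`; combinations are Bliss-independent plus
#' a planted synergy excess `delta` on all interior (both doses nonzero)
#' cells, plus additive noise. Effects are clipped to `[0, 1]` and the
#' clipped cells flagged.
#'
#' @param doses_a,doses_b Dose vectors including 0.
#' @param ic50_a,h_a,ic50_b,h_b Hill parameters of the two agents.
#' @param delta Planted Bliss excess on interior cells.
#' @param noise_sd Additive noise SD.
#' @param seed RNG seed.
#' @return List with `matrix` (a `"dose_matrix"`, carrying a `clipped`
#'   attribute) and `truth`.
#' @export
sim_dose_matrix <- function(doses_a = c(0, 125 * 2^(0:5)),
                            doses_b = c(0, 125 * 2^(0:5)),
                            ic50_a = 1000, h_a = 1,
                            ic50_b = 1000, h_b = 1,
                            delta = 0, noise_sd = 0, seed = 1L) {
  if (!0 %in% doses_a || !0 %in% doses_b) stop("dose grids must include 0")
  hill <- function(d, ic50, h) ifelse(d == 0, 0, d^h / (ic50^h + d^h))
  f_a <- hill(doses_a, ic50_a, h_a)
  f_b <- hill(doses_b, ic50_b, h_b)
  expected <- outer(f_a, f_b, function(a, b) a + b - a * b)
  interior <- outer(doses_a > 0, doses_b > 0, `&`)
  eff <- expected + delta * interior
  eff <- with_seed(seed, eff + matrix(
    stats::rnorm(length(eff), 0, noise_sd) * interior, nrow(eff)))
  clipped <- eff < 0 | eff > 1
  eff <- pmin(pmax(eff, 0), 1)
  dm <- dose_matrix(doses_a, doses_b, eff)
  attr(dm, "clipped") <- clipped
  list(matrix = dm,
       truth = list(delta = delta, f_a = f_a, f_b = f_b,
                    any_clipped = any(clipped)))
}

# --- SEC profiles ---------------------------------------------------------

#' Default SEC fraction label to volume-window map
#'
#' 0.5-ml fractions laid out so a dimer peak centered in 14-14.5 ml sits
#' mid-window of C3-C5 and a monomer peak in 15.5-16 ml at the start of
#' C7-C9, with the shared tail in the half-split fraction C6.
#'
#' @return data.frame with `fraction`, `start_ml`, `end_ml`.
#' @export
sec_fraction_map <- function() {
  labs <- c("B1", "B2", paste0("C", 1:9))
  start <- 11.5 + 0.5 * (seq_along(labs) - 1L)
  data.frame(fraction = labs, start_ml = start, end_ml = start + 0.5,
             stringsAsFactors = FALSE)
}

#' Simulate a bimodal SEC elution profile
#'
#' Dimer and monomer species elute as Gaussians centered in the stated
#' volume windows; each fraction's intensity is the integrated peak mass
#' in its 0.5-ml window, times multiplicative noise.
#'
#' @param dimer_fraction Fraction of total mass in the dimer peak, in
#'   `[0, 1]`.
#' @param total Total intensity (arbitrary units).
#' @param dimer_center,monomer_center Peak centers (ml).
#' @param width Peak SD (ml).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param fractions Label/volume map (see [sec_fraction_map()]).
#' @param seed RNG seed.
#' @return List with `profile` (data.frame `fraction`, `intensity`) and
#'   `truth`.
#' @export
sim_sec_profile <- function(dimer_fraction = 0.5, total = 1000,
                            dimer_center = 14.25, monomer_center = 15.75,
                            width = 0.2, noise_cv = 0,
                            fractions = sec_fraction_map(), seed = 1L) {
  if (dimer_fraction < 0 || dimer_fraction > 1) {
    stop("dimer_fraction must lie in [0, 1]")
  }
  mass <- function(center) {
    stats::pnorm(fractions$end_ml, center, width) -
      stats::pnorm(fractions$start_ml, center, width)
  }
  mu <- total * (dimer_fraction * mass(dimer_center) +
                   (1 - dimer_fraction) * mass(monomer_center))
  intensity <- with_seed(seed,
    mu * (1 + stats::rnorm(length(mu), 0, noise_cv)))
  intensity <- pmax(intensity, 0)
  list(profile = data.frame(fraction = fractions$fraction,
                            intensity = intensity,
                            stringsAsFactors = FALSE),
       truth = list(dimer_fraction = dimer_fraction,
                    dimer_center = dimer_center,
                    monomer_center = monomer_center))
}

# --- depolarization traces ------------------------------------------------

#' Simulate depolarization fluorescence time courses
#'
#' The solvent control decays slowly, the uncoupler control drops fast;
#' each sample trace is the pointwise mixture
#' `dmso - p/100 * (dmso - cccp)` for its true percent depolarization `p`,
#' so trapezoid-AUC normalization recovers `p` exactly in the noiseless
#' case.
#'
#' @param true_percent Numeric vector of per-sample true depolarization
#'   percentages.
#' @param time Time grid (min).
#' @param noise_cv Multiplicative noise CV on the sample traces.
#' @param seed RNG seed.
#' @return List with `time`, `sample` (matrix), `dmso`, `cccp`, `truth`.
#' @export
sim_depolarization <- function(true_percent = c(25, 50, 75),
                               time = seq(0, 180, by = 15),
                               noise_cv = 0, seed = 1L) {
  dmso <- 1000 * exp(-0.0005 * time)
  cccp <- 1000 * exp(-0.02 * time)
  sample <- t(vapply(true_percent, function(p) {
    dmso - p / 100 * (dmso - cccp)
  }, numeric(length(time))))
  sample <- with_seed(seed,
    sample * (1 + matrix(stats::rnorm(length(sample), 0, noise_cv),
                         nrow(sample))))
  list(time = time, sample = sample, dmso = dmso, cccp = cccp,
       truth = list(true_percent = true_percent))
}

# --- conformer libraries --------------------------------------------------

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Simulate an active/decoy conformer library around a pharmacophore model
#'
#' Actives are rule-satisfying subsets of the model's own features (three
#' hydrophobic, one aromatic, one polar/charged by default), rigidly
#' transformed into a random frame and jittered. Decoys keep the same
#' feature kinds but have their geometry scaled about the centroid by a
#' factor large enough that no pairwise distance can be matched within
#' `2 * tolerance`, so they cannot satisfy any correspondence of two or
#' more features.
#'
#' @param model A `"pharmacophore_model"`.
#' @param n_active,n_decoy Library composition.
#' @param jitter Per-coordinate Gaussian jitter SD on actives (Angstrom);
#'   must be below the model tolerance.
#' @param seed RNG seed.
#' @return List with `conformers` (list of `"ligand_conformer"`) and
#'   `truth` (data.frame `id`, `active`).
#' @export
sim_conformer_library <- function(model, n_active = 5L, n_decoy = 95L,
                                  jitter = 0.1, seed = 1L) {
  if (jitter >= model$tolerance) {
    stop("jitter must be below the matching tolerance")
  }
  kinds <- model$features$kind
  pick <- c(which(kinds == "hydrophobic")[1:3],
            which(kinds == "aromatic")[1L],
            which(kinds %in% .polar_kinds)[1L])
  if (anyNA(pick)) {
    stop("composition rule unsatisfiable from the model's features")
  }
  sub <- feature_matrix(model$features)[pick, , drop = FALSE]
  sub_kinds <- kinds[pick]
  dmat <- as.matrix(stats::dist(sub))
  dvals <- dmat[upper.tri(dmat)]
  scale_factor <- 1.1 * (max(dvals) + 2 * model$tolerance) / min(dvals)
  with_seed(seed, {
    make <- function(id, pts) {
      pts <- pts %*% t(random_rotation())
      pts <- sweep(pts, 2L, stats::runif(3, -20, 20), `+`)
      pts <- pts + stats::rnorm(length(pts), 0, jitter)
      ligand_conformer(id, data.frame(kind = sub_kinds,
                                      x = pts[, 1L], y = pts[, 2L],
                                      z = pts[, 3L],
                                      stringsAsFactors = FALSE))
    }
    actives <- lapply(seq_len(n_active), function(i) {
      make(sprintf("ACT%03d", i), sub)
    })
    centroid <- colMeans(sub)
    scaled <- sweep(sub, 2L, centroid) * scale_factor
    scaled <- sweep(scaled, 2L, centroid, `+`)
    decoys <- lapply(seq_len(n_decoy), function(i) {
      make(sprintf("DEC%03d", i), scaled)
    })
    conformers <- c(actives, decoys)
    truth <- data.frame(
      id = vapply(conformers, `[[`, character(1), "id"),
      active = c(rep(TRUE, n_active), rep(FALSE, n_decoy)),
      stringsAsFactors = FALSE)
    list(conformers = conformers, truth = truth)
  })
}
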