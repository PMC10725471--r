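# Assay curve fits and quantifications: one-site binding (MST K_D),
# constrained competitive 4PL (FP IC50), thermal-shift melt curves
# (CETSA Tm / delta-Tm), Bliss independence synergy, SEC fraction
# percentages and MW calibration, and AUC-normalized depolarization.

new_curve_fit <- function(model_name, parameters, se, rss, converged,
                          flags = character(0), fitted = NULL,
                          residuals = NULL, data = NULL) {
  structure(
    list(model_name = model_name, parameters = parameters, se = se,
         rss = rss, converged = converged, flags = flags,
         fitted = fitted, residuals = residuals, data = data),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  cat("<curve_fit> ", x$model_name,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  if (length(x$parameters)) {
    print(signif(x$parameters, 6))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.extract_fit <- function(fit, model_name, data) {
  su <- summary(fit)
  pars <- stats::coef(fit)
  se <- su$coefficients[, "Std. Error"]
  new_curve_fit(model_name, pars, se,
                rss = sum(stats::residuals(fit)^2),
                converged = isTRUE(fit$convInfo$isConv),
                fitted = as.numeric(stats::fitted(fit)),
                residuals = as.numeric(stats::residuals(fit)),
                data = data)
}

.failed_fit <- function(model_name, par_names, data, flag) {
  pars <- stats::setNames(rep(NA_real_, length(par_names)), par_names)
  new_curve_fit(model_name, pars, pars, rss = NA_real_, converged = FALSE,
                flags = flag, data = data)
}

#' Fit a one-site specific binding isotherm
#'
#' Least-squares fit of `response = bmax * L / (kd + L) + baseline` to a
#' titration (the model behind MST and other saturation binding readouts).
#' Starting values are taken from the data (`kd0` = concentration at
#' half-maximal response, `bmax0 = max - min`, `baseline0 = min`); `kd` is
#' box-constrained to `[1e-3, 1e7]` nM and flagged when it lands on a
#' bound. Degenerate data (no dynamic range) yield `converged = FALSE` or
#' a flagged near-zero amplitude.
#'
#' @param concentration Ligand concentrations (nM), strictly increasing,
#'   at least 5 points spanning >= 2 orders of magnitude.
#' @param response Measured response (fraction bound or raw signal).
#' @return A `"curve_fit"` with parameters `kd`, `bmax`, `baseline`.
#' @export
fit_one_site <- function(concentration, response) {
  stopifnot(length(concentration) == length(response))
  if (length(concentration) < 5L) stop("need at least 5 titration points")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentration, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  if (max(concentration) / min(concentration) < 100) {
    stop("titration must span at least 2 orders of magnitude")
  }
  data <- data.frame(conc = concentration, resp = response)
  if (diff(range(response)) == 0) {
    return(.failed_fit("one_site_binding", c("kd", "bmax", "baseline"),
                       data, "no_dynamic_range"))
  }
  baseline0 <- min(response)
  bmax0 <- max(response) - min(response)
  half <- baseline0 + bmax0 / 2
  kd0 <- concentration[which.min(abs(response - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bmax * conc / (kd + conc) + baseline,
      data = data,
      start = list(kd = kd0, bmax = bmax0, baseline = baseline0),
      lower = c(kd = 1e-3, bmax = -Inf, baseline = -Inf),
      upper = c(kd = 1e7, bmax = Inf, baseline = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(.failed_fit("one_site_binding", c("kd", "bmax", "baseline"),
                       data, "fit_failed"))
  }
  out <- .extract_fit(fit, "one_site_binding", data)
  kd <- out$parameters[["kd"]]
  if (kd <= 1e-3 * (1 + 1e-6) || kd >= 1e7 * (1 - 1e-6)) {
    out$flags <- c(out$flags, "kd_at_bound")
  }
  if (abs(out$parameters[["bmax"]]) <
      1e-3 * diff(range(response)) + 1e-12) {
    out$flags <- c(out$flags, "no_dynamic_range")
  }
  out
}

#' Fit a constrained competitive four-parameter logistic
#'
#' Fits `response = bottom + (top - bottom) / (1 + (x / ic50)^h)` with the
#' `top` and `bottom` plateaus fixed to the supplied anchors (e.g. the
#' polarization of saturated protein-probe complex and of free probe), so
#' only `ic50` and the Hill slope `h` are free.
#'
#' @param concentration Competitor concentrations (nM), positive.
#' @param response Measured response.
#' @param top_fixed,bottom_fixed Fixed plateau values.
#' @return A `"curve_fit"` with parameters `ic50` and `h`.
#' @export
fit_competitive_4pl <- function(concentration, response, top_fixed,
                                bottom_fixed) {
  stopifnot(length(concentration) == length(response))
  if (any(concentration <= 0)) stop("concentrations must be positive")
  data <- data.frame(conc = concentration, resp = response)
  span <- abs(top_fixed - bottom_fixed)
  if (span == 0) stop("top and bottom anchors are equal")
  mid <- (top_fixed + bottom_fixed) / 2
  ic50_0 <- concentration[which.min(abs(response - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom_fixed + (top_fixed - bottom_fixed) /
        (1 + (conc / ic50)^h),
      data = data,
      start = list(ic50 = ic50_0, h = 1),
      lower = c(ic50 = 1e-3, h = 0.1),
      upper = c(ic50 = 1e7, h = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(.failed_fit("competitive_4pl", c("ic50", "h"), data,
                       "fit_failed"))
  }
  out <- .extract_fit(fit, "competitive_4pl", data)
  # response never leaves a plateau -> IC50 not identified
  if (diff(range(response)) < 0.05 * span) {
    out$flags <- c(out$flags, "ic50_unidentifiable")
    out$converged <- FALSE
  }
  ic50 <- out$parameters[["ic50"]]
  if (ic50 <= 1e-3 * (1 + 1e-6) || ic50 >= 1e7 * (1 - 1e-6)) {
    out$flags <- c(out$flags, "ic50_at_bound")
  }
  out
}

#' Normalize a melt curve to its temperature anchors
#'
#' Rescales the signal so the low-temperature anchor maps to 100% and the
#' high-temperature anchor to 0% (the thermal-shift convention of
#' normalizing to 25 degC = 100% and 74 degC = 0%).
#'
#' @param temperature Temperatures (degC), strictly increasing.
#' @param signal Measured signal (e.g. band intensity).
#' @param anchors Length-2 vector `c(low_T, high_T)`; both must be among
#'   the measured temperatures.
#' @return data.frame with `temperature` and `percent`.
#' @export
normalize_melt_curve <- function(temperature, signal,
                                 anchors = c(25, 74)) {
  stopifnot(length(temperature) == length(signal))
  if (is.unsorted(temperature, strictly = TRUE)) {
    stop("temperatures must be strictly increasing")
  }
  i_lo <- match(anchors[1L], temperature)
  i_hi <- match(anchors[2L], temperature)
  if (is.na(i_lo) || is.na(i_hi)) {
    stop("anchor temperature not measured: ",
         paste(anchors[c(is.na(i_lo), is.na(i_hi))], collapse = ", "))
  }
  s_lo <- signal[i_lo]; s_hi <- signal[i_hi]
  if (s_lo == s_hi) stop("anchor signals equal; no dynamic range")
  data.frame(temperature = temperature,
             percent = 100 * (signal - s_hi) / (s_lo - s_hi))
}

#' Normalize and fit a thermal-shift melt curve
#'
#' After anchor normalization ([normalize_melt_curve()]) a two-state
#' Boltzmann sigmoid `f(T) = baseline + amplitude / (1 + exp((T - Tm) /
#' k))` is fitted; `Tm` is the inflection (melting) temperature and `k`
#' the transition slope (degC). The amplitude and baseline are left free
#' (started at 100 and 0): anchor normalization maps the measured anchor
#' signals, not the sigmoid's asymptotes, onto 100%/0%, so the normalized
#' curve is an affine image of the underlying sigmoid — and the inflection
#' temperature is invariant under that affine map, which makes `Tm`
#' recovery exact on noiseless data. A melt that rises with temperature
#' beyond noise triggers a warning.
#'
#' @inheritParams normalize_melt_curve
#' @return A `"curve_fit"` with parameters `tm`, `k`, `amplitude`,
#'   `baseline`.
#' @export
fit_melt <- function(temperature, signal, anchors = c(25, 74)) {
  norm <- normalize_melt_curve(temperature, signal, anchors)
  if (any(diff(norm$percent) > 15)) {
    warning("melt curve is non-monotone beyond noise")
  }
  tm0 <- norm$temperature[which.min(abs(norm$percent - 50))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      percent ~ baseline + amplitude / (1 + exp((temperature - tm) / k)),
      data = norm,
      start = list(tm = tm0, k = 2, amplitude = 100, baseline = 0),
      lower = c(tm = min(temperature), k = 0.05, amplitude = 10,
                baseline = -50),
      upper = c(tm = max(temperature), k = 50, amplitude = 200,
                baseline = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(.failed_fit("boltzmann_melt",
                       c("tm", "k", "amplitude", "baseline"), norm,
                       "fit_failed"))
  }
  .extract_fit(fit, "boltzmann_melt", norm)
}

#' Melting-point shift between control and treated fits
#'
#' `Tm(control) - Tm(treated)`: a ligand that destabilizes the protein
#' (lowers its melting point) gives a positive shift.
#'
#' @param fit_control,fit_treated `"curve_fit"` objects from [fit_melt()].
#' @return Shift in degC.
#' @export
delta_tm <- function(fit_control, fit_treated) {
  unname(fit_control$parameters[["tm"]] - fit_treated$parameters[["tm"]])
}

#' Construct a dose-combination effect matrix
#'
#' @param doses_a,doses_b Dose vectors (each must contain 0, the
#'   single-agent/vehicle anchors).
#' @param effect Matrix of fraction loss-of-viability in `[0, 1]`, rows
#'   indexed by `doses_a`, columns by `doses_b`.
#' @return Object of class `"dose_matrix"`.
#' @export
dose_matrix <- function(doses_a, doses_b, effect) {
  effect <- as.matrix(effect)
  if (nrow(effect) != length(doses_a) || ncol(effect) != length(doses_b)) {
    stop("effect matrix dimensions must match the dose vectors")
  }
  if (!0 %in% doses_a || !0 %in% doses_b) {
    stop("dose grids must include 0 (single-agent marginals)")
  }
  if (any(effect < 0 | effect > 1)) {
    stop("effects must lie in [0, 1] (fraction loss of viability)")
  }
  dimnames(effect) <- list(doses_a, doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b, effect = effect),
            class = "dose_matrix")
}

#' Bliss independence synergy scores
#'
#' With `f_A(a)` and `f_B(b)` the single-agent effect marginals (the
#' zero-dose column and row), the Bliss-expected combination effect is
#' `f_A + f_B - f_A * f_B`; the per-cell synergy score is
#' `observed - expected` (positive = synergy). Cells with a zero dose on
#' either axis score 0 by construction. The summary score is the mean over
#' cells where both doses are nonzero. Scores are formula-exact; no
#' surface smoothing is applied.
#'
#' @param matrix A `"dose_matrix"`.
#' @return Object of class `"synergy_map"`: list with `expected`, `score`
#'   matrices and `summary_score`.
#' @export
bliss_synergy <- function(matrix) {
  stopifnot(inherits(matrix, "dose_matrix"))
  ia0 <- match(0, matrix$doses_a)
  ib0 <- match(0, matrix$doses_b)
  f_a <- matrix$effect[, ib0]
  f_b <- matrix$effect[ia0, ]
  expected <- outer(f_a, f_b, function(a, b) a + b - a * b)
  score <- matrix$effect - expected
  interior <- outer(matrix$doses_a > 0, matrix$doses_b > 0, `&`)
  structure(
    list(expected = expected, score = score,
         summary_score = mean(score[interior])),
    class = "synergy_map"
  )
}

#' @export
print.synergy_map <- function(x, ...) {
  cat("<synergy_map> mean score over combination cells: ",
      signif(x$summary_score, 4), "\n", sep = "")
  invisible(x)
}

#' Quantify SEC species percentages from elution-fraction intensities
#'
#' Implements the label-keyed window quantification: `% monomer =
#' (C6/2 + C7 + C8 + C9) / total * 100`, `% dimer = (C3 + C4 + C5 + C6/2)
#' / total * 100`, and (when the oligomer fractions are reported)
#' `% oligomer = (C2 + C1 + B1 + B2) / total * 100`, where `total` is the
#' summed intensity over all reported fractions and the shared boundary
#' fraction C6 is split half-and-half between monomer and dimer.
#'
#' @param profile Named numeric vector of fraction intensities, or a
#'   data.frame with columns `fraction`, `intensity`.
#' @param monomer,dimer,shared,oligomer Fraction labels for each window.
#' @return Named numeric vector with `monomer`, `dimer` and (if any
#'   oligomer fraction is present) `oligomer`, in percent.
#' @export
sec_quantify <- function(profile,
                         monomer = c("C7", "C8", "C9"),
                         dimer = c("C3", "C4", "C5"),
                         shared = "C6",
                         oligomer = c("C2", "C1", "B1", "B2")) {
  if (is.data.frame(profile)) {
    profile <- stats::setNames(profile$intensity, profile$fraction)
  }
  if (anyDuplicated(names(profile))) stop("duplicate fraction labels")
  if (any(profile < 0)) stop("negative fraction intensity")
  need <- c(monomer, dimer, shared)
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("missing fractions: ", paste(miss, collapse = ", "))
  total <- sum(profile)
  if (total <= 0) stop("zero total intensity")
  half_shared <- sum(profile[shared]) / 2
  out <- c(
    monomer = 100 * (half_shared + sum(profile[monomer])) / total,
    dimer = 100 * (half_shared + sum(profile[dimer])) / total
  )
  olig_present <- intersect(oligomer, names(profile))
  if (length(olig_present)) {
    out["oligomer"] <- 100 * sum(profile[olig_present]) / total
  }
  out
}

#' Calibrate molecular weight against SEC elution volume
#'
#' Linear fit of `log10(MW)` versus elution volume through the standards
#' (e.g. ovalbumin and carbonic anhydrase); the returned estimator
#' interpolates and extrapolates, flagging queries outside the standards'
#' volume range.
#'
#' @param volume Elution volumes of the standards (ml), distinct.
#' @param mw_kda Their molecular weights (kDa).
#' @return Object of class `"sec_calibration"`; use [predict_mw()] to
#'   query it.
#' @export
sec_mw_calibrate <- function(volume, mw_kda) {
  if (length(volume) < 2L) stop("need at least 2 standards")
  if (anyDuplicated(volume)) stop("duplicate standard volumes")
  fit <- stats::lm(log10(mw_kda) ~ volume,
                   data = data.frame(volume = volume, mw_kda = mw_kda))
  structure(list(fit = fit, range = range(volume)),
            class = "sec_calibration")
}

#' Estimate molecular weight from elution volume
#'
#' @param calibration A `"sec_calibration"` from [sec_mw_calibrate()].
#' @param volume Query elution volumes (ml).
#' @return data.frame with `volume`, `mw_kda` and `extrapolated`.
#' @export
predict_mw <- function(calibration, volume) {
  lg <- stats::predict(calibration$fit,
                       newdata = data.frame(volume = volume))
  data.frame(
    volume = volume,
    mw_kda = 10^as.numeric(lg),
    extrapolated = volume < calibration$range[1L] |
      volume > calibration$range[2L]
  )
}

#' Percent depolarization from fluorescence time courses
#'
#' Trapezoid AUCs over the common time grid are normalized between the
#' solvent-only control (0% depolarization) and the uncoupler positive
#' control (100%): `% = 100 * (AUC_dmso - AUC_sample) / (AUC_dmso -
#' AUC_cccp)`. Values outside `[0, 100]` are reported as-is but flagged in
#' the `"out_of_range"` attribute, never clipped. The statistic is
#' invariant to a common affine rescaling (gain/offset) of all traces.
#'
#' @param time Common time grid (min), >= 2 points.
#' @param sample Numeric vector (one trace) or matrix with one row per
#'   sample trace.
#' @param dmso,cccp Control traces on the same grid.
#' @return Numeric vector of percent depolarization per sample, with an
#'   `"out_of_range"` logical attribute.
#' @export
depolarization_percent <- function(time, sample, dmso, cccp) {
  if (length(time) < 2L) stop("need at least 2 time points")
  if (is.null(dim(sample))) sample <- matrix(sample, nrow = 1L)
  if (ncol(sample) != length(time) || length(dmso) != length(time) ||
      length(cccp) != length(time)) {
    stop("all traces must share the common time grid")
  }
  auc <- function(y) pracma::trapz(time, y)
  a_dmso <- auc(dmso)
  a_cccp <- auc(cccp)
  if (a_dmso == a_cccp) stop("DMSO and CCCP AUCs equal; no dynamic range")
  pct <- apply(sample, 1L, function(y) {
    100 * (a_dmso - auc(y)) / (a_dmso - a_cccp)
  })
  attr(pct, "out_of_range") <- pct < 0 | pct > 100
  pct
}
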