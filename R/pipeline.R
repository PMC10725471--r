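# Orchestration: run every stage of the synthetic end-to-end workflow from
# one config, write per-stage outputs and a consolidated report, and derive
# the headline summary numbers (fold-IC50 ratio, percent area change,
# delta-Tm, K_D table).

#' Default pipeline configuration
#'
#' A nested list of every stage's parameters with no hidden defaults; edit
#' any entry (or supply a YAML file with the same shape to
#' [run_pipeline()]) to change the workflow. Stage entries mirror the
#' generator/analysis pairs: `csp`, `ensemble`, `isotherm`, `melt`,
#' `synergy`, `sec`, `depolarization`, `screen`.
#'
#' @param seed Global seed; each stage derives its own sub-seed from it.
#' @return Named list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    csp = list(n_residues = 150L, planted = c(21L, 22L, 24L, 28L, 134L,
                                              145L),
               offset_H = 0.025, offset_N = 0.125,
               noise_sd_H = 0.005, noise_sd_N = 0.025),
    ensemble = list(n_frames = 200L, base_amplitude = 0.05,
                    area_percent = 9),
    isotherm = list(kd = 560, n_points = 12L, noise_cv = 0.03),
    melt = list(tm_control = 62, delta_tm = 4.5, k = 2, noise_cv = 0.02),
    synergy = list(delta = 0.15, noise_sd = 0.02),
    sec = list(dimer_fraction = 0.7),
    depolarization = list(true_percent = c(25, 50, 75)),
    screen = list(n_active = 5L, n_decoy = 45L, jitter = 0.1,
                  top_k = 10L)
  )
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147483647)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates every synthetic input at the configured truth values, runs
#' the corresponding analysis stage, writes per-stage TSV/JSON outputs
#' under `outdir`, and returns (and writes) a consolidated report whose
#' summary numbers each name their source stage. Identical config and
#' seed give identical numeric outputs.
#'
#' @param config A config list ([default_pipeline_config()]) or the path
#'   to a YAML file with the same shape.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The report, invisibly: a list with one element per stage and a
#'   `summary` data.frame of derived numbers.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = tempfile("baxdm_run_"), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  for (nm in names(base)) {
    if (is.null(config[[nm]])) {
      stop("config error: missing section '", nm, "'")
    }
  }
  say <- function(...) if (!quiet) message(...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list(config = config, outdir = outdir)

  say("stage csp")
  pk <- do.call(sim_peak_lists, c(config$csp,
                                  list(seed = stage_seed(seed, 1L))))
  csp <- classify_csp(compute_csp(pk$ref, pk$bound))
  regions <- map_to_regions(csp, bax_helix_regions())
  utils::write.table(regions$assignments, file.path(outdir, "csp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$csp <- list(
    thresholds = attr(csp, "thresholds"),
    n_significant = sum(csp$class %in% c("significant",
                                         "highly_significant")),
    region_counts = regions$summary,
    source = "csp.tsv"
  )

  say("stage ensemble")
  fold <- build_toy_fold(ca_only = TRUE)
  ens_cfg <- config$ensemble
  apo <- sim_ensemble(fold, n_frames = ens_cfg$n_frames,
                      base_amplitude = ens_cfg$base_amplitude,
                      seed = stage_seed(seed, 2L))
  bound <- sim_ensemble(fold, n_frames = ens_cfg$n_frames,
                        base_amplitude = ens_cfg$base_amplitude,
                        area_percent = ens_cfg$area_percent,
                        seed = stage_seed(seed, 3L))
  area_apo <- canonical_site_area(apo$ensemble)
  area_bound <- canonical_site_area(bound$ensemble)
  drmsf <- delta_rmsf(rmsf_per_residue(bound$ensemble),
                      rmsf_per_residue(apo$ensemble))
  utils::write.table(
    data.frame(frame = seq_along(area_apo$series),
               area_apo = area_apo$series,
               area_bound = area_bound$series),
    file.path(outdir, "area_series.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  report$ensemble <- list(
    area_mean_apo = area_apo$mean,
    area_mean_bound = area_bound$mean,
    area_percent_change = area_percent_change(area_apo$mean,
                                              area_bound$mean),
    mean_abs_delta_rmsf = mean(abs(drmsf)),
    source = "area_series.tsv"
  )

  say("stage isotherm")
  iso <- do.call(sim_isotherm, c(config$isotherm,
                                 list(seed = stage_seed(seed, 4L))))
  fit_iso <- fit_one_site(iso$concentration, iso$response)
  report$isotherm <- list(kd = unname(fit_iso$parameters[["kd"]]),
                          kd_truth = iso$truth$kd,
                          converged = fit_iso$converged,
                          source = "isotherm_fit.json")

  say("stage melt")
  mc <- do.call(sim_melt_curves, c(config$melt,
                                   list(seed = stage_seed(seed, 5L))))
  fit_ctrl <- fit_melt(mc$control$temperature, mc$control$signal)
  fit_trt <- fit_melt(mc$treated$temperature, mc$treated$signal)
  report$melt <- list(tm_control = unname(fit_ctrl$parameters[["tm"]]),
                      tm_treated = unname(fit_trt$parameters[["tm"]]),
                      delta_tm = delta_tm(fit_ctrl, fit_trt),
                      delta_tm_truth = mc$truth$delta_tm,
                      source = "melt_fit.json")

  say("stage synergy")
  dm <- do.call(sim_dose_matrix, c(config$synergy,
                                   list(seed = stage_seed(seed, 6L))))
  syn <- bliss_synergy(dm$matrix)
  utils::write.table(syn$score, file.path(outdir, "bliss_scores.tsv"),
                     sep = "\t", quote = FALSE)
  report$synergy <- list(summary_score = syn$summary_score,
                         delta_truth = dm$truth$delta,
                         source = "bliss_scores.tsv")

  say("stage sec")
  sec <- do.call(sim_sec_profile, c(config$sec,
                                    list(seed = stage_seed(seed, 7L))))
  pct <- sec_quantify(sec$profile)
  utils::write.table(sec$profile, file.path(outdir, "sec_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$sec <- list(percent = as.list(pct),
                     dimer_fraction_truth = sec$truth$dimer_fraction,
                     source = "sec_profile.tsv")

  say("stage depolarization")
  dep <- do.call(sim_depolarization,
                 c(config$depolarization,
                   list(seed = stage_seed(seed, 8L))))
  dep_pct <- depolarization_percent(dep$time, dep$sample, dep$dmso,
                                    dep$cccp)
  report$depolarization <- list(percent = as.numeric(dep_pct),
                                truth = dep$truth$true_percent,
                                source = "report.json")

  say("stage screen")
  model <- build_pharmacophore(build_toy_fold())
  lib <- do.call(sim_conformer_library,
                 c(list(model = model), config$screen[
                   setdiff(names(config$screen), "top_k")],
                   list(seed = stage_seed(seed, 9L))))
  hits <- screen_library(model, lib$conformers,
                         top_k = config$screen$top_k)
  utils::write.table(hits, file.path(outdir, "screen_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_active <- config$screen$n_active
  top_ids <- utils::head(hits$ligand_id, n_active)
  report$screen <- list(
    n_passed = sum(hits$passed),
    top_k_are_planted_actives =
      all(top_ids %in% lib$truth$id[lib$truth$active]),
    source = "screen_hits.tsv"
  )

  report$summary <- derive_headline_numbers(
    areas = c(apo = report$ensemble$area_mean_apo,
              bound = report$ensemble$area_mean_bound),
    delta_tm = report$melt$delta_tm,
    kd = c(fitted = report$isotherm$kd)
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("report written to ", file.path(outdir, "report.json"))
  invisible(report)
}

#' Derive headline summary numbers
#'
#' Computes the derived readouts that summarize a full analysis: the
#' fold-ratio of two IC50s (reported raw and rounded to the nearest
#' integer), the percent change between two mean canonical-site areas,
#' the melting-point shift, and any K_D values, as one tidy table.
#'
#' @param ic50 Optional length-2 named vector `c(resistant, sensitive)`
#'   (nM); the fold ratio is `resistant / sensitive`.
#' @param areas Optional length-2 named vector `c(apo, bound)` (square
#'   Angstrom).
#' @param delta_tm Optional melting-point shift (degC).
#' @param kd Optional named vector of dissociation constants (nM).
#' @return data.frame with columns `quantity`, `value`, `rounded`.
#' @export
derive_headline_numbers <- function(ic50 = NULL, areas = NULL,
                                    delta_tm = NULL, kd = NULL) {
  rows <- list()
  add <- function(quantity, value, rounded = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, value = value, rounded = rounded,
      stringsAsFactors = FALSE)
  }
  if (!is.null(ic50)) {
    if (length(ic50) != 2L) stop("ic50 must hold two values")
    fold <- unname(ic50[1L] / ic50[2L])
    add("ic50_fold_ratio", fold, round(fold))
  }
  if (!is.null(areas)) {
    if (length(areas) != 2L) stop("areas must hold two values")
    pc <- area_percent_change(unname(areas[1L]), unname(areas[2L]))
    add("area_percent_change", pc, round(pc))
  }
  if (!is.null(delta_tm)) {
    add("delta_tm_C", delta_tm, round(delta_tm, 1))
  }
  if (!is.null(kd)) {
    for (nm in names(kd)) {
      add(paste0("kd_nM_", nm), unname(kd[[nm]]), round(unname(kd[[nm]])))
    }
  }
  if (length(rows) == 0L) stop("no inputs supplied")
  do.call(rbind, rows)
}
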