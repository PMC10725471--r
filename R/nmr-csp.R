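# HSQC chemical-shift-perturbation analysis: weighted per-residue CSPs
# between a reference (free) and a ligand-bound peak list, significance
# classification against mean + 0.5/1 s.d. thresholds, and per-region
# summaries.

#' Read an HSQC peak list from TSV
#'
#' Expected columns: `residue`, `delta_H_ppm`, `delta_N_ppm` (one row per
#' assigned backbone amide).
#'
#' @param file Path to the TSV file.
#' @param label Optional label stored as an attribute.
#' @return data.frame of class `"peak_list"`.
#' @export
read_peak_list <- function(file, label = basename(file)) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  peak_list(tab, label = label)
}

#' Construct a peak list
#'
#' @param x data.frame with columns `residue`, `delta_H_ppm`,
#'   `delta_N_ppm`.
#' @param label Optional label.
#' @return data.frame of class `"peak_list"`.
#' @export
peak_list <- function(x, label = NULL) {
  need <- c("residue", "delta_H_ppm", "delta_N_ppm")
  if (!all(need %in% names(x))) {
    stop("peak list needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$residue)) stop("duplicate residue in peak list")
  if (any(!is.finite(x$delta_H_ppm)) || any(!is.finite(x$delta_N_ppm))) {
    stop("non-finite chemical shift in peak list")
  }
  x <- as.data.frame(x)[, need]
  attr(x, "label") <- label
  class(x) <- c("peak_list", "data.frame")
  x
}

#' Per-residue chemical-shift perturbations
#'
#' For every residue present in both lists the weighted CSP is
#' `overall_scale * sqrt(ddH^2 + (nitrogen_scale * ddN)^2)` (defaults give
#' `sqrt(ddH^2 + (ddN/5)^2) / 2`, in ppm). Residues present in only one
#' list — prolines, overlapped or missing peaks — get class `"absent"` and
#' an undefined CSP; they carry no bar in a CSP plot and are excluded from
#' the significance statistics. The common alternative convention
#' `sqrt((ddH^2 + (ddN/5)^2) / 2)` is one parameter change away
#' (`overall_scale = 1, nitrogen_scale = 1/5`, then square-root weights);
#' the literal scale-outside-the-radical form is the default.
#'
#' @param ref,bound Peak lists ([peak_list()]) for the free and bound
#'   states.
#' @param nitrogen_scale Weight on the nitrogen shift change (default 1/5).
#' @param overall_scale Overall scale outside the radical (default 1/2).
#' @return data.frame of class `"csp_table"` with columns `residue`,
#'   `delta_dH`, `delta_dN`, `csp`, `class` (`"absent"` or `NA` until
#'   classified by [classify_csp()]).
#' @export
compute_csp <- function(ref, bound, nitrogen_scale = 1 / 5,
                        overall_scale = 1 / 2) {
  ref <- peak_list(ref, attr(ref, "label"))
  bound <- peak_list(bound, attr(bound, "label"))
  residues <- sort(union(ref$residue, bound$residue))
  common <- intersect(ref$residue, bound$residue)
  if (length(common) == 0L) {
    stop("peak lists share no residues; nothing to compare")
  }
  ir <- match(residues, ref$residue)
  ib <- match(residues, bound$residue)
  ddH <- bound$delta_H_ppm[ib] - ref$delta_H_ppm[ir]
  ddN <- bound$delta_N_ppm[ib] - ref$delta_N_ppm[ir]
  csp <- overall_scale * sqrt(ddH^2 + (nitrogen_scale * ddN)^2)
  absent <- is.na(ir) | is.na(ib)
  out <- data.frame(
    residue = residues,
    delta_dH = ifelse(absent, NA_real_, ddH),
    delta_dN = ifelse(absent, NA_real_, ddN),
    csp = ifelse(absent, NA_real_, csp),
    class = ifelse(absent, "absent", NA_character_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Classify CSP significance
#'
#' With `m` the mean and `s` the sample standard deviation (n - 1
#' denominator) of the CSPs over non-absent residues, a residue is
#' `highly_significant` when `csp > m + s`, `significant` when
#' `m + 0.5 s < csp <= m + s`, and `below` otherwise. The thresholds are
#' attached as the `"thresholds"` attribute.
#'
#' @param records A `"csp_table"` from [compute_csp()].
#' @return The table with `class` filled in.
#' @export
classify_csp <- function(records) {
  ok <- !is.na(records$csp)
  if (sum(ok) < 2L) {
    stop("need at least 2 measured residues to estimate the threshold")
  }
  m <- mean(records$csp[ok])
  s <- stats::sd(records$csp[ok])
  th_sig <- m + 0.5 * s
  th_high <- m + s
  cls <- records$class
  cls[ok] <- ifelse(records$csp[ok] > th_high, "highly_significant",
                    ifelse(records$csp[ok] > th_sig, "significant",
                           "below"))
  records$class <- cls
  attr(records, "thresholds") <- list(mean = m, sd = s,
                                      significant = th_sig,
                                      highly_significant = th_high)
  records
}

#' Define a structural region table
#'
#' @param region Character vector of labels (e.g. helix names).
#' @param start,end Inclusive residue ranges; ranges must not overlap.
#' @return data.frame of class `"region_table"`.
#' @export
region_table <- function(region, start, end) {
  if (anyDuplicated(region)) stop("duplicate region labels")
  if (any(end < start)) stop("region end before start")
  o <- order(start)
  if (any(start[o][-1L] <= end[o][-length(o)])) {
    stop("region ranges overlap")
  }
  out <- data.frame(region = region, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  class(out) <- c("region_table", "data.frame")
  out
}

#' Example helix region table for BAX
#'
#' Approximate boundaries of the nine helices of the inactive BAX fold,
#' intended as a documented example; region tables for real analyses
#' should be supplied from the structure's own helix annotations (see
#' [read_region_table()]).
#'
#' @return A `"region_table"` with labels a1..a9.
#' @export
bax_helix_regions <- function() {
  region_table(
    region = paste0("a", 1:9),
    start = c(16L, 54L, 73L, 89L, 107L, 130L, 150L, 160L, 169L),
    end = c(35L, 70L, 84L, 100L, 126L, 146L, 158L, 165L, 186L)
  )
}

#' Read/write a region table as YAML
#'
#' The YAML maps region labels to `[start, end]` residue ranges. The
#' example table of [bax_helix_regions()] ships as
#' `system.file("extdata", "bax_helix_regions.yaml", package = "baxdm")`.
#'
#' @param file Path to the YAML file.
#' @return A `"region_table"`.
#' @export
read_region_table <- function(file) {
  obj <- yaml::read_yaml(file)
  region_table(names(obj),
               vapply(obj, function(r) as.integer(r[[1L]]), integer(1)),
               vapply(obj, function(r) as.integer(r[[2L]]), integer(1)))
}

#' @param regions A `"region_table"`.
#' @rdname read_region_table
#' @export
write_region_table <- function(regions, file) {
  obj <- lapply(seq_len(nrow(regions)), function(i)
    c(regions$start[i], regions$end[i]))
  names(obj) <- regions$region
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' Summarize classified CSPs by structural region
#'
#' Every residue is assigned to the single region whose range contains it,
#' or to `"unassigned"`.
#'
#' @param records A classified `"csp_table"` ([classify_csp()]).
#' @param regions A `"region_table"`.
#' @return List with `assignments` (the records plus a `region` column)
#'   and `summary` (per-region counts of measured, significant and highly
#'   significant residues plus a comma-separated list of the significant
#'   ones).
#' @export
map_to_regions <- function(records, regions) {
  assign_one <- function(res) {
    hit <- which(regions$start <= res & res <= regions$end)
    if (length(hit) == 0L) "unassigned" else regions$region[hit[1L]]
  }
  reg <- vapply(records$residue, assign_one, character(1))
  records$region <- reg
  labels <- c(regions$region, "unassigned")
  summary <- do.call(rbind, lapply(labels, function(lab) {
    r <- records[records$region == lab, , drop = FALSE]
    sig <- r$residue[r$class %in% c("significant", "highly_significant")]
    data.frame(
      region = lab,
      n_measured = sum(!is.na(r$csp)),
      n_significant = sum(r$class == "significant", na.rm = TRUE),
      n_highly_significant = sum(r$class == "highly_significant",
                                 na.rm = TRUE),
      significant_residues = paste(sig, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  list(assignments = records, summary = summary)
}
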