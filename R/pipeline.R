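#' Run the full suppression-analysis pipeline on a scenario
#'
#' End-to-end orchestration of the four stages:
#' \enumerate{
#'   \item \strong{simulate} — [generate_scenario()]; with `out_dir` set the
#'     dataset is serialized to mzML + TSV + YAML and read back from disk, so
#'     the downstream stages consume exactly what a real run would.
#'   \item \strong{extract} — pooled per-window average spectra, peak picking
#'     with the height filter, per-scan trapezoidal integration
#'     ([extract_features()], [integrate_trace()]).
#'   \item \strong{segment} — per-trace exact l2 change-point detection and
#'     last-`n_last`-scan pulse summaries ([summarize_pulses()]). A trace
#'     whose pulses cannot be recovered (e.g. a feature fully suppressed into
#'     the noise at a high suppressor level) yields `NA` for that level, with
#'     a message; the failure is recorded, not repaired.
#'   \item \strong{doseresponse} — per-feature [dose_response_curve()]s,
#'     normalization to the control level and trend classification.
#' }
#' The run is deterministic given the scenario (which carries its seed).
#'
#' @param scenario A `sesi_scenario`.
#' @param out_dir Optional run directory; when given, all intermediates
#'   (mzML, truth, feature table, pulse summaries, curves, effective config)
#'   are written there.
#' @param min_height Peak-picking height filter in a.u. (default 1e4).
#' @param bound_fraction Height fraction for integration bounds
#'   (default 0.9).
#' @param n_last Trailing scans per pulse to average (default 10).
#' @return A list of class `sesi_run`: `scenario`, `truth`, `features`,
#'   `summaries` (long data frame: level x feature x pulse), `levels` (level
#'   table with suppressor ppm), `curves` (named list of `dose_response`),
#'   `classification` (data frame), and `dir`.
#' @export
run_pipeline <- function(scenario, out_dir = NULL, min_height = 1e4,
                         bound_fraction = 0.9, n_last = 10) {
  dataset <- generate_scenario(scenario)
  if (!is.null(out_dir)) {
    write_dataset_mzml(dataset, out_dir)
    dataset <- read_dataset_mzml(out_dir)
  }
  run <- process_dataset(dataset, min_height = min_height,
                         bound_fraction = bound_fraction, n_last = n_last)
  run$dir <- out_dir
  if (!is.null(out_dir)) write_run_tables(run, out_dir)
  run
}

#' Process an existing dataset (extract, segment, dose-response)
#'
#' The processing half of [run_pipeline()], applicable to any
#' `sesi_dataset` — freshly generated, or read back from an mzML run
#' directory with [read_dataset_mzml()].
#'
#' @param dataset A `sesi_dataset`.
#' @inheritParams run_pipeline
#' @return A `sesi_run` (see [run_pipeline()]).
#' @export
process_dataset <- function(dataset, min_height = 1e4, bound_fraction = 0.9,
                            n_last = 10) {
  stopifnot(inherits(dataset, "sesi_dataset"))
  scenario <- dataset$scenario
  level_scans <- lapply(dataset$levels, function(l) l$scans)
  levels_ppm <- vapply(dataset$levels, function(l) l$suppressor_ppm,
                       numeric(1))
  features <- extract_features(level_scans, min_height, bound_fraction)
  if (nrow(features) == 0L)
    stop("no peaks above the height filter", call. = FALSE)
  n_pulses <- scenario$program$n_pulses
  rows <- list()
  for (li in seq_along(level_scans)) {
    for (fi in seq_len(nrow(features))) {
      trace <- integrate_trace(level_scans[[li]], features[fi, ])
      summ <- tryCatch(
        suppressWarnings(summarize_pulses(trace, n_pulses, n_last)),
        error = function(e) {
          message(sprintf(
            "level %d (%.3g ppm), feature %.4f: %s", li, levels_ppm[li],
            features$apex_mz[fi], conditionMessage(e)))
          NULL
        })
      rows[[length(rows) + 1L]] <- data.frame(
        level = li, suppressor_ppm = levels_ppm[li],
        feature_mz = features$apex_mz[fi],
        mean_intensity = if (is.null(summ)) NA_real_ else
          attr(summ, "replicate_mean"),
        sem = if (is.null(summ)) NA_real_ else attr(summ, "replicate_sem"),
        pulse_means = if (is.null(summ)) NA_character_ else
          paste(signif(summ$mean_intensity, 8), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, rows)
  curves <- lapply(seq_len(nrow(features)), function(fi) {
    sub <- summaries[summaries$feature_mz == features$apex_mz[fi], ]
    dose_response_curve(sub$suppressor_ppm, sub$mean_intensity, sub$sem,
                        feature_id = sprintf("%.4f", features$apex_mz[fi]))
  })
  names(curves) <- vapply(curves, function(cv) cv$feature_id, character(1))
  curves <- lapply(curves, function(cv) {
    tryCatch(normalize_curve(cv), error = function(e) cv)
  })
  classification <- do.call(rbind, lapply(curves, function(cv) {
    cl <- tryCatch(classify_feature(cv),
                   error = function(e) list(label = NA_character_,
                                            rho = NA_real_))
    data.frame(feature_id = cv$feature_id, label = cl$label, rho = cl$rho,
               stringsAsFactors = FALSE)
  }))
  rownames(classification) <- NULL
  structure(list(scenario = scenario, truth = dataset$truth,
                 features = features, summaries = summaries,
                 levels = data.frame(level = seq_along(levels_ppm),
                                     suppressor_ppm = levels_ppm),
                 curves = curves, classification = classification,
                 dir = NULL),
            class = "sesi_run")
}

write_run_tables <- function(run, dir) {
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$features, "features.tsv")
  wt(run$summaries, "pulse_summaries.tsv")
  curve_tab <- do.call(rbind, lapply(run$curves, function(cv)
    data.frame(feature_id = cv$feature_id,
               suppressor_ppm = cv$suppressor_ppm,
               mean_intensity = cv$mean_intensity, sem = cv$sem,
               normalized = if (is.null(cv$normalized)) NA_real_ else
                 cv$normalized,
               stringsAsFactors = FALSE)))
  wt(curve_tab, "curves.tsv")
  wt(run$classification, "classification.tsv")
  invisible(dir)
}

#' Match pipeline features to the generator's ground truth
#'
#' Joins picked features to simulated compounds by m/z proximity.
#'
#' @param run A `sesi_run`.
#' @param tol m/z matching tolerance in Th (default 0.01).
#' @return `run$features` with a `compound` column (`NA` where unmatched).
#' @export
match_features_truth <- function(run, tol = 0.01) {
  truth1 <- run$truth[run$truth$level == 1, ]
  feats <- run$features
  feats$compound <- vapply(feats$apex_mz, function(m) {
    d <- abs(truth1$mz - m)
    if (min(d) <= tol) truth1$compound[which.min(d)] else NA_character_
  }, character(1))
  feats
}
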