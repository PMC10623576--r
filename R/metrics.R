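#' Normalized curves of the decreasing features of a run
#'
#' Selects the features a run classified as `decreasing` (the condensate
#' volatiles, as opposed to the suppressor's own increasing channels) and
#' returns their normalized dose-response curves.
#'
#' @param run A `sesi_run` from [run_pipeline()].
#' @return Named list of normalized `dose_response` curves.
#' @export
decreasing_curves <- function(run) {
  dec <- !is.na(run$classification$label) &
    run$classification$label == "decreasing"
  run$curves[dec]
}

#' Fractional losses of a set of curves at one suppressor concentration
#'
#' @param curves List of `dose_response` curves.
#' @param ppm Query concentration (interpolated log-linearly).
#' @return Numeric vector of losses in percent; `NA` where a curve cannot be
#'   evaluated at `ppm`.
#' @export
feature_losses <- function(curves, ppm) {
  vapply(curves, function(cv)
    tryCatch(fractional_loss_at(cv, ppm), error = function(e) NA_real_),
    numeric(1))
}

#' Dose-response curve of a named compound in a run
#'
#' @param run A `sesi_run`.
#' @param name Compound name in the scenario's truth table.
#' @param tol m/z matching tolerance in Th.
#' @return The compound's `dose_response` curve.
#' @export
compound_curve <- function(run, name, tol = 0.01) {
  feats <- match_features_truth(run, tol)
  i <- which(feats$compound == name)
  if (length(i) != 1L)
    stop("compound not uniquely matched in the feature table: ", name,
         call. = FALSE)
  run$curves[[i]]
}

#' Dry-to-humid sensitivity ratio recovered end to end
#'
#' Simulates the same single-analyte delivery once dry and once humid,
#' extracts and segments both measurements, and takes the ratio of the
#' replicate mean pulse intensities.
#'
#' @param seed Integer seed shared by both runs.
#' @param ppm Delivered concentration (default 1.1e-2, far below the dry
#'   suppression scale).
#' @return The dimensionless dry/humid intensity ratio.
#' @export
sensitivity_ratio <- function(seed = 1L, ppm = 1.1e-2) {
  mean_int <- function(condition) {
    # a single-level scenario has no control; normalization is irrelevant
    # here, only the raw replicate mean is used
    run <- suppressMessages(suppressWarnings(
      run_pipeline(scenario_sensitivity(condition, seed = seed, ppm = ppm))))
    run$summaries$mean_intensity[1]
  }
  mean_int("dry") / mean_int("humid")
}
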