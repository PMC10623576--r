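#' Construct a dose-response curve
#'
#' Feature intensity as a function of the suppressor gas-phase concentration.
#' Levels must be strictly increasing with the zero-suppressor control (if
#' any) first.
#'
#' @param suppressor_ppm Suppressor levels in ppm (0 = control).
#' @param mean_intensity Mean feature intensity per level (a.u.); `NA` marks
#'   a level where the feature could not be quantified.
#' @param sem Standard error per level (optional).
#' @param feature_id Identifier, conventionally the apex m/z.
#' @return An object of class `dose_response`.
#' @export
dose_response_curve <- function(suppressor_ppm, mean_intensity, sem = NULL,
                                feature_id = NA) {
  stopifnot(length(suppressor_ppm) == length(mean_intensity))
  if (is.null(sem)) sem <- rep(NA_real_, length(suppressor_ppm))
  o <- order(suppressor_ppm)
  ppm <- suppressor_ppm[o]
  if (anyDuplicated(ppm)) stop("duplicate suppressor levels", call. = FALSE)
  structure(list(feature_id = feature_id, suppressor_ppm = ppm,
                 mean_intensity = mean_intensity[o], sem = sem[o],
                 normalized = NULL, normalized_sem = NULL),
            class = "dose_response")
}

#' Normalize a dose-response curve to its control level
#'
#' Divides every level by the mean intensity of the zero-suppressor control,
#' so the control maps to 1; errors are scaled by the same ratio. When the
#' curve has no control level, the lowest concentration level is used as the
#' reference, with a warning.
#'
#' @param curve A [dose_response_curve()].
#' @return The curve with `normalized` (and `normalized_sem`) filled in.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "dose_response"))
  i <- which(curve$suppressor_ppm == 0)
  if (length(i) == 0L) {
    warning("no control level; normalizing to the lowest concentration")
    i <- 1L
  }
  ref <- curve$mean_intensity[i]
  if (!is.finite(ref) || ref <= 0)
    stop("control level mean must be positive to normalize", call. = FALSE)
  curve$normalized <- curve$mean_intensity / ref
  curve$normalized_sem <- curve$sem / ref
  curve
}

#' Classify a feature's trend along the suppressor ladder
#'
#' Spearman rank correlation of intensity against log10 suppressor
#' concentration over the nonzero levels: at or above `+rho_threshold` the
#' feature is `increasing`, at or below `-rho_threshold` `decreasing`,
#' otherwise `flat`. Rank correlation is scale invariant, so raw and
#' normalized intensities give the same label. An undefined correlation
#' (all-tied intensities) yields `flat` with a warning.
#'
#' @param curve A [dose_response_curve()] with at least 4 nonzero levels.
#' @param rho_threshold Classification threshold (default 0.8).
#' @return A list with `label` and `rho`.
#' @export
classify_feature <- function(curve, rho_threshold = 0.8) {
  stopifnot(inherits(curve, "dose_response"))
  nz <- curve$suppressor_ppm > 0 & is.finite(curve$mean_intensity)
  if (sum(nz) < 4L)
    stop("need at least 4 quantified nonzero levels to classify",
         call. = FALSE)
  x <- log10(curve$suppressor_ppm[nz])
  y <- curve$mean_intensity[nz]
  if (stats::sd(y) == 0) {
    warning("all intensities tied; rank correlation undefined")
    return(list(label = "flat", rho = NA_real_))
  }
  rho <- stats::cor(x, y, method = "spearman")
  label <- if (rho >= rho_threshold) "increasing"
  else if (rho <= -rho_threshold) "decreasing"
  else "flat"
  list(label = label, rho = rho)
}

# normalized intensity at an arbitrary concentration, log-linear between
# measured nonzero levels
interp_normalized <- function(curve, ppm) {
  if (is.null(curve$normalized)) curve <- normalize_curve(curve)
  nz <- curve$suppressor_ppm > 0 & is.finite(curve$normalized)
  x <- log10(curve$suppressor_ppm[nz])
  y <- curve$normalized[nz]
  if (ppm <= 0 || log10(ppm) < min(x) - 1e-9 || log10(ppm) > max(x) + 1e-9)
    stop("requested concentration outside the measured range ",
         "(extrapolation refused)", call. = FALSE)
  stats::approx(x, y, xout = log10(ppm), rule = 2)$y
}

#' Fractional signal loss at a suppressor concentration
#'
#' `100 * (1 - normalized intensity)` at `ppm`, with the normalized curve
#' interpolated log-linearly between measured nonzero levels. Queries outside
#' the measured range are refused.
#'
#' @param curve A [dose_response_curve()].
#' @param ppm Query concentration in ppm.
#' @return Loss in percent (negative for an enhanced signal).
#' @export
fractional_loss_at <- function(curve, ppm) {
  100 * (1 - interp_normalized(curve, ppm))
}

#' Signal drop between two suppressor levels, in orders of magnitude
#'
#' `log10` of the intensity ratio between two measured levels. A
#' non-positive intensity at either level cannot be expressed in decades and
#' raises an error (the feature is below detection, "ND").
#'
#' @param curve A [dose_response_curve()].
#' @param ppm_lo,ppm_hi Two measured suppressor levels (matched to the
#'   curve's levels within 1e-6 relative).
#' @return Drop in decades (positive when the signal falls from `ppm_lo` to
#'   `ppm_hi`).
#' @export
orders_of_magnitude_drop <- function(curve, ppm_lo, ppm_hi) {
  stopifnot(inherits(curve, "dose_response"))
  find_level <- function(p) {
    i <- which(abs(curve$suppressor_ppm - p) <=
                 1e-6 * max(p, .Machine$double.eps))
    if (length(i) != 1L)
      stop("level ", p, " ppm is not a measured level", call. = FALSE)
    i
  }
  i <- find_level(ppm_lo)
  j <- find_level(ppm_hi)
  a <- curve$mean_intensity[i]
  b <- curve$mean_intensity[j]
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("intensity below detection at a queried level", call. = FALSE)
  log10(a) - log10(b)
}

#' Dilution factor needed to keep the signal loss below a bound
#'
#' Smallest dilution `d >= 1` such that the interpolated fractional loss at
#' `c_current / d` does not exceed `max_loss_percent`, rounded up to one
#' significant figure. Returns 1 when the loss at `c_current` is already
#' within the bound; errors if even the lowest measured level violates it.
#'
#' @param curve A [dose_response_curve()].
#' @param max_loss_percent Acceptable relative signal loss in percent.
#' @param c_current Operating suppressor concentration (default: the highest
#'   measured level).
#' @return Dilution factor (dimensionless).
#' @export
required_dilution <- function(curve, max_loss_percent,
                              c_current = NULL) {
  if (is.null(curve$normalized)) curve <- normalize_curve(curve)
  nz <- curve$suppressor_ppm[curve$suppressor_ppm > 0]
  if (is.null(c_current)) c_current <- max(nz)
  if (fractional_loss_at(curve, c_current) <= max_loss_percent) return(1)
  lo <- min(nz)
  if (fractional_loss_at(curve, lo) > max_loss_percent)
    stop("loss exceeds the bound over the whole measured range",
         call. = FALSE)
  # the loss is piecewise linear in log10(c); the smallest dilution
  # corresponds to the largest concentration c* <= c_current with
  # loss(c*) <= bound, solved exactly on the crossing segment
  x <- log10(nz[nz <= c_current * (1 + 1e-12)])
  l <- vapply(10^x, function(cc) fractional_loss_at(curve, cc), numeric(1))
  k <- max(which(l <= max_loss_percent))
  if (k == length(x)) {
    x_star <- log10(c_current) # loss at c_current itself exceeds the
    l_hi <- fractional_loss_at(curve, c_current) # bound (checked above)
    x_star <- x[k] + (max_loss_percent - l[k]) * (x_star - x[k]) /
      (l_hi - l[k])
  } else {
    x_star <- x[k] + (max_loss_percent - l[k]) * (x[k + 1] - x[k]) /
      (l[k + 1] - l[k])
  }
  d <- c_current / 10^x_star
  # round up to one significant figure
  m <- 10^floor(log10(d))
  ceiling(d / m - 1e-9) * m
}

#' Median normalized dose-response curve across features
#'
#' Per-level median of the normalized intensities of several curves sharing
#' the same ladder; the usual summary of "most features" in a condensate
#' panel.
#'
#' @param curves List of [dose_response_curve()]s (normalized on demand).
#' @return A normalized `dose_response` with the median curve.
#' @export
median_normalized_curve <- function(curves) {
  curves <- lapply(curves, function(cv)
    if (is.null(cv$normalized)) normalize_curve(cv) else cv)
  ppm <- curves[[1]]$suppressor_ppm
  for (cv in curves)
    if (!isTRUE(all.equal(cv$suppressor_ppm, ppm)))
      stop("curves do not share a common ladder", call. = FALSE)
  m <- vapply(curves, function(cv) cv$normalized, numeric(length(ppm)))
  med <- apply(matrix(m, nrow = length(ppm)), 1, stats::median, na.rm = TRUE)
  out <- dose_response_curve(ppm, med, feature_id = "median")
  out$normalized <- med
  out
}
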