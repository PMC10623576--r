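#' Average mass spectrum of a set of scans
#'
#' Pointwise mean over scans. Scans acquired on a common m/z grid (the usual
#' case within one SIM window) are averaged directly; otherwise all scans are
#' linearly resampled onto the densest grid first.
#'
#' @param scans Non-empty list of `sesi_spectrum` objects (normally all from
#'   one SIM window).
#' @return A `sesi_spectrum` with the mean intensities (time `NA`).
#' @export
average_spectrum <- function(scans) {
  if (length(scans) == 0L) stop("no scans to average", call. = FALSE)
  grids <- lapply(scans, function(s) s$mz)
  same <- all(vapply(grids, function(g)
    length(g) == length(grids[[1]]) && all(g == grids[[1]]), logical(1)))
  wid <- unique(vapply(scans, function(s) s$window_id, character(1)))
  wid <- if (length(wid) == 1L) wid else NA_character_
  if (same) {
    m <- vapply(scans, function(s) s$intensity,
                numeric(length(grids[[1]])))
    m <- matrix(m, nrow = length(grids[[1]]))
    return(new_spectrum(grids[[1]], rowMeans(m), window_id = wid))
  }
  dens <- grids[[which.max(vapply(grids, length, integer(1)))]]
  m <- vapply(scans, function(s)
    stats::approx(s$mz, s$intensity, xout = dens, rule = 2)$y,
    numeric(length(dens)))
  new_spectrum(dens, rowMeans(matrix(m, nrow = length(dens))),
               window_id = wid)
}

#' Integration bounds of a peak at a fraction of its apex height
#'
#' Walks outward from a local maximum to the nearest m/z on each side where
#' the intensity first falls below `fraction * apex_height`, interpolating
#' linearly between grid points. If a side never crosses the threshold
#' before the spectrum edge, the bound is truncated at the edge with a
#' warning.
#'
#' @param spectrum A `sesi_spectrum`.
#' @param apex_index Index of the apex (must be a local maximum).
#' @param fraction Height fraction defining the bounds (default 0.9; for a
#'   Gaussian peak this gives a width of \eqn{2\sigma\sqrt{2\ln(1/0.9)}}).
#' @return Numeric vector `c(lower_mz, upper_mz)`.
#' @export
peak_bounds_at_fraction <- function(spectrum, apex_index, fraction = 0.9) {
  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(y)
  if (apex_index < 1 || apex_index > n)
    stop("apex_index out of range", call. = FALSE)
  if ((apex_index > 1 && y[apex_index] < y[apex_index - 1]) ||
      (apex_index < n && y[apex_index] < y[apex_index + 1]))
    stop("apex_index is not a local maximum", call. = FALSE)
  thr <- fraction * y[apex_index]
  cross <- function(i_in, i_out) {
    # linear interpolation of the crossing between grid points
    mz[i_out] + (mz[i_in] - mz[i_out]) *
      (thr - y[i_out]) / (y[i_in] - y[i_out])
  }
  below_l <- which(y[seq_len(apex_index - 1)] < thr)
  if (length(below_l)) {
    j <- max(below_l)
    lower <- cross(j + 1L, j)
  } else {
    warning("peak truncated at lower spectrum edge")
    lower <- mz[1]
  }
  above <- seq(apex_index + 1L, length.out = n - apex_index)
  below_r <- above[y[above] < thr]
  if (length(below_r)) {
    j <- min(below_r)
    upper <- cross(j - 1L, j)
  } else {
    warning("peak truncated at upper spectrum edge")
    upper <- mz[n]
  }
  c(lower, upper)
}

#' Pick peaks in a spectrum with a height filter
#'
#' Local maxima whose apex height reaches `min_height`, each with
#' integration bounds at `bound_fraction` of the apex height. Peaks are
#' returned sorted by m/z; an empty data frame is a valid result.
#'
#' @param spectrum A `sesi_spectrum` (typically an average spectrum).
#' @param min_height Apex height filter in a.u. (default 1e4).
#' @param bound_fraction Height fraction for the bounds (default 0.9).
#' @return Data frame with columns `apex_mz`, `apex_height`, `lower_mz`,
#'   `upper_mz` and `window_id`.
#' @export
pick_peaks <- function(spectrum, min_height = 1e4, bound_fraction = 0.9) {
  y <- spectrum$intensity
  n <- length(y)
  empty <- data.frame(apex_mz = numeric(0), apex_height = numeric(0),
                      lower_mz = numeric(0), upper_mz = numeric(0),
                      window_id = character(0), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  mid <- 2:(n - 1L)
  is_max <- y[mid] > y[mid - 1L] & y[mid] >= y[mid + 1L] &
    y[mid] >= min_height
  idx <- mid[is_max]
  if (!length(idx)) return(empty)
  rows <- lapply(idx, function(i) {
    b <- peak_bounds_at_fraction(spectrum, i, bound_fraction)
    data.frame(apex_mz = spectrum$mz[i], apex_height = y[i],
               lower_mz = b[1], upper_mz = b[2],
               window_id = spectrum$window_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$apex_mz), , drop = FALSE]
}

# trapezoidal integral of a spectrum over [lo, hi], with linearly
# interpolated endpoint ordinates
trapezoid_between <- function(mz, y, lo, hi) {
  inside <- mz > lo & mz < hi
  xi <- c(lo, mz[inside], hi)
  yi <- c(stats::approx(mz, y, xout = lo, rule = 2)$y,
          y[inside],
          stats::approx(mz, y, xout = hi, rule = 2)$y)
  sum(diff(xi) * (utils::head(yi, -1) + utils::tail(yi, -1)) / 2)
}

#' Time trace of one peak across a measurement
#'
#' Per-scan trapezoidal integral of the intensity over the peak's
#' integration bounds. Scans from SIM windows that do not cover the peak are
#' skipped, so the trace's time axis is the window's own scan schedule.
#'
#' @param scans List of `sesi_spectrum` objects (all windows; the relevant
#'   ones are selected by m/z coverage).
#' @param peak One row of the data frame from [pick_peaks()].
#' @return A list of class `time_trace` with `times`, `intensities` and
#'   `peak`.
#' @export
integrate_trace <- function(scans, peak) {
  covers <- vapply(scans, function(s)
    s$mz[1] <= peak$lower_mz && s$mz[length(s$mz)] >= peak$upper_mz,
    logical(1))
  if (!any(covers))
    stop("no scan covers the peak's m/z window", call. = FALSE)
  sel <- scans[covers]
  times <- vapply(sel, function(s) s$time, numeric(1))
  ints <- vapply(sel, function(s)
    trapezoid_between(s$mz, s$intensity, peak$lower_mz, peak$upper_mz),
    numeric(1))
  o <- order(times)
  structure(list(times = times[o], intensities = ints[o], peak = peak),
            class = "time_trace")
}

#' Group scans by SIM window and stitch a composite spectrum
#'
#' Splits cycled-SIM scans into per-window groups, averages each group, and
#' concatenates the per-window averages into one composite spectrum.
#' Overlapping m/z ranges are resolved by keeping, at each m/z, the window
#' whose centre is nearest.
#'
#' @param scans List of `sesi_spectrum` objects with window tags.
#' @return A list with `groups` (named list of scan lists), `averages`
#'   (named list of per-window average spectra) and `composite` (a single
#'   `sesi_spectrum`).
#' @export
stitch_sim_windows <- function(scans) {
  tags <- vapply(scans, function(s) s$window_id, character(1))
  if (anyNA(tags)) stop("scans without window tags", call. = FALSE)
  groups <- split(scans, tags)
  averages <- lapply(groups, average_spectrum)
  centers <- vapply(averages, function(a) mean(range(a$mz)), numeric(1))
  mz_all <- unname(unlist(lapply(averages, function(a) a$mz)))
  int_all <- unname(unlist(lapply(averages, function(a) a$intensity)))
  from <- rep(seq_along(averages), vapply(averages, function(a)
    length(a$mz), integer(1)))
  # overlap resolution: keep the point whose window centre is nearest
  nearest <- vapply(mz_all, function(m) which.min(abs(centers - m)),
                    integer(1))
  keep <- nearest == from
  o <- order(mz_all[keep])
  mz_o <- mz_all[keep][o]
  int_o <- int_all[keep][o]
  dup <- c(FALSE, diff(mz_o) == 0)
  list(groups = groups, averages = averages,
       composite = new_spectrum(mz_o[!dup], int_o[!dup]))
}

#' Pick features on the pooled average spectra of a whole run
#'
#' Pools the scans of every concentration level, averages per SIM window and
#' picks peaks on each window average. Picking on the pooled average (rather
#' than per level) keeps the feature list identical across levels, so
#' strongly suppressed levels are still traced at the positions where the
#' feature is seen in the run as a whole.
#'
#' @param level_scans List (one element per level) of lists of
#'   `sesi_spectrum`.
#' @param min_height Apex height filter (default 1e4).
#' @param bound_fraction Height fraction for integration bounds
#'   (default 0.9).
#' @return Data frame of peaks as from [pick_peaks()].
#' @export
extract_features <- function(level_scans, min_height = 1e4,
                             bound_fraction = 0.9) {
  all_scans <- unlist(level_scans, recursive = FALSE)
  tags <- vapply(all_scans, function(s) s$window_id, character(1))
  groups <- split(all_scans, tags)
  peaks <- lapply(groups, function(g)
    pick_peaks(average_spectrum(g), min_height, bound_fraction))
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out[order(out$apex_mz), , drop = FALSE]
}
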