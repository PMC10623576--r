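#' Exact least-squares change-point segmentation
#'
#' Finds the segmentation of a series into `n_changepoints + 1` contiguous
#' segments minimizing the total within-segment sum of squared deviations
#' from the segment means (the l2 cost), by exact dynamic programming in
#' O(K n^2). Ties are broken toward the earliest change-point indices.
#'
#' @param series Numeric vector.
#' @param n_changepoints Number of interior change points K;
#'   must be < `length(series)`.
#' @return An object of class `segmentation`: `changepoints` (indices of the
#'   last sample of each segment but the final one), `segments` (data frame
#'   `start`, `end`, `mean`) and `cost` (the optimal l2 cost).
#' @examples
#' changepoints_l2(c(0, 0, 0, 5, 5, 5), 1)$changepoints # 3
#' @export
changepoints_l2 <- function(series, n_changepoints) {
  y <- as.numeric(series)
  n <- length(y)
  K <- as.integer(n_changepoints)
  if (K < 0) stop("n_changepoints must be >= 0", call. = FALSE)
  if (K >= n)
    stop("n_changepoints must be smaller than the series length",
         call. = FALSE)
  if (K > 0 && stats::var(y) == 0)
    stop("degenerate input: constant series cannot be segmented",
         call. = FALSE)
  S <- c(0, cumsum(y))
  Q <- c(0, cumsum(y^2))
  # cost of segment (i+1)..j for vectors of i (0-based prefix indices)
  seg_cost <- function(i, j) {
    len <- j - i
    Q[j + 1] - Q[i + 1] - (S[j + 1] - S[i + 1])^2 / len
  }
  if (K == 0L) {
    seg <- data.frame(start = 1L, end = n, mean = mean(y))
    return(structure(list(changepoints = integer(0), segments = seg,
                          cost = seg_cost(0L, n)),
                     class = "segmentation"))
  }
  # D[k, j]: optimal cost of y[1..j] split into k+1 segments
  prev <- seg_cost(0L, seq_len(n))
  back <- matrix(NA_integer_, nrow = K, ncol = n)
  for (k in seq_len(K)) {
    cur <- rep(Inf, n)
    for (j in seq(k + 1L, n)) {
      i <- seq(k, j - 1L)                # last index of the previous part
      cand <- prev[i] + seg_cost(i, j)
      b <- which.min(cand)               # first minimum = earliest tie
      cur[j] <- cand[b]
      back[k, j] <- i[b]
    }
    prev <- cur
  }
  cps <- integer(K)
  j <- n
  for (k in rev(seq_len(K))) {
    cps[k] <- back[k, j]
    j <- cps[k]
  }
  bounds <- c(0L, cps, n)
  seg <- data.frame(
    start = utils::head(bounds, -1) + 1L,
    end = utils::tail(bounds, -1),
    mean = vapply(seq_len(K + 1), function(s)
      mean(y[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
  )
  structure(list(changepoints = cps, segments = seg, cost = prev[n]),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d change point(s), cost %.4g\n",
              length(x$changepoints), x$cost))
  print(x$segments)
  invisible(x)
}

#' Penalty-selected change-point segmentation
#'
#' Non-default alternative to fixing K from the experimental design: chooses
#' the number of change points minimizing `cost + penalty * K`, with a
#' BIC-like default penalty of `2 * sigma^2 * log(n)` where `sigma` is a
#' robust noise estimate from first differences.
#'
#' @inheritParams changepoints_l2
#' @param max_changepoints Largest K considered (default 10).
#' @param penalty Per-change-point penalty; `NULL` for the default.
#' @return A `segmentation`.
#' @export
changepoints_l2_penalized <- function(series, max_changepoints = 10,
                                      penalty = NULL) {
  y <- as.numeric(series)
  n <- length(y)
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(y)) / sqrt(2)
    penalty <- 2 * sigma^2 * log(n)
  }
  kmax <- min(max_changepoints, n - 1L)
  fits <- lapply(0:kmax, function(k) changepoints_l2(y, k))
  tot <- vapply(seq_along(fits), function(i)
    fits[[i]]$cost + penalty * (i - 1L), numeric(1))
  fits[[which.min(tot)]]
}

#' Extract the on-pulse segments of a segmentation
#'
#' On-segments are the segments whose mean exceeds the midpoint between the
#' smallest and largest segment means. The pulse count is part of the
#' experimental design, so a mismatch is surfaced as an error (condition
#' class `pulse_count_mismatch`), never silently repaired.
#'
#' @param segmentation A [changepoints_l2()] result.
#' @param expected_pulses Number of on-pulses the design prescribes
#'   (default 3).
#' @return The on-segment rows of `segmentation$segments`, with a
#'   `pulse_index` column.
#' @export
extract_pulses <- function(segmentation, expected_pulses = 3) {
  seg <- segmentation$segments
  mid <- (min(seg$mean) + max(seg$mean)) / 2
  on <- seg$mean > mid
  if (sum(on) != expected_pulses)
    stop(errorCondition(
      sprintf("expected %d on-pulses, found %d", expected_pulses, sum(on)),
      class = c("pulse_count_mismatch", "error")))
  out <- seg[on, , drop = FALSE]
  out$pulse_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mean and standard error of the last scans of a pulse
#'
#' The paper-style pulse summary: the mean of the final `n_last` samples of
#' an on-segment (the steady-state plateau after washout) with the standard
#' error of that mean. Segments shorter than `n_last` are summarized over
#' all their samples, with a warning.
#'
#' @param values Intensities of one on-segment, in scan order.
#' @param n_last Number of trailing scans to average (default 10).
#' @return Data frame with `mean_intensity`, `sem`, `n_scans_used`.
#' @examples
#' pulse_intensity(1:10)  # mean 5.5, sem ~0.957
#' @export
pulse_intensity <- function(values, n_last = 10) {
  if (n_last < 1) stop("n_last must be >= 1", call. = FALSE)
  if (length(values) < n_last) {
    warning(sprintf("segment has %d < %d scans; using all of them",
                    length(values), n_last))
    n_last <- length(values)
  }
  v <- utils::tail(values, n_last)
  sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  data.frame(mean_intensity = mean(v), sem = sem,
             n_scans_used = length(v))
}

#' Segment a time trace into pulses and summarize each
#'
#' Runs the full per-trace summary: exact l2 change-point detection with
#' `K = 2 * n_pulses` (two edges per pulse; the leading baseline supplies the
#' extra segment), extraction of the on-segments, and the last-`n_last`-scan
#' summary of each pulse. Alongside the per-pulse rows, the replicate-level
#' aggregate (mean of the pulse means and its standard error across pulses)
#' is attached as attributes `replicate_mean` and `replicate_sem`.
#'
#' @param trace A [integrate_trace()] result, or a numeric vector of
#'   intensities.
#' @param n_pulses Number of delivery pulses (default 3).
#' @param n_last Trailing scans per pulse to average (default 10).
#' @return Data frame with one row per pulse: `pulse_index`,
#'   `mean_intensity`, `sem`, `n_scans_used`, `start`, `end`.
#' @export
summarize_pulses <- function(trace, n_pulses = 3, n_last = 10) {
  y <- if (inherits(trace, "time_trace")) trace$intensities else
    as.numeric(trace)
  seg <- changepoints_l2(y, 2L * n_pulses)
  pulses <- extract_pulses(seg, n_pulses)
  rows <- lapply(seq_len(nrow(pulses)), function(i) {
    s <- pulse_intensity(y[pulses$start[i]:pulses$end[i]], n_last)
    cbind(data.frame(pulse_index = i), s,
          data.frame(start = pulses$start[i], end = pulses$end[i]))
  })
  out <- do.call(rbind, rows)
  attr(out, "replicate_mean") <- mean(out$mean_intensity)
  attr(out, "replicate_sem") <- stats::sd(out$mean_intensity) /
    sqrt(nrow(out))
  out
}
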