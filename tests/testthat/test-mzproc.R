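test_that("average spectrum is the pointwise mean", {
  s <- gaussian_spectrum()
  avg <- average_spectrum(list(s, s, s))
  expect_equal(avg$intensity, s$intensity)
  s3 <- new_spectrum(s$mz, 3 * s$intensity)
  expect_equal(average_spectrum(list(s, s3))$intensity, 2 * s$intensity)
  expect_error(average_spectrum(list()), "no scans")
  # averaging suppresses baseline noise as 1/sqrt(N)
  truth_apex <- 5e5
  scans <- withr::with_seed(8, lapply(1:100, function(i)
    synthesize_scan(100, truth_apex, gaussian_spectrum()$mz,
                    noise = list(baseline_sd = 300, cv = 0))))
  avg <- average_spectrum(scans)
  expect_lt(abs(max(avg$intensity) - truth_apex), 3 * 300 / sqrt(100))
})

test_that("peak picking applies the height filter to local maxima", {
  flat <- new_spectrum(seq(100, 101, by = 0.001), rep(0, 1001))
  expect_equal(nrow(pick_peaks(flat)), 0L)
  # just below the filter
  low <- gaussian_spectrum(height = 9.9e3)
  expect_equal(nrow(pick_peaks(low, min_height = 1e4)), 0L)
  # two well-separated peaks above the filter
  mz <- seq(99.5, 101.5, by = 2.5e-3)
  y <- 2e4 * exp(-((mz - 100)^2) / (2 * 0.01^2)) +
    8e4 * exp(-((mz - 101)^2) / (2 * 0.01^2))
  pk <- pick_peaks(new_spectrum(mz, y), min_height = 1e4)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$apex_mz, c(100, 101), tolerance = 2.5e-3 / 100)
  expect_true(all(pk$lower_mz < pk$apex_mz & pk$apex_mz < pk$upper_mz))
  # peak count is monotone non-increasing in the filter
  counts <- vapply(c(1e3, 1e4, 3e4, 1e5),
                   function(h) nrow(pick_peaks(new_spectrum(mz, y), h)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak bounds at a height fraction match the Gaussian closed form", {
  sigma <- 0.01
  step <- sigma / 4
  s <- gaussian_spectrum(center = 100, sigma = sigma, step = step)
  apex <- which.max(s$intensity)
  b <- peak_bounds_at_fraction(s, apex, fraction = 0.9)
  expect_equal(mean(b), 100, tolerance = 1e-9) # symmetric about the apex
  w <- 2 * sigma * sqrt(2 * log(1 / 0.9))
  expect_equal(b[2] - b[1], w, tolerance = step / w)
  expect_equal(b[2] - b[1], 9.18e-3, tolerance = 1e-2)
  # half height gives the FWHM
  b50 <- peak_bounds_at_fraction(s, apex, fraction = 0.5)
  expect_equal(b50[2] - b50[1], 2.3548 * sigma, tolerance = 5e-3)
  # closed-form agreement within one grid step for sigma >= 3 grid steps
  for (sp in sigma / c(3, 5, 8)) {
    ss <- gaussian_spectrum(center = 100, sigma = sigma, step = sp)
    bb <- peak_bounds_at_fraction(ss, which.max(ss$intensity), 0.9)
    expect_lt(abs((bb[2] - bb[1]) - w), sp)
  }
  # apex on the spectrum edge: truncated with a warning
  edge <- new_spectrum(seq(100, 100.05, by = step),
                       exp(-(seq(0, 0.05, by = step)^2) / (2 * sigma^2)))
  expect_warning(be <- peak_bounds_at_fraction(edge, 1, 0.9), "truncated")
  expect_equal(be[1], 100)
})

test_that("trace integration is trapezoidal over the peak bounds", {
  # all-zero scans give an all-zero trace
  mz <- seq(64, 66, by = 1e-3)
  zeros <- lapply(1:5, function(i)
    new_spectrum(mz, rep(0, length(mz)), time = i, window_id = "w"))
  peak <- data.frame(apex_mz = 65, apex_height = 1, lower_mz = 64.9,
                     upper_mz = 65.1, window_id = "w")
  tr <- integrate_trace(zeros, peak)
  expect_s3_class(tr, "time_trace")
  expect_equal(tr$intensities, rep(0, 5))
  expect_equal(tr$times, 1:5)
  # a rectangle of height h integrates to h * w per scan
  box <- lapply(1:3, function(i)
    new_spectrum(mz, ifelse(mz >= 64.5 & mz <= 65.5, 7, 7), time = i,
                 window_id = "w"))
  peak_box <- data.frame(apex_mz = 65, apex_height = 7, lower_mz = 64.8,
                         upper_mz = 65.2, window_id = "w")
  expect_equal(integrate_trace(box, peak_box)$intensities,
               rep(7 * 0.4, 3), tolerance = 1e-9)
  # scans not covering the bounds are refused
  far <- list(new_spectrum(seq(100, 101, by = 0.01), rep(0, 101),
                           time = 1, window_id = "v"))
  expect_error(integrate_trace(far, peak), "no scan covers")
})

test_that("noiseless traces follow the delivery profile after washout", {
  sc <- tiny_scenario(seed = 2, noise = list(baseline_sd = 0, cv = 0),
                      levels = c(0, 1.1e-2))
  ds <- generate_scenario(sc)
  scans <- ds$levels[[2]]$scans
  feats <- extract_features(list(scans), min_height = 1e3)
  expect_equal(nrow(feats), 2L)
  truth <- ds$truth[ds$truth$level == 2, ]
  # integrated steady intensity proportional to truth; the constant (mean
  # in-bounds height / apex) is shared across compounds once the
  # m/z-dependent bound width is divided out
  ratios <- vapply(seq_len(nrow(feats)), function(fi) {
    tr <- integrate_trace(scans, feats[fi, ])
    plateau <- mean(utils::tail(tr$intensities[tr$times < 18], 5))
    tru <- truth$steady_intensity[which.min(abs(truth$mz -
                                                  feats$apex_mz[fi]))]
    plateau / (tru * (feats$upper_mz[fi] - feats$lower_mz[fi]))
  }, numeric(1))
  expect_equal(ratios[1], ratios[2], tolerance = 0.01)
  # and the trace tracks the washout shape to 1% at the pulse end
  tr <- integrate_trace(scans, feats[2, ])
  prof <- delivery_profile(sc$program, 1, tr$times)
  sel <- tr$times >= 14 & tr$times < 18 # end of first pulse
  shape <- tr$intensities[sel] / max(tr$intensities) -
    prof[sel] / max(prof)
  expect_lt(max(abs(shape)), 0.01)
})

test_that("SIM windows group round-robin and stitch into one spectrum", {
  sc <- scenario_ternary("humid", seed = 3)
  sc$levels <- c(0, 2.7e-4) # two levels are enough for structure checks
  ds <- generate_scenario(sc)
  scans <- ds$levels[[2]]$scans
  st <- stitch_sim_windows(scans)
  expect_length(st$groups, 3L)
  counts <- vapply(st$groups, length, integer(1))
  expect_true(max(counts) - min(counts) <= 1) # round-robin split
  # composite preserves the per-window average apex heights
  for (w in names(st$averages)) {
    avg <- st$averages[[w]]
    apex <- which.max(avg$intensity)
    i <- which(st$composite$mz == avg$mz[apex])
    expect_length(i, 1L)
    expect_equal(st$composite$intensity[i], avg$intensity[apex])
  }
  # single window: identity grouping
  sb <- generate_scenario(tiny_scenario(levels = c(0, 0.011)))
  st1 <- stitch_sim_windows(sb$levels[[2]]$scans)
  expect_length(st1$groups, 1L)
  expect_equal(length(st1$groups[[1]]), length(sb$levels[[2]]$scans))
  # untagged scans are refused
  bad <- list(new_spectrum(1:3, c(0, 1, 0)))
  expect_error(stitch_sim_windows(bad), "window tags")
})
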