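test_that("delivery profile is a first-order pulse train", {
  # square wave in the zero-washout limit
  prog0 <- pulse_program(washout_time_constant = 0, lead_in = 10)
  t <- seq(0, program_duration(prog0) - 0.5, by = 0.5)
  y <- delivery_profile(prog0, 2, t)
  phases <- program_phases(prog0)
  on <- rep(FALSE, length(t))
  for (i in which(phases$on)) on[t >= phases$start[i] & t < phases$end[i]] <- TRUE
  expect_equal(y, ifelse(on, 2, 0))
  # tau -> infinity: never rises
  prog_inf <- pulse_program(washout_time_constant = 1e12)
  expect_equal(delivery_profile(prog_inf, 2, t), rep(0, length(t)),
               tolerance = 1e-9)
  # closed-form step response at the end of a 30 s pulse, tau = 5
  prog5 <- pulse_program(washout_time_constant = 5, lead_in = 0)
  expect_equal(delivery_profile(prog5, 1, 30 - 1e-9), 1 - exp(-6),
               tolerance = 1e-6)
  expect_error(delivery_profile(prog5, 1, c(3, 2, 1)), "increasing")
})

test_that("suppression factor realizes basicity-ordered competition", {
  p <- suppression_params()
  acetone <- get_compound("d6-acetone")
  acoh <- get_compound("d3-acoh")
  pyridine <- get_compound("pyridine")
  # empty mixture: no suppression
  expect_identical(suppression_factor(acoh, params = p,
                                      condition = "dry"), 1)
  # isotopologue symmetry at equal concentration
  f_ab <- suppression_factor(782.1, 782.1, 0.05, p, "dry")
  f_ba <- suppression_factor(782.1, 782.1, 0.05, p, "dry")
  expect_identical(f_ab, f_ba)
  # direct formula: pyridine vs acetone, dGB = 116, co-analyte at c50
  f <- suppression_factor(782.1, 898.1, p$c50_dry, p, "dry")
  expect_equal(f, (1 + exp(116 / 20))^(-2), tolerance = 1e-12)
  expect_equal(f, 9.05e-6, tolerance = 1e-2)
  # bounded in (0, 1] and monotone non-increasing in concentration
  cs <- c(0, 10^seq(-4, 1, by = 0.5))
  fs <- vapply(cs, function(cc)
    suppression_factor(acoh, acetone, cc, p, "dry"), numeric(1))
  expect_true(all(fs > 0 & fs <= 1))
  expect_true(all(diff(fs) <= 0))
  # induced loss is monotone in the co-analyte's basicity
  gbs <- c(700, 752.8, 782.1, 819, 898.1)
  loss <- vapply(gbs, function(g)
    1 - suppression_factor(752.8, g, 0.1, p, "humid"), numeric(1))
  expect_true(all(diff(loss) > 0))
  # humid conditions need more suppressor for the same loss
  expect_gt(suppression_factor(acoh, acetone, 0.1, p, "humid"),
            suppression_factor(acoh, acetone, 0.1, p, "dry"))
})

test_that("steady intensity is linear with a humidity sensitivity divisor", {
  p <- suppression_params()
  a <- get_compound("d6-acetone")
  expect_identical(steady_intensity(a, 0, params = p, condition = "dry"), 0)
  i1 <- steady_intensity(a, 1e-3, params = p, condition = "dry")
  i2 <- steady_intensity(a, 2e-3, params = p, condition = "dry")
  expect_equal(i2, 2 * i1)
  ih <- steady_intensity(a, 1e-3, params = p, condition = "humid")
  expect_equal(i1 / ih, p$humid_sensitivity_ratio)
})

test_that("synthesized scans place Gaussian peaks at the right width", {
  grid <- seq(199.99, 200.01, by = 1e-6)
  flat <- synthesize_scan(numeric(0), numeric(0), grid)
  expect_equal(flat$intensity, rep(0, length(grid)))
  scan <- synthesize_scan(200, 5e6, grid, resolution = 140000)
  expect_equal(scan$mz[which.max(scan$intensity)], 200,
               tolerance = 1e-6 / 2)
  expect_equal(max(scan$intensity), 5e6)
  # FWHM from the resolution model: m/z / R
  half <- scan$mz[scan$intensity >= 2.5e6]
  expect_equal(max(half) - min(half), 200 / 140000, tolerance = 2e-2)
  # fixed RNG state makes noisy scans reproducible
  s1 <- withr::with_seed(9, synthesize_scan(200, 5e6, grid,
                                            noise = list(baseline_sd = 100,
                                                         cv = 0.05)))
  s2 <- withr::with_seed(9, synthesize_scan(200, 5e6, grid,
                                            noise = list(baseline_sd = 100,
                                                         cv = 0.05)))
  expect_identical(s1$intensity, s2$intensity)
})

test_that("generated scenarios are deterministic with a written truth table", {
  sc <- tiny_scenario(seed = 21)
  d1 <- generate_scenario(sc)
  d2 <- generate_scenario(sc)
  expect_identical(d1$levels[[2]]$scans[[17]]$intensity,
                   d2$levels[[2]]$scans[[17]]$intensity)
  expect_identical(d1$truth, d2$truth)
  # truth suppression equals the model recomputed from the config
  p <- sc$params
  for (li in seq_along(sc$levels)) {
    tr <- d1$truth[d1$truth$level == li, ]
    f_acoh <- suppression_factor(752.8, 782.1, sc$levels[li], p, "dry")
    expect_equal(tr$suppression_factor[tr$compound == "d3-acoh"], f_acoh)
    expect_equal(tr$steady_intensity[tr$compound == "d3-acoh"],
                 sc$response_coefficient * 7e-4 * f_acoh)
  }
  # scan count: 3 pulses of 30+30 s at 1 scan/s plus lead-in
  full <- scenario_binary("dry", seed = 1)
  dur <- program_duration(full$program)
  expect_gte(dur / full$scan_period, 180)
  # delivered m/z must be covered by a SIM window
  bad <- tiny_scenario()
  bad$windows <- data.frame(lower = 100, upper = 101)
  expect_error(generate_scenario(bad), "outside all SIM windows")
})

test_that("mzML serialization round-trips scans and windows", {
  sc <- tiny_scenario(seed = 31, levels = c(0, 1.1e-2))
  ds <- generate_scenario(sc)
  dir <- withr::local_tempdir()
  write_dataset_mzml(ds, dir)
  expect_true(file.exists(file.path(dir, "level_01.mzML")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  back <- read_dataset_mzml(dir)
  expect_equal(length(back$levels), 2L)
  orig <- ds$levels[[2]]$scans
  got <- back$levels[[2]]$scans
  expect_equal(length(got), length(orig))
  i <- 25
  expect_equal(got[[i]]$mz, orig[[i]]$mz, tolerance = 1e-10)
  expect_equal(got[[i]]$intensity, orig[[i]]$intensity, tolerance = 1e-6)
  expect_equal(got[[i]]$time, orig[[i]]$time)
  expect_identical(got[[i]]$window_id, orig[[i]]$window_id)
  # regenerating with the same seed and re-serializing gives identical data
  dir2 <- withr::local_tempdir()
  write_dataset_mzml(generate_scenario(sc), dir2)
  b2 <- read_dataset_mzml(dir2)
  expect_identical(vapply(b2$levels[[2]]$scans, function(s)
    sum(s$intensity), numeric(1)),
    vapply(back$levels[[2]]$scans, function(s)
      sum(s$intensity), numeric(1)))
})

test_that("scenario YAML round-trips the full configuration", {
  sc <- scenario_condensate("humid", seed = 4, n_features = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, path)
  back <- read_scenario_yaml(path)
  expect_equal(back$levels, sc$levels)
  expect_equal(back$compounds$mz, sc$compounds$mz)
  expect_equal(back$compounds$gas_phase_basicity,
               sc$compounds$gas_phase_basicity)
  expect_identical(back$condition, sc$condition)
  expect_equal(back$params$c50_humid, sc$params$c50_humid)
  expect_equal(back$program$lead_in, sc$program$lead_in)
  expect_identical(back$seed, sc$seed)
  # the scenario alone fixes the data: regenerate from the YAML copy
  # (YAML serializes doubles at 15 significant digits)
  expect_equal(generate_scenario(back)$truth$steady_intensity,
               generate_scenario(sc)$truth$steady_intensity,
               tolerance = 1e-12)
})
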