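# Small fast scenarios and independent oracles shared across test files.

# Two-compound scenario on a short pulse program; cheap enough for unit
# tests that only need a structurally complete dataset.
tiny_scenario <- function(condition = "dry", seed = 1L,
                          noise = list(baseline_sd = 100, cv = 0.05),
                          levels = c(0, 1.1e-2, 1.1e-1),
                          program = pulse_program(on_duration = 12,
                                                  off_duration = 12,
                                                  n_pulses = 3,
                                                  washout_time_constant = 1,
                                                  lead_in = 6)) {
  comps <- rbind(
    data.frame(name = "d3-acoh", mz = mz_protonated(get_compound("d3-acoh")),
               gas_phase_basicity = 752.8, role = "constant", ppm = 7e-4,
               channel_fraction = NA_real_, parent = NA_character_),
    data.frame(name = "d6-acetone",
               mz = mz_protonated(get_compound("d6-acetone")),
               gas_phase_basicity = 782.1, role = "suppressor",
               ppm = NA_real_, channel_fraction = NA_real_,
               parent = NA_character_)
  )
  sesi_scenario(name = "tiny", compounds = comps, levels = levels,
                condition = condition,
                windows = data.frame(lower = 64, upper = 66),
                program = program, scan_period = 1, noise = noise,
                seed = seed)
}

# Noiseless Gaussian test spectrum with the apex exactly on the grid.
gaussian_spectrum <- function(center = 100, sigma = 0.01, height = 1e6,
                              span = 12, step = sigma / 4) {
  mz <- seq(center - span * sigma, center + span * sigma, by = step)
  new_spectrum(mz, height * exp(-((mz - center)^2) / (2 * sigma^2)))
}

# Independent exhaustive-search oracle for l2 change-point detection:
# enumerates every placement of K change points and returns the first
# (lexicographically smallest) cost minimizer.
brute_force_changepoints <- function(y, K) {
  n <- length(y)
  S <- c(0, cumsum(y))
  Q <- c(0, cumsum(y^2))
  seg_cost <- function(i, j) # segment (i+1)..j, prefix indices
    Q[j + 1] - Q[i + 1] - (S[j + 1] - S[i + 1])^2 / (j - i)
  combos <- utils::combn(n - 1L, K)
  best <- Inf
  best_cp <- NULL
  for (c_i in seq_len(ncol(combos))) {
    cp <- combos[, c_i]
    bounds <- c(0L, cp, n)
    cost <- sum(vapply(seq_len(K + 1L), function(s)
      seg_cost(bounds[s], bounds[s + 1L]), numeric(1)))
    if (cost < best - 1e-12) {
      best <- cost
      best_cp <- cp
    }
  }
  list(changepoints = best_cp, cost = best)
}

# molar volume of an ideal gas, L/mol -- oracle independent of the package
ideal_gas_molar_volume <- function(temperature, pressure) {
  8.314462618 * temperature / pressure * 1000
}
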