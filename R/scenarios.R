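#' Assemble a simulation scenario
#'
#' Low-level constructor; most users want [scenario_binary()],
#' [scenario_ternary()], [scenario_condensate()] or
#' [scenario_sensitivity()], which encode the shipped study designs.
#'
#' @param name Scenario name.
#' @param compounds Data frame with one row per simulated channel: `name`,
#'   `mz` (the observed \eqn{[M+H]^+} m/z), `gas_phase_basicity`, `role`
#'   (`"suppressor"`, `"constant"` or `"channel"`), `ppm` (nominal delivery
#'   for constants; `NA` otherwise), `channel_fraction` and `parent` (for
#'   adduct/cluster channels that ride on another compound's intensity).
#' @param levels Suppressor concentration ladder in ppm; a leading 0 is the
#'   zero-suppressor control level.
#' @param condition `"dry"` or `"humid"`.
#' @param windows Data frame of SIM windows (`lower`, `upper`, in Th),
#'   cycled round-robin one window per scan.
#' @param program A [pulse_program()].
#' @param params A [suppression_params()].
#' @param scan_period Seconds between consecutive scans (default 1).
#' @param resolution Resolving power for the peak-width model
#'   (default 140000).
#' @param noise List with `baseline_sd` (a.u.) and `cv`.
#' @param response_coefficient Dry-condition instrument response, a.u./ppm.
#' @param seed Integer seed; fixes the generated dataset completely.
#' @return An object of class `sesi_scenario`.
#' @export
sesi_scenario <- function(name, compounds, levels,
                          condition = c("dry", "humid"),
                          windows,
                          program = pulse_program(),
                          params = suppression_params(),
                          scan_period = 1,
                          resolution = 140000,
                          noise = list(baseline_sd = 100, cv = 0.05),
                          response_coefficient = 1e11,
                          seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(compounds),
            all(c("name", "mz", "gas_phase_basicity", "role") %in%
                  names(compounds)))
  if (!"ppm" %in% names(compounds)) compounds$ppm <- NA_real_
  if (!"channel_fraction" %in% names(compounds))
    compounds$channel_fraction <- NA_real_
  if (!"parent" %in% names(compounds)) compounds$parent <- NA_character_
  stopifnot(all(compounds$role %in% c("suppressor", "constant", "channel")))
  if (any(!is.finite(levels)) || any(levels < 0))
    stop("levels must be >= 0", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing", call. = FALSE)
  stopifnot(is.data.frame(windows), all(c("lower", "upper") %in%
                                          names(windows)))
  if (any(windows$upper <= windows$lower))
    stop("window upper bound must exceed lower bound", call. = FALSE)
  structure(list(name = name, compounds = compounds,
                 levels = as.numeric(levels), condition = condition,
                 windows = windows, program = program, params = params,
                 scan_period = scan_period, resolution = resolution,
                 noise = noise, response_coefficient = response_coefficient,
                 seed = as.integer(seed)),
            class = "sesi_scenario")
}

compound_row <- function(cmpd, role, ppm = NA_real_,
                         channel_fraction = NA_real_,
                         parent = NA_character_) {
  data.frame(name = cmpd$name, mz = mz_protonated(cmpd),
             gas_phase_basicity = cmpd$gas_phase_basicity, role = role,
             ppm = ppm, channel_fraction = channel_fraction, parent = parent,
             stringsAsFactors = FALSE)
}

#' Binary crossover scenario: D6-acetone titrated against constant D3-AcOH
#'
#' D3-acetic acid is held at its lowest gas-phase set point (7.0e-4 ppm)
#' while D6-acetone rises over two decades in half-logarithmic steps from
#' 1.1e-2 to 1.1 ppm; a zero-suppressor control level leads the ladder. Both
#' \eqn{[M+H]^+} channels share the single 64-66 Th SIM window.
#'
#' @param condition `"dry"` (default) or `"humid"`.
#' @param seed Integer seed.
#' @param params A [suppression_params()].
#' @return A `sesi_scenario`.
#' @export
scenario_binary <- function(condition = "dry", seed = 1L,
                            params = suppression_params()) {
  comps <- rbind(
    compound_row(get_compound("d3-acoh"), "constant", ppm = 7.0e-4),
    compound_row(get_compound("d6-acetone"), "suppressor")
  )
  sesi_scenario(
    name = paste0("binary_", condition),
    compounds = comps,
    levels = c(0, concentration_ladder(1.1e-2, 2, 0.5)),
    condition = condition,
    windows = data.frame(lower = 64, upper = 66),
    scan_period = 1, params = params, seed = seed
  )
}

#' Ternary scenario: pyridine titrated against D3-AcOH and D6-acetone
#'
#' D3-acetic acid (7.0e-4 ppm) and D6-acetone (1.1e-2 ppm) are held constant
#' while pyridine rises from its 2.7e-4 ppm set point in half-logarithmic
#' steps to ~0.85 ppm. Three 1-Th SIM windows centred on the \eqn{[M+H]^+}
#' ions (64.1, 65.1, 80.1) are cycled.
#'
#' @inheritParams scenario_binary
#' @param condition `"humid"` (default) or `"dry"`.
#' @export
scenario_ternary <- function(condition = "humid", seed = 1L,
                             params = suppression_params()) {
  comps <- rbind(
    compound_row(get_compound("d3-acoh"), "constant", ppm = 7.0e-4),
    compound_row(get_compound("d6-acetone"), "constant", ppm = 1.1e-2),
    compound_row(get_compound("pyridine"), "suppressor")
  )
  sesi_scenario(
    name = paste0("ternary_", condition),
    compounds = comps,
    levels = c(0, concentration_ladder(2.7e-4, 3.5, 0.5)),
    condition = condition,
    windows = data.frame(lower = c(63.6, 64.6, 79.6),
                         upper = c(64.6, 65.6, 80.6)),
    scan_period = 0.5, params = params, seed = seed
  )
}

#' Breath-condensate scenario: D6-acetone titrated against a volatile panel
#'
#' Emulates the exhaled-breath-condensate experiment: a panel of
#' `n_features` condensate volatiles (gas-phase basicities drawn uniformly
#' from `gb_range`, below acetone's 782.1 kJ/mol; delivery concentrations
#' log-normal around 3e-4 ppm) is co-delivered while D6-acetone rises over
#' three decades from 1.1e-2 to 11 ppm. The suppressor contributes two
#' increasing channels of its own ion chemistry, the hydrate
#' \eqn{[M+H_2O+H]^+} and the proton-bound dimer \eqn{[2M+H]^+}. Three wide
#' SIM windows (60-90, 90-120, 120-150 Th) are cycled so every feature trace
#' is sampled every 1.5 s.
#'
#' The panel is drawn from `seed`, so the scenario object fixes the ground
#' truth as well as the noise.
#'
#' @inheritParams scenario_binary
#' @param n_features Number of condensate volatiles (default 12).
#' @param gb_range Uniform range of feature gas-phase basicities, kJ/mol.
#' @export
scenario_condensate <- function(condition = "humid", seed = 1L,
                                n_features = 12,
                                gb_range = c(745, 780),
                                params = suppression_params()) {
  supp <- get_compound("d6-acetone")
  supp_mz <- mz_protonated(supp)
  hydrate_mz <- supp$monoisotopic_mass + 18.0105646 + PROTON_MASS
  dimer_mz <- 2 * supp$monoisotopic_mass + PROTON_MASS
  reserved <- c(supp_mz, hydrate_mz, dimer_mz)
  win_edges <- c(60, 90, 120, 150)
  feats <- withr::with_seed(seed, {
    mzs <- numeric(0)
    while (length(mzs) < n_features) {
      cand <- stats::runif(1, 66, 149)
      if (all(abs(cand - c(reserved, mzs)) > 0.8) &&
          all(abs(cand - win_edges) > 0.2)) mzs <- c(mzs, cand)
    }
    data.frame(
      name = sprintf("feature_%03.0f", round(mzs)),
      mz = mzs,
      gas_phase_basicity = stats::runif(n_features, gb_range[1], gb_range[2]),
      role = "constant",
      ppm = stats::rlnorm(n_features, log(3e-4), 0.5),
      channel_fraction = NA_real_, parent = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  comps <- rbind(
    compound_row(supp, "suppressor"),
    data.frame(name = "d6-acetone_hydrate", mz = hydrate_mz,
               gas_phase_basicity = supp$gas_phase_basicity,
               role = "channel", ppm = NA_real_, channel_fraction = 0.5,
               parent = "d6-acetone", stringsAsFactors = FALSE),
    data.frame(name = "d6-acetone_dimer", mz = dimer_mz,
               gas_phase_basicity = supp$gas_phase_basicity,
               role = "channel", ppm = NA_real_, channel_fraction = 0.15,
               parent = "d6-acetone", stringsAsFactors = FALSE),
    feats
  )
  sesi_scenario(
    name = paste0("condensate_", condition),
    compounds = comps,
    levels = c(0, concentration_ladder(1.1e-2, 3, 0.5)),
    condition = condition,
    windows = data.frame(lower = c(60, 90, 120), upper = c(90, 120, 150)),
    scan_period = 0.5, params = params, seed = seed
  )
}

#' Single-analyte sensitivity scenario
#'
#' One compound delivered alone at a concentration far below the suppression
#' scale, used to compare instrument response between dry and humid
#' conditions.
#'
#' @inheritParams scenario_binary
#' @param ppm Delivered concentration (default 1.1e-2 ppm).
#' @export
scenario_sensitivity <- function(condition = "dry", seed = 1L,
                                 ppm = 1.1e-2,
                                 params = suppression_params()) {
  comps <- compound_row(get_compound("d6-acetone"), "suppressor")
  sesi_scenario(
    name = paste0("sensitivity_", condition),
    compounds = comps,
    levels = ppm,
    condition = condition,
    windows = data.frame(lower = 64.6, upper = 65.6),
    scan_period = 1, params = params, seed = seed
  )
}

#' Serialize a scenario to YAML
#' @param scenario A `sesi_scenario`.
#' @param path Output file path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  x <- unclass(scenario)
  x$program <- unclass(x$program)
  x$params <- unclass(x$params)
  x$compounds <- lapply(seq_len(nrow(x$compounds)), function(i)
    as.list(x$compounds[i, ]))
  x$windows <- lapply(seq_len(nrow(x$windows)), function(i)
    as.list(x$windows[i, ]))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a scenario from YAML
#' @param path File written by [write_scenario_yaml()].
#' @return A `sesi_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  comp <- do.call(rbind, lapply(x$compounds, function(r)
    data.frame(name = r$name, mz = r$mz,
               gas_phase_basicity = r$gas_phase_basicity, role = r$role,
               ppm = if (is.null(r$ppm)) NA_real_ else as.numeric(r$ppm),
               channel_fraction = if (is.null(r$channel_fraction))
                 NA_real_ else as.numeric(r$channel_fraction),
               parent = if (is.null(r$parent)) NA_character_
               else as.character(r$parent),
               stringsAsFactors = FALSE)))
  win <- do.call(rbind, lapply(x$windows, function(r)
    data.frame(lower = r$lower, upper = r$upper)))
  sesi_scenario(
    name = x$name, compounds = comp, levels = as.numeric(x$levels),
    condition = x$condition, windows = win,
    program = do.call(pulse_program, x$program[c(
      "on_duration", "off_duration", "n_pulses", "washout_time_constant",
      "lead_in")]),
    params = do.call(suppression_params, x$params),
    scan_period = x$scan_period, resolution = x$resolution,
    noise = x$noise, response_coefficient = x$response_coefficient,
    seed = x$seed
  )
}
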