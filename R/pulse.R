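#' Pulsed delivery program of the evaporation chamber
#'
#' The chamber flow is switched on and off in rectangular pulses; the mixing
#' chamber washes concentration changes in and out with a first-order time
#' constant. A lead-in baseline period precedes the first pulse so every
#' measurement carries its own within-run baseline and the trace has
#' `2 * n_pulses + 1` piecewise-steady segments (baseline, then on/off per
#' pulse).
#'
#' @param on_duration Pulse on-time in seconds (default 30).
#' @param off_duration Pulse off-time in seconds (default 30).
#' @param n_pulses Number of pulses (default 3).
#' @param washout_time_constant First-order mixing-chamber washout constant
#'   in seconds (default 3); 0 gives an exact square wave.
#' @param lead_in Baseline duration before the first pulse in seconds
#'   (default 10).
#' @return An object of class `pulse_program`.
#' @export
pulse_program <- function(on_duration = 30, off_duration = 30, n_pulses = 3,
                          washout_time_constant = 3, lead_in = 10) {
  if (!is.finite(on_duration) || on_duration <= 0)
    stop("on_duration must be > 0", call. = FALSE)
  if (!is.finite(off_duration) || off_duration <= 0)
    stop("off_duration must be > 0", call. = FALSE)
  if (!is.finite(n_pulses) || n_pulses < 1 || n_pulses != round(n_pulses))
    stop("n_pulses must be a positive integer", call. = FALSE)
  if (!is.finite(washout_time_constant) || washout_time_constant < 0)
    stop("washout_time_constant must be >= 0", call. = FALSE)
  if (!is.finite(lead_in) || lead_in < 0)
    stop("lead_in must be >= 0", call. = FALSE)
  structure(list(on_duration = on_duration, off_duration = off_duration,
                 n_pulses = as.integer(n_pulses),
                 washout_time_constant = washout_time_constant,
                 lead_in = lead_in),
            class = "pulse_program")
}

#' Total duration of a pulse program in seconds
#' @param program A [pulse_program()].
#' @export
program_duration <- function(program) {
  program$lead_in +
    program$n_pulses * (program$on_duration + program$off_duration)
}

#' Phase table of a pulse program
#'
#' @param program A [pulse_program()].
#' @return Data frame with one row per phase: `start`, `end` (seconds) and
#'   `on` (logical). The lead-in baseline is the first row (dropped when
#'   `lead_in` is 0).
#' @export
program_phases <- function(program) {
  starts <- program$lead_in +
    rep(seq_len(program$n_pulses) - 1L,
        each = 2L) * (program$on_duration + program$off_duration) +
    rep(c(0, program$on_duration), times = program$n_pulses)
  durations <- rep(c(program$on_duration, program$off_duration),
                   times = program$n_pulses)
  phases <- data.frame(start = starts, end = starts + durations,
                       on = rep(c(TRUE, FALSE), times = program$n_pulses))
  if (program$lead_in > 0)
    phases <- rbind(data.frame(start = 0, end = program$lead_in, on = FALSE),
                    phases)
  phases
}

#' Gas-phase concentration profile of a pulsed delivery
#'
#' Evaluates the mixing-chamber outlet concentration of one analyte over
#' time: a first-order rise toward `nominal_ppm` during on-phases and a
#' first-order decay toward zero during off-phases, with the washout time
#' constant of the program. A zero time constant gives an exact square wave.
#'
#' @param program A [pulse_program()].
#' @param nominal_ppm Plateau concentration in ppm.
#' @param t_grid Increasing vector of times in seconds.
#' @return Concentration in ppm at each time in `t_grid`.
#' @examples
#' prog <- pulse_program(washout_time_constant = 5, lead_in = 0)
#' delivery_profile(prog, 1, 30) # 1 - exp(-6)
#' @export
delivery_profile <- function(program, nominal_ppm, t_grid) {
  stopifnot(inherits(program, "pulse_program"))
  if (is.unsorted(t_grid)) stop("t_grid must be increasing", call. = FALSE)
  if (!is.finite(nominal_ppm) || nominal_ppm < 0)
    stop("nominal_ppm must be >= 0", call. = FALSE)
  phases <- program_phases(program)
  tau <- program$washout_time_constant
  out <- numeric(length(t_grid))
  c_start <- 0
  for (i in seq_len(nrow(phases))) {
    target <- if (phases$on[i]) nominal_ppm else 0
    sel <- t_grid >= phases$start[i] &
      (t_grid < phases$end[i] | i == nrow(phases))
    if (tau == 0) {
      if (any(sel)) out[sel] <- target
      c_end <- target
    } else {
      if (any(sel)) {
        dt <- t_grid[sel] - phases$start[i]
        out[sel] <- target + (c_start - target) * exp(-dt / tau)
      }
      c_end <- target + (c_start - target) *
        exp(-(phases$end[i] - phases$start[i]) / tau)
    }
    c_start <- c_end
  }
  out[t_grid < 0] <- 0
  out
}
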