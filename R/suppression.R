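#' Parameters of the competitive gas-phase suppression model
#'
#' The synthetic instrument model attenuates each analyte's ionization
#' efficiency through saturable competition with its co-analytes, weighted by
#' the difference in gas-phase basicity (GB):
#' \deqn{F_i = \left(1 + \sum_{j \ne i} e^{(GB_j - GB_i)/\beta}
#'       \; c_j / c_{50}\right)^{-\gamma}}
#' A co-analyte that is a stronger gas-phase base than the analyte
#' (\eqn{GB_j > GB_i}) competes super-proportionally for the available
#' charge; an isotopologue (equal GB) competes with unit weight; a weaker
#' base competes sub-proportionally. `c50` sets the co-analyte concentration
#' scale at which suppression becomes substantial and is condition dependent:
#' humidified carrier gas buffers the proton-transfer competition, so
#' `c50_humid >> c50_dry`.
#'
#' Defaults are calibration constants of the shipped scenarios: `beta` and
#' `gamma` shape how steeply suppression grows with basicity difference and
#' with concentration (gamma = 2 lets two decades of suppressor increase
#' produce up to four decades of signal loss), and the two `c50` values place
#' the dry and humid suppression onsets so the shipped scenarios reproduce
#' the headline literature numbers (see the methods vignette).
#'
#' @param beta Basicity selectivity scale in kJ/mol (default 20).
#' @param gamma Saturation exponent (default 2).
#' @param c50_dry Suppressor concentration scale in ppm under dry conditions
#'   (default 0.01).
#' @param c50_humid Suppressor concentration scale in ppm under humid
#'   conditions (default 15).
#' @param humid_sensitivity_ratio Ratio of dry to humid instrument response
#'   for the same gas-phase concentration (default 10).
#' @return An object of class `suppression_params`.
#' @export
suppression_params <- function(beta = 20, gamma = 2, c50_dry = 0.01,
                               c50_humid = 15,
                               humid_sensitivity_ratio = 10) {
  vals <- c(beta = beta, gamma = gamma, c50_dry = c50_dry,
            c50_humid = c50_humid,
            humid_sensitivity_ratio = humid_sensitivity_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all suppression parameters must be positive", call. = FALSE)
  structure(as.list(vals), class = "suppression_params")
}

c50_for <- function(params, condition) {
  condition <- match.arg(condition, c("dry", "humid"))
  if (condition == "dry") params$c50_dry else params$c50_humid
}

#' Suppression factor of an analyte in a gas-phase mixture
#'
#' Evaluates the competitive suppression model (see [suppression_params()])
#' for one analyte against a set of co-analytes. The factor is 1 with no
#' co-analytes, lies in (0, 1], is monotone non-increasing in every
#' co-analyte concentration, and for equal concentrations the induced loss
#' increases with the co-analyte's gas-phase basicity.
#'
#' @param analyte A [compound()] (or its numeric gas-phase basicity).
#' @param co_gb Numeric vector of co-analyte gas-phase basicities in kJ/mol
#'   (or a list of `sesi_compound`s).
#' @param co_ppm Co-analyte gas-phase concentrations in ppm, same length as
#'   `co_gb`; must be >= 0.
#' @param params A [suppression_params()].
#' @param condition `"dry"` or `"humid"`; selects the `c50`.
#' @return Suppression factor in (0, 1].
#' @examples
#' p <- suppression_params()
#' acoh <- get_compound("d3-acoh")
#' pyr <- get_compound("pyridine")
#' suppression_factor(acoh, pyr, co_ppm = 0.1, params = p, condition = "humid")
#' @export
suppression_factor <- function(analyte, co_gb = numeric(0),
                               co_ppm = numeric(0),
                               params = suppression_params(),
                               condition = c("dry", "humid")) {
  condition <- match.arg(condition)
  gb_i <- gb_of(analyte)
  gb_j <- vapply(as_gb_list(co_gb), identity, numeric(1))
  if (length(gb_j) != length(co_ppm))
    stop("co_gb and co_ppm must have the same length", call. = FALSE)
  if (any(!is.finite(co_ppm)) || any(co_ppm < 0))
    stop("co-analyte concentrations must be >= 0", call. = FALSE)
  if (length(gb_j) == 0L) return(1)
  c50 <- c50_for(params, condition)
  load <- sum(exp((gb_j - gb_i) / params$beta) * co_ppm / c50)
  (1 + load)^(-params$gamma)
}

gb_of <- function(x) {
  if (inherits(x, "sesi_compound")) x$gas_phase_basicity
  else if (is.numeric(x) && length(x) == 1L) x
  else stop("expected a compound or a single gas-phase basicity",
            call. = FALSE)
}

as_gb_list <- function(x) {
  if (inherits(x, "sesi_compound")) return(list(x$gas_phase_basicity))
  if (is.list(x)) return(lapply(x, gb_of))
  if (is.numeric(x)) return(as.list(x))
  stop("co_gb must be numeric or a list of compounds", call. = FALSE)
}

#' Steady-state signal intensity of an analyte
#'
#' The noiseless apex intensity the synthetic instrument reports for an
#' analyte delivered at a constant gas-phase concentration:
#' `response * delivered_ppm * suppression_factor`, with the response divided
#' by `humid_sensitivity_ratio` under humid conditions (humidified carrier
#' gas lowers the instrument sensitivity).
#'
#' @inheritParams suppression_factor
#' @param delivered_ppm Analyte gas-phase concentration in ppm; must be >= 0.
#' @param response_coefficient Instrument response under dry conditions in
#'   arbitrary units per ppm (default 1e11, placing sub-ppm analytes in the
#'   1e6-1e8 a.u. apex range typical of Orbitrap profile data).
#' @return Apex intensity in arbitrary units.
#' @export
steady_intensity <- function(analyte, delivered_ppm, co_gb = numeric(0),
                             co_ppm = numeric(0),
                             params = suppression_params(),
                             condition = c("dry", "humid"),
                             response_coefficient = 1e11) {
  condition <- match.arg(condition)
  if (any(!is.finite(delivered_ppm)) || any(delivered_ppm < 0))
    stop("delivered_ppm must be >= 0", call. = FALSE)
  s <- response_coefficient
  if (condition == "humid") s <- s / params$humid_sensitivity_ratio
  s * delivered_ppm *
    suppression_factor(analyte, co_gb, co_ppm, params, condition)
}
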