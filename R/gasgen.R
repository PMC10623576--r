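# molar gas constant, J / (mol K)
R_GAS <- 8.314462618

#' Flow configuration of the gas-standard generation system
#'
#' Describes the evaporation-chamber / mixing-chamber plumbing: a small
#' nitrogen flow pushes the equilibrated headspace of a stock solution into a
#' mixing chamber where a much larger dilution flow dilutes it before the
#' outlet feeds the SESI source.
#'
#' @param chamber_flow Evaporation-chamber flow in L/min (default 0.005,
#'   i.e. 5 mL/min).
#' @param dilution_flow Mixing-chamber dilution flow in L/min (default 8).
#' @param temperature Headspace equilibrium temperature in K (default
#'   298.15, room temperature).
#' @param pressure Pressure in Pa (default 101325).
#' @param humidity Relative humidity at the mixing-chamber outlet as a
#'   fraction in \[0, 1\] (0 = dry, 0.95 = humidified dilution gas). Humidity
#'   does not change the gas-standard arithmetic; it selects the sensitivity
#'   and suppression regime of the synthetic instrument model.
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(chamber_flow = 0.005, dilution_flow = 8,
                        temperature = 298.15, pressure = 101325,
                        humidity = 0) {
  if (!is.finite(chamber_flow) || chamber_flow <= 0)
    stop("chamber_flow must be > 0", call. = FALSE)
  if (!is.finite(dilution_flow) || dilution_flow <= 0)
    stop("dilution_flow must be > 0", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0", call. = FALSE)
  if (!is.finite(pressure) || pressure <= 0)
    stop("pressure must be > 0", call. = FALSE)
  if (!is.finite(humidity) || humidity < 0 || humidity > 1)
    stop("humidity must be in [0, 1]", call. = FALSE)
  structure(list(chamber_flow = chamber_flow, dilution_flow = dilution_flow,
                 temperature = temperature, pressure = pressure,
                 humidity = humidity),
            class = "flow_config")
}

#' Mixing-chamber dilution factor
#'
#' Ratio by which the evaporation-chamber headspace is diluted in the mixing
#' chamber. The default convention is `dilution_flow / chamber_flow`, which
#' gives exactly 1600 for the nominal 8 L/min dilution and 5 mL/min chamber
#' flows; the alternative `"total"` convention uses
#' `(dilution_flow + chamber_flow) / chamber_flow` (1601 for the same flows).
#'
#' @param flows A [flow_config()].
#' @param convention `"ratio"` (default) or `"total"`.
#' @return Dimensionless dilution factor.
#' @examples
#' dilution_factor(flow_config()) # 1600
#' @export
dilution_factor <- function(flows, convention = c("ratio", "total")) {
  stopifnot(inherits(flows, "flow_config"))
  convention <- match.arg(convention)
  switch(convention,
         ratio = flows$dilution_flow / flows$chamber_flow,
         total = (flows$dilution_flow + flows$chamber_flow) / flows$chamber_flow)
}

#' Equilibrium headspace gas-phase molarity over a stock solution
#'
#' Henry's law links the aqueous stock concentration to the gas-phase
#' concentration of the equilibrated headspace:
#' \deqn{c_{gas} = c_{aq} / (s \cdot H)}
#' where `H` is the compound's Henry constant as printed in headspace work
#' and `s` is a scale factor. Printed constants of order 0.67 (acetone),
#' 2.73 (pyridine) and 99.15 (acetic acid) correspond to literature
#' dimensionless liquid/gas partition coefficients of ~670, ~2730 and ~99150,
#' so the default scale is 1000; set `henry_scale = 1` if your constants are
#' already on the full dimensionless scale.
#'
#' @param stock_molarity Aqueous stock concentration in mol/L; must be >= 0.
#' @param compound A [compound()].
#' @param henry_scale Scale factor applied to the stored Henry constant
#'   (default 1000).
#' @return Gas-phase concentration of the headspace in mol/L.
#' @export
headspace_gas_molarity <- function(stock_molarity, compound,
                                   henry_scale = 1000) {
  stopifnot(inherits(compound, "sesi_compound"))
  if (any(!is.finite(stock_molarity)) || any(stock_molarity < 0))
    stop("stock_molarity must be >= 0", call. = FALSE)
  if (!is.finite(henry_scale) || henry_scale <= 0)
    stop("henry_scale must be > 0", call. = FALSE)
  stock_molarity / (henry_scale * compound$henry_constant)
}

#' Convert a gas-phase molar concentration to a mole fraction in ppm
#'
#' Uses the ideal gas law: one mole of gas occupies \eqn{RT/P}, so the mole
#' fraction of an analyte at `gas_molarity` mol/L is
#' \eqn{c \cdot RT/P \cdot 10^6} ppm (24.4655 L/mol at 298.15 K, 101325 Pa).
#'
#' @param gas_molarity Gas-phase concentration in mol/L; may be a vector.
#' @param temperature Temperature in K (default 298.15).
#' @param pressure Pressure in Pa (default 101325).
#' @return Concentration in ppm (mole fraction x 1e6).
#' @export
molar_to_ppm <- function(gas_molarity, temperature = 298.15,
                         pressure = 101325) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0", call. = FALSE)
  if (!is.finite(pressure) || pressure <= 0)
    stop("pressure must be > 0", call. = FALSE)
  molar_volume_l <- R_GAS * temperature / pressure * 1000
  gas_molarity * molar_volume_l * 1e6
}

#' Gas-phase concentration at the mixing-chamber outlet
#'
#' Chains Henry's-law headspace equilibration, the ideal-gas molar-to-ppm
#' conversion and the mixing-chamber dilution: the outlet concentration is
#' linear in the stock molarity and inversely proportional to both the Henry
#' constant and the dilution factor.
#'
#' @inheritParams headspace_gas_molarity
#' @param flows A [flow_config()]; its temperature and pressure are used for
#'   the ideal-gas conversion.
#' @return Outlet concentration in ppm.
#' @export
outlet_ppm <- function(stock_molarity, compound, flows = flow_config(),
                       henry_scale = 1000) {
  gas <- headspace_gas_molarity(stock_molarity, compound, henry_scale)
  molar_to_ppm(gas, flows$temperature, flows$pressure) /
    dilution_factor(flows)
}

#' Stock molarity required for a target outlet concentration
#'
#' Analytic inverse of [outlet_ppm()]: the round trip
#' `outlet_ppm(required_stock(x))` reproduces `x` to machine precision.
#'
#' @param target_ppm Desired outlet concentration in ppm; must be >= 0.
#' @inheritParams outlet_ppm
#' @return Stock concentration in mol/L.
#' @export
required_stock <- function(target_ppm, compound, flows = flow_config(),
                           henry_scale = 1000) {
  stopifnot(inherits(compound, "sesi_compound"))
  if (any(!is.finite(target_ppm)) || any(target_ppm < 0))
    stop("target_ppm must be >= 0", call. = FALSE)
  molar_volume_l <- R_GAS * flows$temperature / flows$pressure * 1000
  target_ppm / 1e6 / molar_volume_l * dilution_factor(flows) *
    henry_scale * compound$henry_constant
}

#' Half-logarithmic concentration ladder
#'
#' Builds the ladder of gas-phase set points used in suppression titrations:
#' levels rising from `base_ppm` in constant log10 steps (default half a
#' decade) over `decades` decades, both endpoints included.
#'
#' @param base_ppm First (lowest) level in ppm; must be > 0.
#' @param decades Total span in decades; must be a positive multiple of
#'   `step_decades`.
#' @param step_decades Log10 step between consecutive levels (default 0.5,
#'   half-logarithmic).
#' @return Numeric vector of class `concentration_ladder`, strictly
#'   increasing, of length `decades / step_decades + 1`.
#' @examples
#' concentration_ladder(1.1e-2, 3) # 1.1e-2 ... 11 ppm, 7 levels
#' @export
concentration_ladder <- function(base_ppm, decades, step_decades = 0.5) {
  if (!is.finite(base_ppm) || base_ppm <= 0)
    stop("base_ppm must be > 0", call. = FALSE)
  if (!is.finite(decades) || decades <= 0)
    stop("decades must be > 0", call. = FALSE)
  if (!is.finite(step_decades) || step_decades <= 0)
    stop("step_decades must be > 0", call. = FALSE)
  n_steps <- decades / step_decades
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("decades must be a multiple of step_decades", call. = FALSE)
  levels <- base_ppm * 10^(seq(0, round(n_steps)) * step_decades)
  structure(levels, class = c("concentration_ladder", "numeric"))
}
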