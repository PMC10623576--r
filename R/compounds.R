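#' Define an analyte compound
#'
#' A compound carries the per-analyte physical parameters used throughout the
#' package: the monoisotopic mass (for the \eqn{[M+H]^+} channel position),
#' the dimensionless Henry's-law liquid/gas partition constant (for headspace
#' gas-standard generation) and the gas-phase basicity (which orders the
#' competitive suppression model).
#'
#' @param name Compound name.
#' @param monoisotopic_mass Monoisotopic mass in Da; must be positive.
#' @param henry_constant Dimensionless liquid/gas Henry constant as
#'   conventionally printed for headspace work (see [headspace_gas_molarity]
#'   for the scale convention); must be positive.
#' @param gas_phase_basicity Gas-phase basicity in kJ/mol; must be positive.
#' @return An object of class `sesi_compound`.
#' @examples
#' pyr <- compound("pyridine", 79.0422, 2.73, 898.1)
#' mz_protonated(pyr)
#' @export
compound <- function(name, monoisotopic_mass, henry_constant,
                     gas_phase_basicity) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(monoisotopic_mass) || monoisotopic_mass <= 0)
    stop("monoisotopic_mass must be a positive number", call. = FALSE)
  if (!is.finite(henry_constant) || henry_constant <= 0)
    stop("henry_constant must be a positive number", call. = FALSE)
  if (!is.finite(gas_phase_basicity) || gas_phase_basicity <= 0)
    stop("gas_phase_basicity must be a positive number", call. = FALSE)
  structure(
    list(name = name,
         monoisotopic_mass = monoisotopic_mass,
         henry_constant = henry_constant,
         gas_phase_basicity = gas_phase_basicity),
    class = "sesi_compound"
  )
}

#' @export
print.sesi_compound <- function(x, ...) {
  cat(sprintf("<compound> %s  M = %.6f Da  H = %.4g  GB = %.1f kJ/mol\n",
              x$name, x$monoisotopic_mass, x$henry_constant,
              x$gas_phase_basicity))
  invisible(x)
}

#' Packaged compound table
#'
#' Returns the compound parameter table shipped with the package: acetone,
#' D6-acetone, D3-acetic acid, pyridine and ammonia. Deuterated compounds use
#' the Henry constant of the non-deuterated analogue; the two acetones share
#' the same gas-phase basicity (isotopologues have identical proton-transfer
#' thermochemistry).
#'
#' @return A data frame with columns `name`, `monoisotopic_mass`,
#'   `henry_constant`, `gas_phase_basicity`.
#' @export
compounds <- function() {
  path <- system.file("extdata", "compounds.tsv", package = "sesisuppress",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Look up a packaged compound by name
#'
#' @param name Name matching a row of [compounds()].
#' @return A `sesi_compound`.
#' @export
get_compound <- function(name) {
  tab <- compounds()
  i <- match(tolower(name), tab$name)
  if (is.na(i)) stop("unknown compound: ", name, call. = FALSE)
  compound(tab$name[i], tab$monoisotopic_mass[i], tab$henry_constant[i],
           tab$gas_phase_basicity[i])
}

# mass of a proton, Da
PROTON_MASS <- 1.00727646688

#' m/z of the protonated molecular ion
#'
#' @param x A `sesi_compound` or a numeric monoisotopic mass.
#' @return The \eqn{[M+H]^+} m/z.
#' @export
mz_protonated <- function(x) {
  m <- if (inherits(x, "sesi_compound")) x$monoisotopic_mass else x
  m + PROTON_MASS
}
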