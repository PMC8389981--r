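#' Physical constants (CODATA 2018, exact SI where defined)
#'
#' Returns the shared table of physical constants used throughout the
#' package. All electrostatic and thermodynamic relations draw from this
#' single table so that derived quantities are mutually consistent.
#'
#' @return A named list:
#' \describe{
#'   \item{eps0}{vacuum permittivity (F/m)}
#'   \item{k_B}{Boltzmann constant (J/K)}
#'   \item{e}{elementary charge (C)}
#'   \item{N_A}{Avogadro constant (1/mol)}
#'   \item{R_gas}{molar gas constant (J/mol/K)}
#' }
#' @examples
#' physical_constants()$k_B
#' @export
physical_constants <- function() {
  list(
    eps0  = 8.8541878128e-12,
    k_B   = 1.380649e-23,
    e     = 1.602176634e-19,
    N_A   = 6.02214076e23,
    R_gas = 8.314462618
  )
}

# internal shorthand, evaluated once at load
.const <- physical_constants()
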