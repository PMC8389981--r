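#' Solution conditions for electrolyte electrostatics
#'
#' Bundles the thermodynamic and electrolyte state from which every
#' double-layer quantity (Debye length, charge-potential relations) is
#' derived. Only symmetric z:z electrolytes are supported.
#'
#' @param ionic_concentration Bulk electrolyte concentration (mol/L).
#' @param temperature Absolute temperature (K). Default 298.15 K, the
#'   temperature at which zeta potentials are conventionally reported.
#' @param relative_permittivity Relative permittivity of the solvent
#'   (dimensionless). Default 78.4, water at 25 degC.
#' @param electrolyte_valence Valence z of the symmetric z:z electrolyte
#'   (positive integer).
#' @return An object of class `solution_conditions`.
#' @examples
#' solution_conditions(1e-3)
#' @export
solution_conditions <- function(ionic_concentration,
                                temperature = 298.15,
                                relative_permittivity = 78.4,
                                electrolyte_valence = 1L) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  stopifnot(is.numeric(relative_permittivity), length(relative_permittivity) == 1L,
            is.finite(relative_permittivity), relative_permittivity > 0)
  z <- as.integer(electrolyte_valence)
  stopifnot(length(z) == 1L, !is.na(z), z >= 1L)
  stopifnot(is.numeric(ionic_concentration), length(ionic_concentration) == 1L,
            is.finite(ionic_concentration))
  if (ionic_concentration < 0)
    stop("`ionic_concentration` must be >= 0 (mol/L)", call. = FALSE)
  structure(
    list(temperature = as.numeric(temperature),
         relative_permittivity = as.numeric(relative_permittivity),
         electrolyte_valence = z,
         ionic_concentration = as.numeric(ionic_concentration)),
    class = "solution_conditions")
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf("<solution_conditions> %g:%g electrolyte, %g mol/L, T = %g K, eps_r = %g\n",
              x$electrolyte_valence, x$electrolyte_valence,
              x$ionic_concentration, x$temperature, x$relative_permittivity))
  if (x$ionic_concentration > 0) {
    dl <- debye_parameter(x)
    cat(sprintf("  Debye length: %.3g nm\n", dl$debye_length * 1e9))
  }
  invisible(x)
}

#' Nanoparticle specification
#'
#' Geometry, suspension number density and (optionally) the measured zeta
#' potential of a spherical nanoparticle. The zeta potential, when used as
#' a stand-in for the surface potential, is an approximation; functions
#' consuming it flag this in their output metadata.
#'
#' @param diameter Sphere diameter (m).
#' @param number_density Particles per litre of suspension (1/L).
#' @param zeta_potential Optional measured zeta potential (V).
#' @param label Free-text label, e.g. `"PS"` or `"PS-COOH"`.
#' @return An object of class `nanoparticle_spec`.
#' @examples
#' nanoparticle_spec(100e-9, 4.55e14, zeta_potential = -42e-3, label = "PS")
#' @export
nanoparticle_spec <- function(diameter, number_density,
                              zeta_potential = NULL, label = "") {
  stopifnot(is.numeric(diameter), length(diameter) == 1L,
            is.finite(diameter), diameter > 0)
  stopifnot(is.numeric(number_density), length(number_density) == 1L,
            is.finite(number_density), number_density > 0)
  if (!is.null(zeta_potential))
    stopifnot(is.numeric(zeta_potential), length(zeta_potential) == 1L,
              is.finite(zeta_potential))
  structure(
    list(diameter = as.numeric(diameter),
         number_density = as.numeric(number_density),
         zeta_potential = if (is.null(zeta_potential)) NULL else as.numeric(zeta_potential),
         label = as.character(label)),
    class = "nanoparticle_spec")
}

#' @export
print.nanoparticle_spec <- function(x, ...) {
  cat(sprintf("<nanoparticle_spec> %s D = %g nm, %.3g /L",
              if (nzchar(x$label)) paste0("[", x$label, "]") else "",
              x$diameter * 1e9, x$number_density))
  if (!is.null(x$zeta_potential))
    cat(sprintf(", zeta = %g mV", x$zeta_potential * 1e3))
  cat("\n")
  invisible(x)
}

#' Protein specification
#'
#' @param name Protein name (nonempty).
#' @param net_valence Signed effective net charge in elementary charges at
#'   the working pH (e.g. about -8 for human serum albumin near pH 6.6).
#' @return An object of class `protein_spec`.
#' @examples
#' protein_spec("HSA", -8)
#' @export
protein_spec <- function(name, net_valence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(net_valence), length(net_valence) == 1L,
            is.finite(net_valence))
  structure(list(name = name, net_valence = as.numeric(net_valence)),
            class = "protein_spec")
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("<protein_spec> %s, net valence %+g e\n", x$name, x$net_valence))
  invisible(x)
}

#' Adsorption parameters (ground truth or fitted)
#'
#' The apparent binding constant and monolayer capacity that parameterise
#' the depletion-corrected Langmuir isotherm. Only the ratio
#' K = k_a/k_d is identifiable from equilibrium titrations; individual
#' rate constants are never separated. The half-saturation free
#' concentration equals `1/binding_constant_app`.
#'
#' @param binding_constant_app Apparent binding constant K_app (1/M).
#' @param n_max_per_particle Maximum number of adsorbed proteins per
#'   nanoparticle (count).
#' @param solvent_molarity Molarity of the solvent (mol/L); 55.5 for water.
#'   Kept for the alternative standard-state convention; the default
#'   parameterisation absorbs it into K_app.
#' @return An object of class `adsorption_params`.
#' @examples
#' adsorption_params(3.3e9, 244)
#' @export
adsorption_params <- function(binding_constant_app, n_max_per_particle,
                              solvent_molarity = 55.5) {
  stopifnot(is.numeric(binding_constant_app), length(binding_constant_app) == 1L,
            is.finite(binding_constant_app), binding_constant_app > 0)
  stopifnot(is.numeric(n_max_per_particle), length(n_max_per_particle) == 1L,
            is.finite(n_max_per_particle), n_max_per_particle > 0)
  stopifnot(is.numeric(solvent_molarity), solvent_molarity > 0)
  structure(
    list(binding_constant_app = as.numeric(binding_constant_app),
         n_max_per_particle = as.numeric(n_max_per_particle),
         solvent_molarity = as.numeric(solvent_molarity)),
    class = "adsorption_params")
}

#' @export
print.adsorption_params <- function(x, ...) {
  cat(sprintf("<adsorption_params> K_app = %.3g /M, N_max = %.4g per particle\n",
              x$binding_constant_app, x$n_max_per_particle))
  invisible(x)
}
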