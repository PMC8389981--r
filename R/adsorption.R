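# Depletion-corrected Langmuir isotherm and the thermodynamic quantities
# derived from it: capacity conversions, surface-charge update on
# adsorption, apparent Gibbs free energy and its first-order uncertainty.

#' Convert a per-particle capacity to a per-volume capacity
#'
#' N_max (mol/L) = n_max_per_particle * number_density / N_A. This links
#' the per-particle monolayer capacity reported for each particle/protein
#' pair to the volumetric capacity entering the depletion-corrected
#' isotherm.
#'
#' @param n_max_per_particle Maximum adsorbed proteins per particle.
#' @param number_density Particles per litre (1/L).
#' @return Capacity in mol/L.
#' @examples
#' capacity_per_volume(244, 4.55e14)  # ~1.84e-7 mol/L
#' @export
capacity_per_volume <- function(n_max_per_particle, number_density) {
  stopifnot(is.numeric(n_max_per_particle), all(n_max_per_particle > 0),
            is.numeric(number_density), all(number_density > 0))
  n_max_per_particle * number_density / .const$N_A
}

#' Convert a per-volume capacity back to a per-particle count
#'
#' Exact inverse of [capacity_per_volume()].
#'
#' @param n_max_vol Capacity (mol/L).
#' @param number_density Particles per litre (1/L).
#' @return Count per particle.
#' @export
capacity_per_particle <- function(n_max_vol, number_density) {
  stopifnot(is.numeric(n_max_vol), all(n_max_vol > 0),
            is.numeric(number_density), all(number_density > 0))
  n_max_vol * .const$N_A / number_density
}

# bare closed-form root, shared by the user-facing wrapper and the fit
# residuals (which call it in a tight loop)
.langmuir_adsorbed <- function(c_total, k_app, n_max_vol) {
  s <- c_total + n_max_vol + 1 / k_app
  disc <- s^2 - 4 * c_total * n_max_vol
  # disc >= (c_total - n_max_vol)^2 > 0 analytically; clamp roundoff
  2 * c_total * n_max_vol / (s + sqrt(pmax(disc, 0)))
}

#' Langmuir coverage with bulk depletion
#'
#' Solves the coupled monolayer-adsorption / mass-balance system
#' \deqn{adsorbed = N_{max} K c_{free} / (1 + K c_{free}), \quad
#'       c_{free} = c_{total} - adsorbed}
#' in closed form. The physical root of the resulting quadratic is
#' evaluated in the cancellation-free form
#' `adsorbed = 2 c_total N_max / (S + sqrt(S^2 - 4 c_total N_max))` with
#' `S = c_total + N_max + 1/K`, which stays accurate when the
#' discriminant is small (the strong-binding, strong-depletion regime
#' `c_total ~ N_max`, `K c_total >> 1`).
#'
#' @param c_total Total adsorbate concentration (mol/L); vectorised.
#' @param k_app Apparent binding constant (1/M), > 0.
#' @param n_max_vol Volumetric monolayer capacity (mol/L), > 0.
#' @return A `coverage_result` data frame with columns `c_total`, `theta`
#'   (fractional coverage), `adsorbed` and `free` (mol/L). Mass balance
#'   `adsorbed + free = c_total` holds to machine precision.
#' @examples
#' coverage_with_depletion(1e-7, k_app = 3.3e9, n_max_vol = 1.844e-7)
#' @export
coverage_with_depletion <- function(c_total, k_app, n_max_vol) {
  stopifnot(is.numeric(c_total), all(is.finite(c_total)),
            is.numeric(k_app), length(k_app) == 1L, is.finite(k_app), k_app > 0,
            is.numeric(n_max_vol), length(n_max_vol) == 1L,
            is.finite(n_max_vol), n_max_vol > 0)
  if (any(c_total < 0))
    stop("negative total concentration", call. = FALSE)
  adsorbed <- .langmuir_adsorbed(c_total, k_app, n_max_vol)
  free <- c_total - adsorbed
  out <- data.frame(c_total = c_total, theta = adsorbed / n_max_vol,
                    adsorbed = adsorbed, free = free)
  class(out) <- c("coverage_result", class(out))
  out
}

#' Surface charge density after adsorption of charged proteins
#'
#' Linear charge bookkeeping on the sphere surface: at full coverage the
#' adsorbed monolayer carries `N_max |z_p|` elementary charges spread
#' over the particle surface, of which a fraction `eta` (the effective
#' charge-screening efficiency) acts to screen the bare surface charge:
#' \deqn{\sigma(\theta) = \sigma_{bare} - \eta\,\theta\,
#'   \frac{N_{max} |z_p| e}{\pi D^2}\,\mathrm{sign}(\sigma_{bare}).}
#' The protein term always opposes the bare charge because the magnitude
#' of the surface potential is observed to decrease upon adsorption even
#' for like-charged proteins (counterion rearrangement is not tracked
#' microscopically); `eta` in \[0, 1\] can be calibrated with
#' [charge_efficiency_from_endpoints()] so that full coverage reproduces
#' a measured saturated zeta potential.
#'
#' @param theta Fractional coverage in \[0, 1\]; vectorised.
#' @param bare_sigma Bare surface charge density (C/m^2).
#' @param protein A [protein_spec()].
#' @param n_max_per_particle Monolayer capacity per particle.
#' @param diameter Particle diameter (m).
#' @param efficiency Charge-screening efficiency eta in \[0, 1\], default 1.
#' @return Surface charge density (C/m^2), linear in `theta`.
#' @export
surface_charge_after_adsorption <- function(theta, bare_sigma, protein,
                                            n_max_per_particle, diameter,
                                            efficiency = 1) {
  stopifnot(is.numeric(theta), all(theta >= 0), all(theta <= 1),
            inherits(protein, "protein_spec"),
            is.numeric(efficiency), efficiency >= 0, efficiency <= 1)
  bare_sigma - efficiency * theta * sign(bare_sigma) *
    (n_max_per_particle * abs(protein$net_valence) * .const$e) /
    (pi * diameter^2)
}

#' Calibrate the charge-screening efficiency from potential endpoints
#'
#' Solves [surface_charge_after_adsorption()] at full coverage for the
#' efficiency that maps a bare surface charge density onto a saturated
#' one (both obtained from measured potentials through the sphere
#' charge-potential relation).
#'
#' @param bare_sigma,saturated_sigma Surface charge densities (C/m^2)
#'   before and at full monolayer coverage; same sign, with
#'   `|saturated_sigma| <= |bare_sigma|`.
#' @param protein A [protein_spec()].
#' @param n_max_per_particle Monolayer capacity per particle.
#' @param diameter Particle diameter (m).
#' @return Efficiency eta; errors if outside \[0, 1\] (the monolayer
#'   cannot screen that much charge).
#' @export
charge_efficiency_from_endpoints <- function(bare_sigma, saturated_sigma,
                                             protein, n_max_per_particle,
                                             diameter) {
  stopifnot(inherits(protein, "protein_spec"))
  full <- n_max_per_particle * abs(protein$net_valence) * .const$e /
    (pi * diameter^2)
  eta <- (bare_sigma - saturated_sigma) * sign(bare_sigma) / full
  if (eta < 0 || eta > 1)
    stop(sprintf("calibrated efficiency %.3g outside [0, 1]", eta),
         call. = FALSE)
  eta
}

#' Apparent Gibbs free energy from an apparent binding constant
#'
#' DeltaG_app = -R T ln(K_app c0) with standard state c0 (default 1 mol/L).
#' The alternative solvent-molarity convention (c0 = 55.5 mol/L for water)
#' is available through `standard_state_M`.
#'
#' @param k_app Apparent binding constant (1/M), > 0; vectorised.
#' @param temperature Absolute temperature (K), default 298.15.
#' @param standard_state_M Standard-state concentration c0 (mol/L),
#'   default 1.
#' @return Gibbs free energy (J/mol); negative for `k_app * c0 > 1`.
#' @examples
#' gibbs_from_k(19e8) / 1000  # about -53.0 kJ/mol
#' @export
gibbs_from_k <- function(k_app, temperature = 298.15, standard_state_M = 1) {
  stopifnot(is.numeric(k_app), all(is.finite(k_app)))
  if (any(k_app <= 0)) stop("k_app must be > 0", call. = FALSE)
  -.const$R_gas * temperature * log(k_app * standard_state_M)
}

#' First-order uncertainty of the apparent Gibbs free energy
#'
#' Propagates the uncertainty of the binding constant through the
#' logarithm: delta(DeltaG) = R T dK/K.
#'
#' @param k_app Apparent binding constant (1/M).
#' @param dk_app Its standard uncertainty (1/M), >= 0.
#' @param temperature Absolute temperature (K), default 298.15.
#' @return Uncertainty (J/mol).
#' @examples
#' gibbs_uncertainty(270e8, 170e8) / 1000  # ~1.6 kJ/mol
#' @export
gibbs_uncertainty <- function(k_app, dk_app, temperature = 298.15) {
  stopifnot(is.numeric(k_app), all(k_app > 0),
            is.numeric(dk_app), all(dk_app >= 0))
  .const$R_gas * temperature * dk_app / k_app
}

#' Mean surface area per adsorbed protein
#'
#' pi D^2 / N_max: the sphere surface area divided by the monolayer
#' capacity.
#'
#' @param n_max_per_particle Monolayer capacity per particle.
#' @param diameter Particle diameter (m).
#' @return Area per protein in nm^2.
#' @examples
#' area_per_protein(244, 100e-9)  # ~129 nm^2
#' @export
area_per_protein <- function(n_max_per_particle, diameter) {
  stopifnot(is.numeric(n_max_per_particle), all(n_max_per_particle > 0),
            is.numeric(diameter), all(diameter > 0))
  pi * (diameter * 1e9)^2 / n_max_per_particle
}
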