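# Charge-potential relations of the diffuse electrical double layer:
# Debye screening, the planar Grahame equation, the Ohshima sphere
# approximation, its numerical inverse, and the linearised map used when
# converting surface-potential changes into surface-charge changes.

#' Debye screening parameter and Debye length
#'
#' Computes the inverse Debye length of a symmetric z:z electrolyte,
#' kappa = sqrt(2 N_A e^2 z^2 (1000 c) / (eps0 eps_r k_B T)), with c the
#' bulk concentration in mol/L.
#'
#' @param cond A [solution_conditions()] object with
#'   `ionic_concentration > 0`.
#' @return A list with `kappa` (1/m) and `debye_length` (m).
#' @examples
#' debye_parameter(solution_conditions(1e-3))$debye_length * 1e9  # ~9.6 nm
#' @export
debye_parameter <- function(cond) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (cond$ionic_concentration <= 0)
    stop("Debye length undefined: ionic_concentration must be > 0 (mol/L)",
         call. = FALSE)
  k <- with(.const, sqrt(
    2 * N_A * e^2 * cond$electrolyte_valence^2 * (1000 * cond$ionic_concentration) /
      (eps0 * cond$relative_permittivity * k_B * cond$temperature)))
  list(kappa = k, debye_length = 1 / k)
}

#' Planar Grahame equation: charge density from surface potential
#'
#' sigma = (2 eps0 eps_r kappa k_B T / (z e)) * sinh(z e phi / (2 k_B T)).
#' Odd in `phi`; reduces to the Debye-Hueckel capacitance
#' eps0 eps_r kappa per unit potential for small potentials.
#'
#' @param phi Surface potential (V); vectorised.
#' @param cond A [solution_conditions()] object.
#' @return Surface charge density (C/m^2).
#' @examples
#' sigma_from_potential_planar(-42e-3, solution_conditions(1e-3))  # ~ -3.4e-3
#' @export
sigma_from_potential_planar <- function(phi, cond) {
  stopifnot(inherits(cond, "solution_conditions"), is.numeric(phi),
            all(is.finite(phi)))
  k <- debye_parameter(cond)$kappa
  kT <- .const$k_B * cond$temperature
  ze <- cond$electrolyte_valence * .const$e
  (2 * .const$eps0 * cond$relative_permittivity * k * kT / ze) *
    sinh(ze * phi / (2 * kT))
}

#' Planar Grahame equation: surface potential from charge density
#'
#' Closed-form inverse of [sigma_from_potential_planar()] via the inverse
#' hyperbolic sine.
#'
#' @param sigma Surface charge density (C/m^2); vectorised.
#' @param cond A [solution_conditions()] object.
#' @return Surface potential (V).
#' @export
potential_from_sigma_planar <- function(sigma, cond) {
  stopifnot(inherits(cond, "solution_conditions"), is.numeric(sigma),
            all(is.finite(sigma)))
  k <- debye_parameter(cond)$kappa
  kT <- .const$k_B * cond$temperature
  ze <- cond$electrolyte_valence * .const$e
  (2 * kT / ze) *
    asinh(sigma * ze / (2 * .const$eps0 * cond$relative_permittivity * k * kT))
}

# Ohshima-Healy-White bracket of the sphere relation, with the y -> 0
# limit of the third term (-> 1/(kR)^2) taken analytically to avoid 0/0.
.ohshima_bracket <- function(y, kR) {
  t2 <- (1 / kR) * 2 / cosh(y / 4)^2
  t3 <- ifelse(abs(y) < 1e-5,
               1 / kR^2,
               (1 / kR^2) * 8 * log(cosh(y / 4)) / sinh(y / 2)^2)
  1 + t2 + t3
}

#' Ohshima sphere approximation: charge density from surface potential
#'
#' Empirical closed-form relation between the surface potential and the
#' surface charge density of a sphere of radius R in a symmetric z:z
#' electrolyte (Ohshima-Healy-White), accurate over a wide kappa*R range:
#'
#' sigma = (2 eps0 eps_r kappa k_B T/(z e)) sinh(y/2) *
#'   sqrt(1 + (1/(kR)) 2/cosh^2(y/4) + (1/(kR)^2) 8 ln cosh(y/4)/sinh^2(y/2)),
#'
#' with y = z e phi/(k_B T) the reduced potential. Odd in `phi`. The
#' small-potential limit is the exact Debye-Hueckel sphere capacitance
#' eps0 eps_r (1 + kappa R)/R per unit potential; the large kappa*R limit
#' is the planar Grahame relation.
#'
#' @param phi Surface potential (V); vectorised.
#' @param radius Sphere radius (m), > 0.
#' @param cond A [solution_conditions()] object.
#' @return Surface charge density (C/m^2).
#' @examples
#' # 100 nm particle at its measured zeta potential, 1 mM 1:1 electrolyte
#' sigma_from_potential_sphere(-42e-3, 50e-9, solution_conditions(1e-3)) * 1e3
#' @export
sigma_from_potential_sphere <- function(phi, radius, cond) {
  stopifnot(inherits(cond, "solution_conditions"), is.numeric(phi),
            all(is.finite(phi)),
            is.numeric(radius), length(radius) == 1L, is.finite(radius),
            radius > 0)
  k <- debye_parameter(cond)$kappa
  kT <- .const$k_B * cond$temperature
  ze <- cond$electrolyte_valence * .const$e
  y <- ze * phi / kT
  (2 * .const$eps0 * cond$relative_permittivity * k * kT / ze) *
    sinh(y / 2) * sqrt(.ohshima_bracket(y, k * radius))
}

#' Surface potential of a sphere from its charge density
#'
#' Numerical inverse of [sigma_from_potential_sphere()] (no closed-form
#' inverse exists). The relation is odd and strictly monotone, so the
#' root is found by safeguarded bracketing (`uniroot` with interval
#' extension) followed by Newton polishing to drive the residual in sigma
#' below 1e-10 relative.
#'
#' @param sigma Surface charge density (C/m^2); vectorised.
#' @param radius Sphere radius (m).
#' @param cond A [solution_conditions()] object.
#' @return Surface potential (V).
#' @export
potential_from_sigma_sphere <- function(sigma, radius, cond) {
  stopifnot(inherits(cond, "solution_conditions"), is.numeric(sigma),
            all(is.finite(sigma)))
  k <- debye_parameter(cond)$kappa
  cap_dh <- .const$eps0 * cond$relative_permittivity * (1 + k * radius) / radius
  vapply(sigma, function(s) {
    if (s == 0) return(0)
    f <- function(p) sigma_from_potential_sphere(p, radius, cond) - s
    # the sphere relation is superlinear, so |phi| <= |s|/cap_dh brackets
    phi_dh <- s / cap_dh
    lo <- min(0, phi_dh); hi <- max(0, phi_dh)
    r <- tryCatch(
      stats::uniroot(f, c(lo, hi), extendInt = "upX",
                     tol = .Machine$double.eps^0.75, maxiter = 2000L)$root,
      error = function(e)
        stop(sprintf(
          "bracket inversion failed for sigma = %g C/m^2 (kappa*R = %g): %s",
          s, k * radius, conditionMessage(e)), call. = FALSE))
    # Newton polish with numerical derivative
    for (i in 1:4) {
      fr <- f(r)
      if (abs(fr) <= 1e-12 * abs(s)) break
      h <- max(abs(r), 1e-6) * 1e-7
      dfr <- (f(r + h) - f(r - h)) / (2 * h)
      if (!is.finite(dfr) || dfr == 0) break
      r <- r - fr / dfr
    }
    if (abs(f(r)) > 1e-10 * abs(s))
      stop(sprintf("inversion residual %g exceeds tolerance for sigma = %g",
                   abs(f(r)), s), call. = FALSE)
    r
  }, numeric(1))
}

#' Linear charge-potential map for a sphere
#'
#' Least-squares slope of the Ohshima sphere relation over a uniform grid
#' of potentials in `[-phi_range, +phi_range]`. Odd symmetry forces a zero
#' intercept, so the slope is the single linear coefficient. This is the
#' linear approximation used when converting potential changes upon
#' adsorption into charge-density changes.
#'
#' @param radius Sphere radius (m).
#' @param cond A [solution_conditions()] object.
#' @param phi_range Half-width of the potential window (V); default 0.150.
#' @param n_grid Number of grid points (default 201).
#' @return Slope (C/m^2 per V).
#' @export
linear_map_coefficient <- function(radius, cond, phi_range = 0.150,
                                   n_grid = 201L) {
  stopifnot(is.numeric(phi_range), length(phi_range) == 1L, phi_range > 0)
  phi <- seq(-phi_range, phi_range, length.out = n_grid)
  sig <- sigma_from_potential_sphere(phi, radius, cond)
  sum(phi * sig) / sum(phi * phi)
}

#' Surface state (potential and charge density pair)
#'
#' Couples a surface potential with the consistent surface charge density.
#' The charge-potential relation is odd and monotone, so the two always
#' share a sign (or are both zero); the constructor enforces this.
#'
#' @param potential Surface potential (V).
#' @param charge_density Surface charge density (C/m^2).
#' @return An object of class `surface_state`.
#' @export
surface_state <- function(potential, charge_density) {
  stopifnot(is.numeric(potential), is.finite(potential),
            is.numeric(charge_density), is.finite(charge_density))
  if (sign(potential) * sign(charge_density) < 0)
    stop("potential and charge_density must share a sign (odd monotone relation)",
         call. = FALSE)
  structure(list(potential = as.numeric(potential),
                 charge_density = as.numeric(charge_density)),
            class = "surface_state")
}

#' @export
print.surface_state <- function(x, ...) {
  cat(sprintf("<surface_state> Phi0 = %.4g mV, sigma0 = %.4g mC/m^2\n",
              x$potential * 1e3, x$charge_density * 1e3))
  invisible(x)
}

#' Convert a measured zeta potential to a surface charge density
#'
#' Treats the zeta potential as equal to the surface potential (an
#' approximation: the slip plane sits outside the surface) and applies
#' the Ohshima sphere relation. The approximation is recorded in the
#' result's metadata.
#'
#' @param particle A [nanoparticle_spec()] with a `zeta_potential`.
#' @param cond A [solution_conditions()] object.
#' @return A [surface_state()] with attribute `approximation`.
#' @examples
#' ps <- nanoparticle_spec(100e-9, 4.55e14, zeta_potential = -42e-3)
#' zeta_to_sigma(ps, solution_conditions(1e-3))
#' @export
zeta_to_sigma <- function(particle, cond) {
  stopifnot(inherits(particle, "nanoparticle_spec"))
  if (is.null(particle$zeta_potential))
    stop("particle has no zeta_potential", call. = FALSE)
  s <- sigma_from_potential_sphere(particle$zeta_potential,
                                   particle$diameter / 2, cond)
  out <- surface_state(particle$zeta_potential, s)
  attr(out, "approximation") <- "zeta potential taken equal to surface potential"
  out
}
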