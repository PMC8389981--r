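# Nonresonant SHS forward model in the nonlinear Rayleigh-Gans-Debye
# (RGD) framework: scattering wave vector, surface form factors built
# from normal-projection moments of the sphere, the bulk chi(3) form
# factor weighted by the static double-layer field, angle-resolved
# patterns and the fixed-angle titration response.

# Spherical Bessel functions j0..j3 with series forms near zero to avoid
# catastrophic cancellation in the closed-form expressions.
sph_bessel_j <- function(n, x) {
  stopifnot(n %in% 0:3)
  x <- as.numeric(x)
  out <- numeric(length(x))
  small <- abs(x) < 1e-2
  xs <- x[small]; xl <- x[big <- !small]
  if (n == 0) {
    out[small] <- 1 - xs^2 / 6 + xs^4 / 120
    out[big] <- sin(xl) / xl
  } else if (n == 1) {
    out[small] <- xs / 3 - xs^3 / 30 + xs^5 / 840
    out[big] <- sin(xl) / xl^2 - cos(xl) / xl
  } else if (n == 2) {
    out[small] <- xs^2 / 15 - xs^4 / 210
    out[big] <- (3 / xl^3 - 1 / xl) * sin(xl) - 3 * cos(xl) / xl^2
  } else {
    out[small] <- xs^3 / 105 - xs^5 / 1890
    out[big] <- (15 / xl^4 - 6 / xl^2) * sin(xl) -
      (15 / xl^3 - 1 / xl) * cos(xl)
  }
  out
}

#' Scattering geometry
#'
#' @param scattering_angle In-plane scattering angle (degrees), in (0, 180).
#' @param polarization One of `"ppp"` or `"pss"` (output, then input
#'   polarizations; p = in-plane, s = out-of-plane).
#' @param fundamental_wavelength Fundamental wavelength (m); default
#'   1028 nm.
#' @param medium_refractive_index Refractive index of the dispersion
#'   medium; default 1.33 (water), taken dispersionless.
#' @return An object of class `scattering_geometry`.
#' @export
scattering_geometry <- function(scattering_angle, polarization = c("ppp", "pss"),
                                fundamental_wavelength = 1028e-9,
                                medium_refractive_index = 1.33) {
  polarization <- match.arg(polarization)
  stopifnot(is.numeric(scattering_angle), all(scattering_angle > 0),
            all(scattering_angle < 180),
            fundamental_wavelength > 0, medium_refractive_index > 0)
  structure(list(scattering_angle = as.numeric(scattering_angle),
                 polarization = polarization,
                 fundamental_wavelength = as.numeric(fundamental_wavelength),
                 medium_refractive_index = as.numeric(medium_refractive_index)),
            class = "scattering_geometry")
}

#' Scattering wave vector magnitude
#'
#' For second-harmonic scattering with a dispersionless medium the
#' incoming and outgoing wave vectors at 2w have equal magnitude
#' 4 pi n / lambda, so q = (8 pi n / lambda) sin(theta/2).
#'
#' @param geometry A [scattering_geometry()], or a numeric angle in
#'   degrees together with `wavelength` and `refractive_index`.
#' @param wavelength,refractive_index Used when `geometry` is numeric.
#' @return q (1/m), vectorised over the angle.
#' @examples
#' scattering_q(scattering_geometry(40))  # ~1.11e7 1/m
#' @export
scattering_q <- function(geometry, wavelength = 1028e-9,
                         refractive_index = 1.33) {
  if (inherits(geometry, "scattering_geometry")) {
    ang <- geometry$scattering_angle
    wavelength <- geometry$fundamental_wavelength
    refractive_index <- geometry$medium_refractive_index
  } else {
    ang <- geometry
  }
  (8 * pi * refractive_index / wavelength) * sin(ang * pi / 360)
}

#' Surface form factor of a sphere (normal-projection moments)
#'
#' Evaluates the surface integral of exp(i q.r) times the m-th power of
#' the normal projection onto the scattering direction,
#' \deqn{F_m(qR) = \int_S e^{i q \cdot r} (\hat n \cdot \hat q)^m \, dS,}
#' in closed form in spherical Bessel functions:
#' \itemize{
#'   \item m = 0: `4 pi R^2 j0(qR)`
#'   \item m = 1: `4 pi R^2 i j1(qR)`
#'   \item m = 2: `(4 pi R^2 / 3) (j0(qR) - 2 j2(qR))`
#'   \item m = 3: `(4 pi R^2 / 5) i (3 j1(qR) - 2 j3(qR))`
#' }
#' At q = 0 the order-0 moment is the total surface area and the odd
#' moments vanish by symmetry.
#'
#' @param qR Dimensionless product of wave vector and radius, >= 0;
#'   vectorised.
#' @param order Moment order m in 0..3.
#' @param radius Sphere radius (m), default 1 (form factor per unit
#'   radius squared).
#' @return Complex amplitude(s).
#' @export
surface_form_factor <- function(qR, order = 0L, radius = 1) {
  stopifnot(is.numeric(qR), all(qR >= 0), order %in% 0:3, radius > 0)
  a <- 4 * pi * radius^2
  switch(as.character(order),
    "0" = complex(real = a * sph_bessel_j(0, qR), imaginary = 0),
    "1" = complex(real = 0, imaginary = a * sph_bessel_j(1, qR)),
    "2" = complex(real = (a / 3) * (sph_bessel_j(0, qR) - 2 * sph_bessel_j(2, qR)),
                  imaginary = 0),
    "3" = complex(real = 0,
                  imaginary = (a / 5) * (3 * sph_bessel_j(1, qR) -
                                           2 * sph_bessel_j(3, qR))))
}

# Angular channel weights: the polarization-resolved tensor contraction is
# reduced to two scalar channels built from normal-projection moments.
# ppp uses the longitudinal projection (weight mu), pss the transverse
# projection (weight mu (1 - mu^2)); their angular integrals are
# 4 pi i j1(x) and 4 pi i (2/5)(j1(x) + j3(x)) respectively.
.channel_weight <- function(x, polarization) {
  if (polarization == "ppp") sph_bessel_j(1, x)
  else 0.4 * (sph_bessel_j(1, x) + sph_bessel_j(3, x))
}

#' Bulk chi(3) form factor of the diffuse double layer
#'
#' Volume integral over r > R of exp(i q.r) weighted by the radial static
#' field of the linearised (Debye-Hueckel) double-layer potential
#' `Phi(r) = Phi0 (R/r) exp(-kappa (r - R))`, i.e.
#' `E_r(r) = Phi0 R exp(-kappa (r - R)) (1/r^2 + kappa/r)`.
#' The angular integral reduces to the channel weight (j1 for the
#' longitudinal ppp channel), leaving a one-dimensional radial integral
#' \deqn{F_3 = 4\pi i \int_R^{R + 20/\kappa} w(qr)\, E_r(r)\, r^2 \, dr,}
#' evaluated by composite Simpson quadrature with the node count scaled
#' to the number of oscillations of w(qr); the exponential tail beyond
#' 20 Debye lengths is below 3e-9 of the integral and is truncated.
#'
#' The returned amplitude is linear in `phi0` and vanishes for an
#' uncharged surface.
#'
#' @param kappa Inverse Debye length (1/m), > 0.
#' @param q Scattering wave vector (1/m), >= 0.
#' @param radius Sphere radius (m).
#' @param phi0 Surface potential (V).
#' @param polarization Channel, `"ppp"` (default) or `"pss"`.
#' @return Complex amplitude (V m^2).
#' @export
bulk_chi3_form_factor <- function(kappa, q, radius, phi0,
                                  polarization = c("ppp", "pss")) {
  polarization <- match.arg(polarization)
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(q), length(q) == 1L, q >= 0,
            is.numeric(radius), radius > 0,
            is.numeric(phi0), is.finite(phi0))
  if (phi0 == 0 || q == 0)
    return(complex(real = 0, imaginary = 0))
  rmax <- radius + 20 / kappa
  # resolve both the oscillation of w(qr) and the exp(-kappa r) decay
  n_osc <- q * (rmax - radius) / (2 * pi)
  n <- max(801L, as.integer(2 * ceiling(40 * n_osc + 40 * 20) + 1L))
  if (n %% 2L == 0L) n <- n + 1L
  r <- seq(radius, rmax, length.out = n)
  er <- phi0 * radius * exp(-kappa * (r - radius)) * (1 / r^2 + kappa / r)
  f <- .channel_weight(q * r, polarization) * er * r^2
  h <- (rmax - radius) / (n - 1L)
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1
  int <- sum(w * f) * h / 3
  complex(real = 0, imaginary = 4 * pi * int)
}

#' Optical amplitudes of the SHS forward model
#'
#' @param chi2 Effective surface second-order susceptibility amplitude
#'   (arbitrary units, real).
#' @param chi3 Effective bulk third-order amplitude per volt (arbitrary
#'   units, real); couples to the static double-layer field.
#' @param phase Relative phase between the two contributions (radians,
#'   in \[0, 2 pi)); default 0 (nonresonant conditions).
#' @param background Flat additive hyper-Rayleigh background of the
#'   solvent; default 0.
#' @return An object of class `optical_amplitudes`.
#' @export
optical_amplitudes <- function(chi2 = 1, chi3 = 2e4, phase = 0,
                               background = 0) {
  stopifnot(is.numeric(chi2), is.finite(chi2),
            is.numeric(chi3), is.finite(chi3),
            is.numeric(phase), phase >= 0, phase < 2 * pi,
            is.numeric(background), background >= 0)
  structure(list(chi2 = as.numeric(chi2), chi3 = as.numeric(chi3),
                 phase = as.numeric(phase),
                 background = as.numeric(background)),
            class = "optical_amplitudes")
}

#' Angle-resolved SHS pattern of a charged sphere dispersion
#'
#' Single-particle coherent amplitude
#' \deqn{A(\theta) = F_{surf}(qR)\,\chi_2 + e^{i\varphi} F_3(\kappa R, qR)\,\chi_3,}
#' with the bulk form factor carrying the surface potential; the
#' intensity is `|A|^2` times the particle number density (incoherent
#' sum over particles). The surface potential is taken from the
#' particle's zeta potential when present, otherwise it must be supplied.
#'
#' @param amplitudes An [optical_amplitudes()] object.
#' @param particle A [nanoparticle_spec()].
#' @param cond A [solution_conditions()] with nonzero ionic strength.
#' @param angles Scattering angles (degrees), default `seq(5, 175, 1)`.
#' @param polarization `"ppp"` or `"pss"`.
#' @param phi0 Surface potential (V); defaults to the particle's zeta
#'   potential.
#' @param wavelength,refractive_index Optical constants; defaults 1028 nm
#'   and 1.33.
#' @return A data frame of class `shs_pattern` with columns `angle` and
#'   `intensity`, and attribute `peak_angle` (angle of maximum intensity).
#' @export
shs_pattern <- function(amplitudes, particle, cond,
                        angles = seq(5, 175, by = 1),
                        polarization = c("ppp", "pss"),
                        phi0 = particle$zeta_potential,
                        wavelength = 1028e-9, refractive_index = 1.33) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(amplitudes, "optical_amplitudes"),
            inherits(particle, "nanoparticle_spec"),
            inherits(cond, "solution_conditions"))
  if (is.null(phi0)) stop("no surface potential: supply `phi0` or a particle zeta potential",
                          call. = FALSE)
  kappa <- debye_parameter(cond)$kappa
  R <- particle$diameter / 2
  q <- scattering_q(angles, wavelength, refractive_index)
  # same angular channel weight as the bulk term (j1 longitudinal for ppp,
  # (2/5)(j1 + j3) transverse for pss); order-1 moment in the ppp case
  a_surf <- complex(imaginary = 4 * pi * R^2 * .channel_weight(q * R, polarization))
  a_bulk <- vapply(q, function(qi)
    bulk_chi3_form_factor(kappa, qi, R, phi0, polarization), complex(1))
  amp <- a_surf * amplitudes$chi2 +
    exp(1i * amplitudes$phase) * a_bulk * amplitudes$chi3
  intensity <- particle$number_density * Mod(amp)^2 + amplitudes$background
  out <- data.frame(angle = angles, intensity = intensity)
  class(out) <- c("shs_pattern", class(out))
  attr(out, "peak_angle") <- angles[which.max(intensity)]
  attr(out, "polarization") <- polarization
  out
}

#' Fixed-angle titration intensity from fractional coverage
#'
#' At a fixed scattering angle and ionic strength the form factors reduce
#' to constants, and the titration response is parameterised by the bare
#' and saturated intensities. Two link models are available:
#' \itemize{
#'   \item `"field_linear"` (default): the scattered field, not the
#'     intensity, is linear in coverage: `sqrt(I) = a - b theta` with
#'     `a = sqrt(I0)`, `b = sqrt(I0) - sqrt(I_sat)`, so
#'     `I(theta) = (a - b theta)^2` (convex in theta).
#'   \item `"intensity_linear"`: `I(theta) = I0 - (I0 - I_sat) theta`.
#' }
#' `I_sat > I0` (charge-increasing adsorbates) is allowed but flagged
#' with a warning.
#'
#' @param theta Fractional coverage in \[0, 1\]; vectorised.
#' @param i0 Intensity at zero coverage (arb), >= 0.
#' @param i_sat Intensity at full coverage (arb), >= 0.
#' @param link `"field_linear"` or `"intensity_linear"`.
#' @return Intensity (arbitrary units).
#' @examples
#' titration_intensity(0.5, i0 = 1, i_sat = 0)  # 0.25 under field_linear
#' @export
titration_intensity <- function(theta, i0, i_sat,
                                link = c("field_linear", "intensity_linear")) {
  link <- match.arg(link)
  stopifnot(is.numeric(theta), all(theta >= 0), all(theta <= 1),
            is.numeric(i0), i0 >= 0, is.numeric(i_sat), i_sat >= 0)
  if (i_sat > i0)
    warning("i_sat > i0: charge-increasing adsorption", call. = FALSE)
  if (link == "field_linear") {
    a <- sqrt(i0); b <- sqrt(i0) - sqrt(i_sat)
    (a - b * theta)^2
  } else {
    i0 - (i0 - i_sat) * theta
  }
}
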