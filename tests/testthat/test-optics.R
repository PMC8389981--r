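test_that("scattering wave vector follows the second-harmonic geometry", {
  expect_identical(scattering_q(0), 0)
  expect_equal(scattering_q(180), 8 * pi * 1.33 / 1028e-9, tolerance = 1e-14)
  expect_equal(scattering_q(40), 1.112116e7, tolerance = 1e-6)
  g <- scattering_geometry(40)
  expect_equal(scattering_q(g), scattering_q(40), tolerance = 1e-14)
  expect_error(scattering_geometry(0))
  expect_error(scattering_geometry(90, polarization = "sps"))
})

test_that("surface form factors agree with direct quadrature of the sphere", {
  R <- 50e-9
  expect_equal(surface_form_factor(0, 0, R), complex(real = 4 * pi * R^2),
               tolerance = 1e-15)
  for (ord in 1:3)
    expect_equal(Mod(surface_form_factor(0, ord, R))[1],
                 if (ord == 2) 4 * pi * R^2 / 3 else 0, tolerance = 1e-15)
  # values chosen away from Bessel zeros; strict relative agreement
  for (qR in c(0.3, 1.7, 5.2, 12.9, 27.3, 49.7)) {
    for (ord in 0:3) {
      oracle <- quad_surface_moment(qR, ord, R)
      got <- surface_form_factor(qR, ord, R)
      expect_lt(Mod(got - oracle),
                1e-6 * max(Mod(oracle), 1e-9 * 4 * pi * R^2))
    }
  }
})

test_that("form factors stay accurate on a dense grid up to qR = 50", {
  R <- 1
  for (ord in 0:3) {
    qR <- seq(0.05, 50, length.out = 61)
    oracle <- vapply(qR, quad_surface_moment, complex(1), order = ord)
    got <- surface_form_factor(qR, ord)
    # mixed tolerance: relative away from zeros, absolute at the scale of
    # the area near them
    expect_true(all(Mod(got - oracle) <=
                      1e-6 * pmax(Mod(oracle), 1e-3 * 4 * pi)))
  }
})

test_that("bulk chi(3) form factor: null cases, linearity, screening", {
  kap <- 1e8
  expect_identical(bulk_chi3_form_factor(kap, 1e7, 50e-9, 0),
                   complex(real = 0, imaginary = 0))
  expect_identical(bulk_chi3_form_factor(kap, 0, 50e-9, -0.05),
                   complex(real = 0, imaginary = 0))
  f1 <- bulk_chi3_form_factor(kap, 1.1e7, 50e-9, -0.02)
  f2 <- bulk_chi3_form_factor(kap, 1.1e7, 50e-9, -0.04)
  expect_equal(f2, 2 * f1, tolerance = 1e-10)
  # thinner diffuse layer carries less aligned volume
  R <- 50e-9; qR <- 1.2
  lo <- bulk_chi3_form_factor(0.1 / R, qR / R, R, -0.05)
  hi <- bulk_chi3_form_factor(10 / R, qR / R, R, -0.05)
  expect_gt(Mod(lo), Mod(hi))
})

test_that("bulk chi(3) radial reduction matches brute-force quadrature", {
  R <- 50e-9
  cases <- list(c(kR = 2, qR = 1.5), c(kR = 10, qR = 3), c(kR = 0.5, qR = 0.8))
  for (cs in cases) {
    kap <- cs[["kR"]] / R; q <- cs[["qR"]] / R
    got <- bulk_chi3_form_factor(kap, q, R, -0.042)
    oracle <- chi3_brute(kap, q, R, -0.042)
    expect_lt(Mod(got - oracle), 1e-4 * Mod(oracle))
  }
})

test_that("pattern: trivial zeros, quadratic amplitude scaling, phase invariance", {
  part <- nanoparticle_spec(100e-9, 4.55e14, -42e-3)
  cond <- solution_conditions(1e-4)
  dark <- shs_pattern(optical_amplitudes(chi2 = 0, chi3 = 0), part, cond,
                      angles = seq(10, 170, 20))
  expect_true(all(dark$intensity == 0))
  p1 <- shs_pattern(optical_amplitudes(1, 2e4), part, cond,
                    angles = seq(10, 170, 20))
  p3 <- shs_pattern(optical_amplitudes(3, 6e4), part, cond,
                    angles = seq(10, 170, 20))
  expect_equal(p3$intensity, 9 * p1$intensity, tolerance = 1e-10)
  # a common phase on both contributions cannot change |A|^2; the phase
  # slot rotates chi3 relative to chi2, so test at chi2 = 0
  pr <- shs_pattern(optical_amplitudes(0, 2e4, phase = 1.3), part, cond,
                    angles = seq(10, 170, 20))
  p0 <- shs_pattern(optical_amplitudes(0, 2e4), part, cond,
                    angles = seq(10, 170, 20))
  expect_equal(pr$intensity, p0$intensity, tolerance = 1e-10)
})

test_that("added salt dims the pattern and pushes the ppp maximum outward", {
  part <- nanoparticle_spec(100e-9, 4.55e14, -42e-3)
  sigma0 <- zeta_to_sigma(part, cond_1mM)$charge_density
  pats <- lapply(c(1e-5, 1e-3, 1e-2), function(cs) {
    cond <- solution_conditions(cs)
    phi <- potential_from_sigma_sphere(sigma0, 50e-9, cond)
    shs_pattern(optical_amplitudes(), part, cond, phi0 = phi)
  })
  peaks <- vapply(pats, function(p) max(p$intensity), numeric(1))
  expect_true(all(diff(peaks) < 0))
  angs <- vapply(pats, attr, numeric(1), "peak_angle")
  expect_true(all(diff(angs) >= 0))
  # screening bites hardest near the pattern maximum (vs 90 degrees)
  lo <- pats[[1]]; hi <- pats[[3]]; pk <- attr(lo, "peak_angle")
  drop_at <- function(a)
    1 - hi$intensity[hi$angle == a] / lo$intensity[lo$angle == a]
  expect_gte(drop_at(pk), drop_at(90))
})

test_that("titration intensity links: endpoints, convexity, residual signal", {
  th <- seq(0, 1, by = 0.1)
  for (lk in c("field_linear", "intensity_linear")) {
    expect_equal(titration_intensity(0, 1, 0.3, lk), 1, tolerance = 1e-15)
    expect_equal(titration_intensity(1, 1, 0.3, lk), 0.3, tolerance = 1e-15)
  }
  expect_equal(titration_intensity(0.5, 1, 0), 0.25, tolerance = 1e-15)
  i_field <- titration_intensity(th, 1, 0.3)
  i_lin <- titration_intensity(th, 1, 0.3, "intensity_linear")
  expect_true(all(diff(diff(i_field)) > 0))            # convex
  expect_equal(diff(diff(i_lin)), rep(0, 9), tolerance = 1e-14)  # affine
  # saturated but still charged surface keeps scattering
  expect_gt(titration_intensity(1, 1, 0.29), 0)
  expect_warning(titration_intensity(0.5, 1, 2), "charge-increasing")
})
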