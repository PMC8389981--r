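test_that("Debye length matches direct evaluation and the square-root law", {
  dl <- debye_parameter(cond_1mM)
  expect_equal(dl$debye_length, 9.613701e-9, tolerance = 1e-6)
  expect_equal(dl$kappa * dl$debye_length, 1, tolerance = 1e-14)
  expect_equal(debye_parameter(solution_conditions(1e-2))$debye_length,
               3.040119e-9, tolerance = 1e-6)
  # quadrupling the concentration exactly halves the Debye length
  l1 <- debye_parameter(solution_conditions(2.5e-4))$debye_length
  l4 <- debye_parameter(solution_conditions(1e-3))$debye_length
  expect_equal(l1 / l4, 2, tolerance = 1e-12)
})

test_that("zero ionic strength is a distinct, informative error", {
  pure <- solution_conditions(0)  # valid conditions
  expect_error(debye_parameter(pure), "ionic_concentration")
  expect_error(solution_conditions(-1e-3), "ionic_concentration")
  expect_error(solution_conditions(1e-3, temperature = -1))
})

test_that("planar Grahame relation: values, odd symmetry, DH limit, inverse", {
  expect_identical(sigma_from_potential_planar(0, cond_1mM), 0)
  expect_equal(sigma_from_potential_planar(-42e-3, cond_1mM),
               -3.381791e-3, tolerance = 1e-6)
  phi <- seq(-0.3, 0.3, by = 0.017)
  expect_equal(sigma_from_potential_planar(-phi, cond_1mM),
               -sigma_from_potential_planar(phi, cond_1mM), tolerance = 1e-15)
  # Debye-Hueckel capacitance limit
  cap <- physical_constants()$eps0 * 78.4 * debye_parameter(cond_1mM)$kappa
  for (p in c(-5e-3, -1e-3, 2e-3, 5e-3))
    expect_equal(sigma_from_potential_planar(p, cond_1mM) / p, cap,
                 tolerance = 5e-3)
  # closed-form inverse round trips
  for (p in c(-0.15, -0.042, 0.01, 0.2))
    expect_equal(potential_from_sigma_planar(
      sigma_from_potential_planar(p, cond_1mM), cond_1mM), p,
      tolerance = 1e-12)
  expect_identical(potential_from_sigma_planar(0, cond_1mM), 0)
  expect_equal(potential_from_sigma_planar(-3.381791e-3, cond_1mM),
               -42e-3, tolerance = 1e-6)
})

test_that("Ohshima sphere relation reproduces the measured-zeta conversion", {
  expect_equal(sigma_from_potential_sphere(-42e-3, 50e-9, cond_1mM),
               -3.9377e-3, tolerance = 1e-4)
  expect_identical(sigma_from_potential_sphere(0, 50e-9, cond_1mM), 0)
})

test_that("sphere relation: odd, monotone, above planar, correct limits", {
  phi <- seq(-0.3, 0.3, by = 0.0137)
  s <- sigma_from_potential_sphere(phi, 50e-9, cond_1mM)
  expect_equal(sigma_from_potential_sphere(-phi, 50e-9, cond_1mM), -s,
               tolerance = 1e-15)
  expect_true(all(diff(s) > 0))  # strict monotonicity enables bisection
  # curvature adds charge: sphere magnitude >= planar magnitude
  sp <- sigma_from_potential_planar(phi, cond_1mM)
  expect_true(all(abs(s) >= abs(sp) - 1e-18))
  # planar limit at kappa*R = 1e4
  R_big <- 1e4 * debye_parameter(cond_1mM)$debye_length
  expect_equal(sigma_from_potential_sphere(-0.1, R_big, cond_1mM),
               sigma_from_potential_planar(-0.1, cond_1mM), tolerance = 1e-3)
  # small-potential limit is the exact DH sphere capacitance
  kR <- debye_parameter(cond_1mM)$kappa * 50e-9
  cap_dh <- physical_constants()$eps0 * 78.4 * (1 + kR) / 50e-9
  for (p in c(-5e-3, 1e-3, 3e-3))
    expect_equal(sigma_from_potential_sphere(p, 50e-9, cond_1mM) / p,
                 cap_dh, tolerance = 5e-3)
})

test_that("sphere inversion round-trips and meets its residual tolerance", {
  expect_identical(potential_from_sigma_sphere(0, 50e-9, cond_1mM), 0)
  for (p in c(-0.15, -0.042, 0.05, 0.25)) {
    s <- sigma_from_potential_sphere(p, 50e-9, cond_1mM)
    expect_equal(potential_from_sigma_sphere(s, 50e-9, cond_1mM), p,
                 tolerance = 1e-8 / abs(p))
  }
  expect_equal(potential_from_sigma_sphere(-3.9377e-3, 50e-9, cond_1mM),
               -42e-3, tolerance = 1e-4)
  # residuals stay below 1e-10 relative up to 1 C/m^2
  for (s in c(-1, -0.1, -1e-3, 1e-6, 0.5, 1)) {
    p <- potential_from_sigma_sphere(s, 50e-9, cond_1mM)
    expect_lt(abs(sigma_from_potential_sphere(p, 50e-9, cond_1mM) - s),
              1e-10 * abs(s))
  }
})

test_that("linearised charge-potential map behaves like the DH capacitance", {
  cond_lo <- solution_conditions(1e-6)
  kR <- debye_parameter(cond_lo)$kappa * 50e-9
  cap_dh <- physical_constants()$eps0 * 78.4 * (1 + kR) / 50e-9
  expect_equal(linear_map_coefficient(50e-9, cond_lo, phi_range = 5e-3),
               cap_dh, tolerance = 5e-3)
  # screening steepens the map
  slopes <- vapply(c(1e-6, 1e-4, 1e-2), function(cs)
    linear_map_coefficient(50e-9, solution_conditions(cs)), numeric(1))
  expect_true(all(slopes > 0) && all(diff(slopes) > 0))
})

test_that("high-valence electrolyte pushes the sphere onto the planar curve", {
  cond44 <- solution_conditions(1e-6, electrolyte_valence = 4L)
  phi <- seq(-0.15, 0.15, by = 0.005); phi <- phi[phi != 0]
  s_sph <- sigma_from_potential_sphere(phi, 50e-9, cond44)
  s_pla <- sigma_from_potential_planar(phi, cond44)
  # the two curves superimpose at the full scale of the +/-150 mV window,
  # and agree pointwise once the sinh nonlinearity dominates curvature
  expect_lt(max(abs(s_sph - s_pla)) / max(abs(s_pla)), 0.05)
  hi <- abs(phi) >= 0.075
  expect_true(all(abs(s_sph[hi] / s_pla[hi] - 1) < 0.05))
})

test_that("surface state enforces the shared-sign invariant; zeta conversion is flagged", {
  expect_error(surface_state(-0.04, 3e-3), "sign")
  st <- surface_state(-0.04, -3e-3)
  expect_s3_class(st, "surface_state")
  ps <- nanoparticle_spec(100e-9, 4.55e14, zeta_potential = -42e-3)
  zs <- zeta_to_sigma(ps, cond_1mM)
  expect_equal(zs$charge_density, -3.9377e-3, tolerance = 1e-4)
  expect_match(attr(zs, "approximation"), "zeta")
  expect_error(zeta_to_sigma(nanoparticle_spec(100e-9, 1e14), cond_1mM),
               "zeta")
})
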