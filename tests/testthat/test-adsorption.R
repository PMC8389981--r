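test_that("capacity conversions are exact inverses with the expected scale", {
  expect_equal(capacity_per_volume(244, 4.55e14), 1.84353e-7,
               tolerance = 1e-5)
  expect_equal(capacity_per_volume(1, physical_constants()$N_A), 1,
               tolerance = 1e-15)
  for (nm in c(38, 244, 18614))
    expect_equal(capacity_per_particle(capacity_per_volume(nm, 1.31e13),
                                       1.31e13), nm, tolerance = 1e-14)
})

test_that("depletion-corrected coverage solves the mass-balance fixed point", {
  expect_identical(coverage_with_depletion(0, 3.3e9, 1.844e-7)$theta, 0)
  cv <- coverage_with_depletion(1e-7, 3.3e9, 1.844e-7)
  expect_equal(cv$theta, bisect_adsorbed(1e-7, 3.3e9, 1.844e-7) / 1.844e-7,
               tolerance = 1e-9)
  expect_equal(cv$theta, 0.5403674, tolerance = 1e-6)
  expect_error(coverage_with_depletion(-1e-9, 1e9, 1e-7), "negative")
})

test_that("closed form equals the bisection oracle across 6 decades", {
  grid <- expand.grid(c_total = 10^seq(-10, -4, by = 1.5),
                      k_app = 10^seq(6, 12, by = 1.5),
                      n_max_vol = 10^seq(-10, -4, by = 1.5))
  # near-degenerate discriminant: capacity matches load at strong binding
  grid <- rbind(grid,
                data.frame(c_total = c(1e-7, 1e-7, 2e-7),
                           k_app = c(1e12, 1e11, 1e12),
                           n_max_vol = c(1e-7, 1.0001e-7, 2e-7)))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      a <- coverage_with_depletion(c_total, k_app, n_max_vol)$adsorbed
      a0 <- bisect_adsorbed(c_total, k_app, n_max_vol)
      expect_lt(abs(a - a0), 1e-10 * max(a0, 1e-300))
    })
  }
})

test_that("coverage obeys mass balance, monotonicity and saturation", {
  ct <- 10^seq(-10, -3, length.out = 40)
  cv <- coverage_with_depletion(ct, 3.3e9, 1.844e-7)
  expect_equal(cv$adsorbed + cv$free, ct, tolerance = 1e-12)
  expect_true(all(cv$free >= 0) && all(cv$theta >= 0) && all(cv$theta <= 1))
  expect_true(all(diff(cv$theta) > 0))
  expect_equal(cv$theta[length(ct)], 1, tolerance = 1e-3)  # c_total >> N_max
  th_k <- vapply(10^seq(7, 11, by = 0.5), function(k)
    coverage_with_depletion(5e-8, k, 1.844e-7)$theta, numeric(1))
  expect_true(all(diff(th_k) > 0))
})

test_that("no-depletion limit reduces to the simple Langmuir isotherm", {
  ct <- 10^seq(-9, -5, length.out = 25)
  th <- coverage_with_depletion(ct, 1e8, 1e-15)$theta
  expect_equal(th, 1e8 * ct / (1 + 1e8 * ct), tolerance = 1e-6)
})

test_that("adsorption screens the surface charge linearly in coverage", {
  hsa <- protein_spec("HSA", -8)
  s0 <- -3.9377e-3
  expect_identical(
    surface_charge_after_adsorption(0, s0, hsa, 244, 100e-9, 0.5), s0)
  s_mid <- surface_charge_after_adsorption(0.5, s0, hsa, 244, 100e-9, 0.5)
  s_full <- surface_charge_after_adsorption(1, s0, hsa, 244, 100e-9, 0.5)
  expect_equal(s_mid, (s0 + s_full) / 2, tolerance = 1e-14)
  expect_lt(abs(s_full), abs(s0))  # like-charged protein still screens
})

test_that("efficiency calibrated on measured zeta endpoints round-trips", {
  hsa <- protein_spec("HSA", -8)
  s_bare <- sigma_from_potential_sphere(-42e-3, 50e-9, cond_1mM)
  s_sat <- sigma_from_potential_sphere(-31e-3, 50e-9, cond_1mM)
  eta <- charge_efficiency_from_endpoints(s_bare, s_sat, hsa, 244, 100e-9)
  expect_gt(eta, 0); expect_lt(eta, 1)
  s1 <- surface_charge_after_adsorption(1, s_bare, hsa, 244, 100e-9, eta)
  expect_equal(s1 / s_bare, s_sat / s_bare, tolerance = 1e-10)
  expect_equal(potential_from_sigma_sphere(s1, 50e-9, cond_1mM), -31e-3,
               tolerance = 1e-8)
  # a monolayer cannot screen more charge than it carries
  expect_error(charge_efficiency_from_endpoints(s_bare, -3 * s_bare,
                                                hsa, 244, 100e-9))
})

test_that("Gibbs free energy reproduces the reported (K, DeltaG) pairs", {
  expect_equal(gibbs_from_k(19e8) / 1000, -53.0, tolerance = 1e-3)
  expect_equal(gibbs_from_k(9.0e9) / 1000, -56.8, tolerance = 1e-3)
  expect_identical(gibbs_from_k(1), 0)
  expect_error(gibbs_from_k(-1), "k_app")
  # strictly decreasing in K; solvent-molarity convention shifts by RT ln 55.5
  ks <- 10^seq(6, 11, by = 0.5)
  expect_true(all(diff(gibbs_from_k(ks)) < 0))
  expect_equal(gibbs_from_k(1e9, standard_state_M = 55.5) -
                 gibbs_from_k(1e9),
               -physical_constants()$R_gas * 298.15 * log(55.5),
               tolerance = 1e-12)
})

test_that("Gibbs uncertainty is first-order in dK/K", {
  expect_equal(gibbs_uncertainty(270e8, 170e8) / 1000, 1.5608,
               tolerance = 1e-4)
  expect_equal(gibbs_uncertainty(19e8, 5e8) / 1000, 0.65236,
               tolerance = 1e-4)
  expect_identical(gibbs_uncertainty(1e9, 0), 0)
  expect_equal(gibbs_uncertainty(1e9, 2e8), 2 * gibbs_uncertainty(1e9, 1e8),
               tolerance = 1e-14)
})

test_that("area per protein matches the sphere-geometry values", {
  expect_equal(area_per_protein(244, 100e-9), 128.75, tolerance = 1e-4)
  expect_equal(area_per_protein(18614, 500e-9), 42.19, tolerance = 1e-3)
  expect_equal(area_per_protein(1, 100e-9), pi * 100^2, tolerance = 1e-14)
})
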