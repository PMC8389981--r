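# Independent numerical oracles used across the suite.

# default test conditions: 1:1 electrolyte, 1 mM, 298.15 K, water
cond_1mM <- solution_conditions(1e-3)

# surface-moment integral over the unit sphere by high-order Gauss-
# Legendre quadrature (the closed forms under test use spherical Bessel
# functions instead)
.gl800 <- pracma::gaussLegendre(800, -1, 1)
quad_surface_moment <- function(qR, order, radius = 1) {
  mu <- .gl800$x; w <- .gl800$w
  re <- sum(w * cos(qR * mu) * mu^order)
  im <- sum(w * sin(qR * mu) * mu^order)
  2 * pi * radius^2 * complex(real = re, imaginary = im)
}

# depletion-Langmuir mass-balance fixed point solved by bisection
bisect_adsorbed <- function(c_total, k_app, n_max_vol) {
  if (c_total == 0) return(0)
  f <- function(a) n_max_vol * k_app * (c_total - a) /
    (1 + k_app * (c_total - a)) - a
  lo <- 0; hi <- min(c_total, n_max_vol)
  if (f(hi) >= 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force double-layer chi(3) integral: Simpson in both r and mu,
# no reduction to Bessel functions (coarse-setting oracle)
chi3_brute <- function(kappa, q, radius, phi0, nr = 3001, nmu = 1601) {
  rmax <- radius + 20 / kappa
  r <- seq(radius, rmax, length.out = nr)
  mu <- seq(-1, 1, length.out = nmu)
  wr <- rep(c(2, 4), length.out = nr); wr[1] <- 1; wr[nr] <- 1
  wm <- rep(c(2, 4), length.out = nmu); wm[1] <- 1; wm[nmu] <- 1
  er <- phi0 * radius * exp(-kappa * (r - radius)) * (1 / r^2 + kappa / r)
  hr <- (rmax - radius) / (nr - 1); hm <- 2 / (nmu - 1)
  # inner mu integral of exp(i q r mu) mu for each r
  phase <- outer(r, mu, function(ri, mi) q * ri * mi)
  inner <- (cos(phase) + 1i * sin(phase)) %*% (wm * mu) * hm / 3
  int <- sum(wr * er * r^2 * inner) * hr / 3
  2 * pi * int
}

# deterministic small scenario shared by inference tests
make_test_scenario <- function(k_app = 1e9, n_max = 264.7146,
                               noise = 0, seed = 1,
                               i0 = 1, i_sat = 0.3, angles = 40) {
  simulation_scenario(
    particle = nanoparticle_spec(100e-9, 4.55e14, -42e-3, "PS"),
    protein = protein_spec("HSA", -8),
    solution = solution_conditions(1e-6),
    adsorption = adsorption_params(k_app, n_max),
    seed = seed, i0 = i0, i_sat = i_sat, scattering_angles = angles,
    noise_level = noise)
}
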