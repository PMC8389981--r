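# Synthetic titration curves and scattering patterns with the
# statistical structure the analysis assumes: forward model plus seeded
# replicate-averaged noise, always paired with a ground-truth record.

#' Simulation scenario
#'
#' Bundles a particle, protein, solution, ground-truth adsorption
#' parameters, amplitudes, a concentration grid and a noise model into a
#' reproducible scenario. The default grid (15 log-spaced points from
#' 1 nM to 10 uM) straddles the depletion breakpoint of all presets; the
#' default noise (multiplicative Gaussian, 2 % relative, 10 replicates
#' per point) matches the replicate-averaged acquisition of fixed-angle
#' titrations.
#'
#' @param particle A [nanoparticle_spec()].
#' @param protein A [protein_spec()].
#' @param solution A [solution_conditions()].
#' @param adsorption An [adsorption_params()] ground truth.
#' @param seed Integer seed (mandatory).
#' @param i0,i_sat Bare and saturated intensities, recycled over
#'   `scattering_angles`.
#' @param scattering_angles Detection angle(s) in degrees.
#' @param concentration_grid Strictly increasing grid (mol/L).
#' @param noise_model `"multiplicative_gaussian"` or `"additive_gaussian"`.
#' @param noise_level Relative (multiplicative) or absolute (additive)
#'   standard deviation of one measurement, >= 0.
#' @param replicates Measurements averaged per point (>= 1).
#' @param link Intensity link model, see [titration_intensity()].
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(particle, protein, solution, adsorption, seed,
                                i0 = 1, i_sat = 0.545,
                                scattering_angles = 40,
                                concentration_grid = 10^seq(-9, -5, length.out = 15),
                                noise_model = c("multiplicative_gaussian",
                                                "additive_gaussian"),
                                noise_level = 0.02, replicates = 10L,
                                link = "field_linear") {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(particle, "nanoparticle_spec"),
            inherits(protein, "protein_spec"),
            inherits(solution, "solution_conditions"),
            inherits(adsorption, "adsorption_params"))
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric `seed` is mandatory", call. = FALSE)
  stopifnot(is.numeric(noise_level), noise_level >= 0,
            is.numeric(replicates), replicates >= 1,
            all(diff(concentration_grid) > 0), all(concentration_grid >= 0))
  na <- length(scattering_angles)
  i0 <- rep_len(i0, na); i_sat <- rep_len(i_sat, na)
  structure(list(particle = particle, protein = protein, solution = solution,
                 adsorption = adsorption, seed = as.integer(seed),
                 i0 = i0, i_sat = i_sat,
                 scattering_angles = as.numeric(scattering_angles),
                 concentration_grid = as.numeric(concentration_grid),
                 noise_model = noise_model,
                 noise_level = as.numeric(noise_level),
                 replicates = as.integer(replicates), link = link),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("<simulation_scenario> %s on %s (D = %g nm)\n",
              x$protein$name,
              if (nzchar(x$particle$label)) x$particle$label else "particle",
              x$particle$diameter * 1e9))
  cat(sprintf("  truth: K_app = %.3g /M, N_max = %g per particle\n",
              x$adsorption$binding_constant_app,
              x$adsorption$n_max_per_particle))
  cat(sprintf("  %d concentrations, angles %s deg, %s noise %.3g, %d replicates, seed %d\n",
              length(x$concentration_grid),
              paste(x$scattering_angles, collapse = "/"),
              x$noise_model, x$noise_level, x$replicates, x$seed))
  invisible(x)
}

# noiseless forward curve of a scenario at angle index j
.scenario_model <- function(scenario, j) {
  nv <- capacity_per_volume(scenario$adsorption$n_max_per_particle,
                            scenario$particle$number_density)
  theta <- coverage_with_depletion(scenario$concentration_grid,
                                   scenario$adsorption$binding_constant_app,
                                   nv)$theta
  titration_intensity(theta, scenario$i0[j], scenario$i_sat[j],
                      link = scenario$link)
}

#' Generate synthetic titration curve(s)
#'
#' Evaluates the depletion-corrected coverage and the intensity link on
#' the scenario grid, then adds seeded noise: each reported point is the
#' mean of `replicates` independent draws and carries the corresponding
#' standard error. The ground truth travels with the result.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Optional override of the scenario seed.
#' @return A [titration_curve()] (or a list of them, one per scattering
#'   angle) with attribute `truth`: a list with `k_app`,
#'   `n_max_per_particle`, `n_max_vol`, `i0`, `i_sat`.
#' @export
make_titration <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  nv <- capacity_per_volume(scenario$adsorption$n_max_per_particle,
                            scenario$particle$number_density)
  truth <- list(k_app = scenario$adsorption$binding_constant_app,
                n_max_per_particle = scenario$adsorption$n_max_per_particle,
                n_max_vol = nv, i0 = scenario$i0, i_sat = scenario$i_sat,
                link = scenario$link, seed = as.integer(seed))
  curves <- .with_seed(seed, lapply(seq_along(scenario$scattering_angles),
    function(j) {
      mu <- .scenario_model(scenario, j)
      n <- length(mu); reps <- scenario$replicates
      if (scenario$noise_level == 0) {
        inten <- mu; err <- NULL
      } else {
        draws <- matrix(stats::rnorm(n * reps), n, reps)
        draws <- if (scenario$noise_model == "multiplicative_gaussian")
          mu * (1 + scenario$noise_level * draws)
        else mu + scenario$noise_level * draws
        inten <- pmax(rowMeans(draws), 0)
        err <- if (reps > 1) apply(draws, 1, stats::sd) / sqrt(reps)
        else if (scenario$noise_model == "multiplicative_gaussian")
          scenario$noise_level * mu
        else rep(scenario$noise_level, n)
        err <- pmax(err, 1e-12)
      }
      titration_curve(scenario$concentration_grid, inten, err,
                      scattering_angle = scenario$scattering_angles[j],
                      polarization = "ppp",
                      metadata = list(particle = scenario$particle$label,
                                      protein = scenario$protein$name))
    }))
  if (length(curves) == 1L) {
    out <- curves[[1]]
  } else {
    out <- curves
    class(out) <- c("titration_curve_set", class(out))
  }
  attr(out, "truth") <- truth
  out
}

#' Generate a paired low/high ionic-strength pattern dataset
#'
#' Derives the bare surface charge density from the particle's zeta
#' potential at the scenario's solution conditions, then, holding that
#' charge density fixed, inverts the sphere charge-potential relation at
#' each member of the salt pair to obtain the screened surface potential
#' and evaluates the angle-resolved forward model, with seeded
#' multiplicative noise.
#'
#' @param scenario A [simulation_scenario()] whose particle carries a
#'   zeta potential.
#' @param amplitudes An [optical_amplitudes()] object.
#' @param angles Scattering angles (degrees).
#' @param polarization `"ppp"` or `"pss"`.
#' @param salt_pair Low and high ionic strengths (mol/L), default
#'   `c(1e-5, 1e-2)`.
#' @param noise_level Relative noise per angle point (default the
#'   scenario's level).
#' @param seed Optional override of the scenario seed.
#' @return A list with elements `low` and `high` (class `shs_pattern`
#'   data frames) and `truth` (surface potentials and charge density).
#' @export
make_pattern <- function(scenario, amplitudes = optical_amplitudes(),
                         angles = seq(5, 175, by = 2),
                         polarization = "ppp",
                         salt_pair = c(1e-5, 1e-2),
                         noise_level = scenario$noise_level,
                         seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            length(salt_pair) == 2L, salt_pair[1] < salt_pair[2])
  part <- scenario$particle
  if (is.null(part$zeta_potential))
    stop("pattern generation needs a particle zeta potential", call. = FALSE)
  sigma0 <- zeta_to_sigma(part, scenario$solution)$charge_density
  pats <- .with_seed(seed, lapply(salt_pair, function(cs) {
    cond <- solution_conditions(cs,
              temperature = scenario$solution$temperature,
              relative_permittivity = scenario$solution$relative_permittivity,
              electrolyte_valence = scenario$solution$electrolyte_valence)
    phi <- potential_from_sigma_sphere(sigma0, part$diameter / 2, cond)
    pat <- shs_pattern(amplitudes, part, cond, angles = angles,
                       polarization = polarization, phi0 = phi)
    if (noise_level > 0) {
      pat$intensity <- pat$intensity *
        (1 + noise_level * stats::rnorm(nrow(pat)))
      attr(pat, "peak_angle") <- pat$angle[which.max(pat$intensity)]
    }
    attr(pat, "phi0") <- phi
    pat
  }))
  list(low = pats[[1]], high = pats[[2]],
       truth = list(sigma0 = sigma0,
                    phi0 = vapply(pats, attr, numeric(1), "phi0"),
                    salt_pair = salt_pair))
}

#' Ready-made scenarios for the studied particle/protein systems
#'
#' Returns the nine fitted parameter sets of the studied systems as
#' simulation scenarios with the reported apparent binding constants and
#' monolayer capacities as ground truth: six 100 nm particle/protein
#' combinations (plain and carboxylated polystyrene with fibrinogen,
#' serum albumin and transferrin) and the serum-albumin size series
#' (100/200/500 nm). Number densities, zeta potentials and detection
#' angles follow the corresponding measurements; titrations are in
#' ultrapure water, with the residual ionic strength set to 1e-6 M and
#' zeta potentials referring to 1 mM added salt.
#'
#' The saturated/bare intensity ratio (0.545) is calibrated from the
#' only reported zeta-potential endpoint pair (-42 mV bare, -31 mV after
#' serum-albumin saturation) through the field-linear link; protein net
#' valences are nominal literature values at near-neutral pH.
#'
#' @param seed Seed stored in every scenario (default 1).
#' @return Named list of nine [simulation_scenario()] objects.
#' @examples
#' names(scenario_presets())
#' scenario_presets()[["PS-COOH + HSA"]]
#' @export
scenario_presets <- function(seed = 1L) {
  water <- solution_conditions(1e-6)
  hsa <- protein_spec("HSA", -8)
  fbg <- protein_spec("Fbg", -10)
  tf  <- protein_spec("Tf", -2)
  ps100  <- nanoparticle_spec(100e-9, 4.55e14, -42e-3, "PS")
  psc100 <- nanoparticle_spec(100e-9, 4.55e14, -44e-3, "PS-COOH")
  ps200  <- nanoparticle_spec(200e-9, 1.31e13, -50e-3, "PS")
  ps500  <- nanoparticle_spec(500e-9, 1.81e12, -54e-3, "PS")
  mk <- function(particle, protein, k, nmax, angle)
    simulation_scenario(particle, protein, water,
                        adsorption_params(k, nmax), seed = seed,
                        scattering_angles = angle)
  list(
    "PS + Fbg"       = mk(ps100,  fbg, 19e8,  130,   40),
    "PS + HSA"       = mk(ps100,  hsa, 33e8,  244,   40),
    "PS + Tf"        = mk(ps100,  tf,  4.8e8, 183,   40),
    "PS-COOH + Fbg"  = mk(psc100, fbg, 90e8,  38,    40),
    "PS-COOH + HSA"  = mk(psc100, hsa, 270e8, 137,   40),
    "PS-COOH + Tf"   = mk(psc100, tf,  79e8,  131,   40),
    "PS 100 nm + HSA" = mk(ps100, hsa, 3.3e9, 244,   40),
    "PS 200 nm + HSA" = mk(ps200, hsa, 80e9,  1179,  35),
    "PS 500 nm + HSA" = mk(ps500, hsa, 3.0e9, 18614, 25)
  )
}
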