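# Global weighted nonlinear least-squares fit of the depletion-corrected
# Langmuir titration model, with multi-start initialisation and residual
# bootstrap uncertainties. K_app and N_max are shared across curves
# (global fit); the intensity amplitudes (I0, I_sat) are per curve.

# run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# pack/unpack parameter vector: c(logK, logNvol, then per curve 2 params)
# field_linear:    (log a_j, b_j) with I = (a - b*theta)^2
# intensity_linear:(log i0_j, di_j) with I = i0 - di*theta
.predict_curves <- function(p, curves, link) {
  k <- exp(p[1]); nv <- exp(p[2])
  lapply(seq_along(curves), function(j) {
    pj <- p[(2 * j + 1):(2 * j + 2)]
    theta <- .langmuir_adsorbed(curves[[j]]$concentration, k, nv) / nv
    if (link == "field_linear") {
      a <- exp(pj[1]); b <- pj[2]
      (a - b * theta)^2
    } else {
      i0 <- exp(pj[1]); di <- pj[2]
      i0 - di * theta
    }
  })
}

.residual_fun <- function(p, curves, link, weights) {
  pred <- .predict_curves(p, curves, link)
  unlist(lapply(seq_along(curves), function(j)
    (pred[[j]] - curves[[j]]$intensity) / weights[[j]]))
}

# amplitude parameters (i0, i_sat) -> raw parameterisation
.amp_to_raw <- function(i0, i_sat, link) {
  if (link == "field_linear") c(log(sqrt(i0)), sqrt(i0) - sqrt(i_sat))
  else c(log(i0), i0 - i_sat)
}
.raw_to_amp <- function(pj, link) {
  if (link == "field_linear") {
    a <- exp(pj[1]); b <- pj[2]
    c(i0 = a^2, i_sat = (a - b)^2)
  } else {
    c(i0 = exp(pj[1]), i_sat = exp(pj[1]) - pj[2])
  }
}

#' Initial parameter guess for a titration fit
#'
#' Heuristics for the strong-binding, strong-depletion regime: the bare
#' intensity from the low-concentration plateau (mean of the first two
#' points), the saturated intensity from the high-concentration plateau
#' (mean of the last two), the volumetric capacity from the concentration
#' at the half-drop of the square-root intensity (in the depletion-
#' dominated regime adsorption is stoichiometric, so the breakpoint sits
#' near the capacity), and the binding constant seeded at 1e9 1/M.
#'
#' @param curve A [titration_curve()] with at least 4 points.
#' @return A list with `i0`, `i_sat`, `n_max_vol`, `k_app`, and logical
#'   flags `monotone` and `identifiable_k` (the latter is FALSE for flat
#'   curves with no measurable intensity change).
#' @export
initial_guess <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  n <- nrow(curve)
  if (n < 4L) stop("need at least 4 points per curve", call. = FALSE)
  i0 <- mean(curve$intensity[1:2])
  i_sat <- mean(curve$intensity[(n - 1):n])
  monotone <- all(diff(curve$intensity) <= 0) || all(diff(curve$intensity) >= 0)
  identifiable <- abs(i0 - i_sat) > 0.01 * max(i0, i_sat, .Machine$double.eps)
  s <- sqrt(pmax(curve$intensity, 0))
  half <- (sqrt(max(i0, 0)) + sqrt(max(i_sat, 0))) / 2
  # first concentration where sqrt-intensity crosses the half level
  below <- if (i0 >= i_sat) which(s <= half) else which(s >= half)
  c_half <- if (length(below)) curve$concentration[below[1]] else
    stats::median(curve$concentration)
  if (c_half <= 0) c_half <- curve$concentration[curve$concentration > 0][1]
  list(i0 = i0, i_sat = i_sat,
       n_max_vol = 2 * c_half, k_app = 1e9,
       monotone = monotone, identifiable_k = identifiable)
}

#' Global fit of SHS titration curves
#'
#' Weighted nonlinear least squares of the depletion-corrected Langmuir
#' forward model against one or more fixed-angle titration curves. The
#' apparent binding constant and the monolayer capacity are shared
#' across curves; the amplitudes (bare and saturated intensity) are per
#' curve. Positivity of K_app and N_max is enforced by fitting in log
#' space. Optimisation uses Levenberg-Marquardt with multi-start from a
#' 3x3 log-grid around the initial guess; the best chi-square wins, with
#' ties (below 1e-9 relative) resolved toward the smaller binding
#' constant.
#'
#' @param curves A [titration_curve()] or list of them (>= 4 points
#'   each). When no intensity errors are present, the fit is unweighted.
#' @param number_density Particle number density (1/L), used to convert
#'   the volumetric capacity to a per-particle count.
#' @param link Intensity link model, `"field_linear"` (default; the
#'   scattered field is linear in coverage) or `"intensity_linear"`.
#' @param start Optional named list overriding the initial guess
#'   (`k_app`, `n_max_vol`, per-curve `i0`, `i_sat`).
#' @param multistart Logical; use the 3x3 log-grid multi-start (default
#'   TRUE).
#' @param temperature Temperature for the Gibbs free energy (K).
#' @param k_bounds,n_vol_bounds Box constraints (1/M and mol/L) on the
#'   shared parameters. The defaults span everything physically
#'   plausible for protein adsorption (femtomolar affinity cap); they
#'   exist to keep the optimiser from wandering to absurd values when a
#'   saturated titration leaves K unidentified upward.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `shs_fit`: apparent binding constant,
#'   capacity (per particle and per volume), per-curve amplitudes,
#'   apparent Gibbs free energy (always consistent with the fitted
#'   K_app), chi-square, residuals and convergence diagnostics.
#'   Curvature-based standard errors are included; call
#'   [bootstrap_uncertainties()] for resampling-based intervals.
#' @examples
#' sc <- scenario_presets()[["PS + HSA"]]
#' cur <- make_titration(sc)
#' fit_titration(cur, number_density = sc$particle$number_density)
#' @export
fit_titration <- function(curves, number_density,
                          link = c("field_linear", "intensity_linear"),
                          start = NULL, multistart = TRUE,
                          temperature = 298.15,
                          k_bounds = c(1e3, 1e15),
                          n_vol_bounds = c(1e-13, 1e-1),
                          control = minpack.lm::nls.lm.control(maxiter = 200)) {
  link <- match.arg(link)
  curves <- .as_curve_list(curves)
  stopifnot(is.numeric(number_density), number_density > 0)
  npts <- vapply(curves, nrow, integer(1))
  if (any(npts < 4L)) stop("need at least 4 points per curve", call. = FALSE)
  weights <- lapply(curves, function(cu)
    if (!is.null(cu$intensity_err)) cu$intensity_err else rep(1, nrow(cu)))

  guesses <- lapply(curves, initial_guess)
  g1 <- guesses[[1]]
  k0 <- if (!is.null(start$k_app)) start$k_app else g1$k_app
  nv0 <- if (!is.null(start$n_max_vol)) start$n_max_vol else
    stats::median(vapply(guesses, `[[`, numeric(1), "n_max_vol"))
  if (!all(vapply(guesses, `[[`, logical(1), "monotone"))) {
    # non-monotone data: coarse grid search for the shared parameters
    grid <- expand.grid(lk = log(10) * seq(6, 12, by = 0.5),
                        ln = log(nv0) + log(10) * seq(-1.5, 1.5, by = 0.25))
    cost <- apply(grid, 1, function(gr) {
      p <- c(gr[["lk"]], gr[["ln"]],
             unlist(lapply(guesses, function(g)
               .amp_to_raw(max(g$i0, 1e-12), max(g$i_sat, 1e-12), link))))
      sum(.residual_fun(p, curves, link, weights)^2)
    })
    best <- grid[which.min(cost), ]
    k0 <- exp(best$lk); nv0 <- exp(best$ln)
  }

  amp0 <- unname(unlist(lapply(guesses, function(g) {
    i0 <- if (!is.null(start$i0)) start$i0 else max(g$i0, 1e-12)
    is <- if (!is.null(start$i_sat)) start$i_sat else max(g$i_sat, 1e-12)
    .amp_to_raw(i0, is, link)
  })))

  offsets <- if (multistart)
    expand.grid(dk = c(-1, 0, 1) * log(10), dn = c(-0.5, 0, 0.5) * log(10))
  else data.frame(dk = 0, dn = 0)

  npar <- 2L + 2L * length(curves)
  lower <- c(log(k_bounds[1]), log(n_vol_bounds[1]), rep(-Inf, npar - 2L))
  upper <- c(log(k_bounds[2]), log(n_vol_bounds[2]), rep(Inf, npar - 2L))
  best_fit <- NULL; best_cost <- Inf; best_k <- Inf
  for (i in seq_len(nrow(offsets))) {
    p0 <- c(min(max(log(k0) + offsets$dk[i], lower[1]), upper[1]),
            min(max(log(nv0) + offsets$dn[i], lower[2]), upper[2]),
            amp0)
    fm <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = .residual_fun, curves = curves,
                         link = link, weights = weights,
                         lower = lower, upper = upper, control = control),
      error = function(e) NULL)
    if (is.null(fm)) next
    cost <- fm$deviance
    kf <- exp(fm$par[1])
    take <- cost < best_cost * (1 - 1e-9) ||
      (abs(cost - best_cost) <= 1e-9 * max(best_cost, 1e-300) && kf < best_k)
    if (is.null(best_fit) || take) {
      best_fit <- fm; best_cost <- cost; best_k <- kf
    }
  }
  if (is.null(best_fit))
    stop("optimisation failed for every start; check the input curves",
         call. = FALSE)

  p <- unname(best_fit$par)
  k_app <- exp(p[1]); n_max_vol <- exp(p[2])
  amps <- do.call(rbind, lapply(seq_along(curves), function(j)
    .raw_to_amp(p[(2 * j + 1):(2 * j + 2)], link)))
  amps <- data.frame(curve = seq_along(curves),
                     scattering_angle = vapply(curves, attr, numeric(1),
                                               "scattering_angle"),
                     i0 = amps[, "i0"], i_sat = amps[, "i_sat"])
  dof <- sum(npts) - length(p)
  # curvature-based covariance: sigma^2 (J'J)^-1, delta method for logs
  se <- rep(NA_real_, length(p))
  cv <- tryCatch({
    s2 <- best_cost / max(dof, 1L)
    v <- s2 * solve(best_fit$hessian)
    sqrt(pmax(diag(v), 0))
  }, error = function(e) NULL)
  if (!is.null(cv)) se <- cv

  pred <- .predict_curves(p, curves, link)
  residuals <- lapply(seq_along(curves), function(j)
    curves[[j]]$intensity - pred[[j]])

  n_max_pp <- capacity_per_particle(n_max_vol, number_density)
  structure(list(
    k_app = k_app,
    k_app_se = k_app * se[1],
    n_max_per_particle = n_max_pp,
    n_max_per_particle_se = n_max_pp * se[2],
    n_max_vol = n_max_vol,
    amplitudes = amps,
    delta_g = gibbs_from_k(k_app, temperature),
    delta_g_se = if (is.finite(se[1])) gibbs_uncertainty(k_app, k_app * se[1],
                                                         temperature) else NA_real_,
    temperature = temperature,
    chi_square = best_cost,
    dof = dof,
    residuals = residuals,
    fitted = pred,
    link = link,
    number_density = number_density,
    converged = best_fit$info %in% 1:4,
    message = best_fit$message,
    identifiable_k = all(vapply(guesses, `[[`, logical(1), "identifiable_k")),
    par = p,
    bootstrap = NULL,
    seed = NA_integer_
  ), class = "shs_fit")
}

#' Bootstrap uncertainties for a titration fit
#'
#' Parametric residual bootstrap: for each replicate the fitted
#' intensities are perturbed by synthetic noise and the model is
#' refitted from the original optimum. Two noise mechanisms are
#' available. By default residuals are resampled with replacement within
#' each curve (standardised by the point weights and inflated by
#' sqrt(n/dof) to undo the variance deflation of fitted residuals).
#' When the data are replicate-averaged points with recorded standard
#' errors, pass `measurement_replicates`: each bootstrap point is then
#' regenerated as the mean of that many Gaussian draws and its standard
#' error is re-estimated from them, so the sampling noise of the error
#' bars themselves (which feeds the fit weights) is propagated too.
#' Reports the bootstrap standard deviation and 2.5/97.5 percentiles for
#' K_app, N_max and the Gibbs free energy, alongside the analytic
#' first-order [gibbs_uncertainty()] for comparison.
#'
#' @param fit A converged [fit_titration()] result.
#' @param curves The curves that produced it.
#' @param n_boot Number of bootstrap replicates (>= 10; default 500).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param measurement_replicates Number of averaged measurements behind
#'   each data point, when known and when the curves carry standard
#'   errors; `NULL` (default) selects plain residual resampling.
#' @return The `shs_fit` object with a `bootstrap` element: `samples`
#'   (data frame of replicate estimates), `k_sd`, `k_ci`, `n_max_sd`,
#'   `n_max_ci`, `delta_g_sd`, `delta_g_ci`, `delta_g_analytic`.
#' @export
bootstrap_uncertainties <- function(fit, curves, n_boot = 500, seed,
                                    measurement_replicates = NULL) {
  stopifnot(inherits(fit, "shs_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (n_boot < 10) stop("n_boot must be >= 10", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric `seed` is mandatory", call. = FALSE)
  curves <- .as_curve_list(curves)
  weights <- lapply(curves, function(cu)
    if (!is.null(cu$intensity_err)) cu$intensity_err else rep(1, nrow(cu)))
  # fitted residuals have deflated variance (p parameters absorb part of
  # the noise); inflate by sqrt(n/dof) so resampled noise has the right scale
  n_tot <- sum(vapply(curves, nrow, integer(1)))
  infl <- sqrt(n_tot / max(fit$dof, 1L))
  std_res <- lapply(seq_along(curves), function(j)
    infl * fit$residuals[[j]] / weights[[j]])
  use_meas <- !is.null(measurement_replicates)
  if (use_meas) {
    m <- as.integer(measurement_replicates)
    stopifnot(m >= 2)
    if (!all(vapply(curves, function(cu) !is.null(cu$intensity_err),
                    logical(1))))
      stop("measurement_replicates requires curves with standard errors",
           call. = FALSE)
  }

  samples <- .with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("k_app", "n_max_per_particle")))
    for (b in seq_len(n_boot)) {
      bcur <- lapply(seq_along(curves), function(j) {
        cu <- curves[[j]]
        if (use_meas) {
          # regenerate the replicate-averaged acquisition per point
          s <- cu$intensity_err * sqrt(m)      # per-measurement sd
          n <- nrow(cu)
          draws <- matrix(stats::rnorm(n * m, mean = fit$fitted[[j]],
                                       sd = s), n, m)
          inten <- pmax(rowMeans(draws), 0)
          err <- pmax(apply(draws, 1, stats::sd) / sqrt(m), 1e-12)
          return(titration_curve(cu$concentration, inten, err,
                                 scattering_angle = attr(cu, "scattering_angle"),
                                 polarization = attr(cu, "polarization")))
        }
        res <- sample(std_res[[j]], replace = TRUE) * weights[[j]]
        inten <- pmax(fit$fitted[[j]] + res, 0)
        titration_curve(cu$concentration, inten, cu$intensity_err,
                        scattering_angle = attr(cu, "scattering_angle"),
                        polarization = attr(cu, "polarization"))
      })
      bf <- tryCatch(
        fit_titration(bcur, fit$number_density, link = fit$link,
                      start = list(k_app = fit$k_app,
                                   n_max_vol = fit$n_max_vol),
                      multistart = FALSE, temperature = fit$temperature),
        error = function(e) NULL)
      if (!is.null(bf) && bf$converged)
        out[b, ] <- c(bf$k_app, bf$n_max_per_particle)
    }
    out
  })
  ok <- stats::complete.cases(samples)
  samples <- as.data.frame(samples[ok, , drop = FALSE])
  samples$delta_g <- gibbs_from_k(samples$k_app, fit$temperature)
  q <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  # Percentile and basic (reflected) bootstrap limits disagree when the
  # estimator is biased or skewed -- both happen for K in the strong-
  # depletion regime. Reported intervals span both sets of limits, a
  # deliberately conservative choice; K is handled on the log scale
  # (positive, strongly right-skewed), N_max on the natural scale.
  # DeltaG is linear in log K and maps from the K interval.
  union_ci <- function(est, smp) {
    p <- q(smp); b <- 2 * est - rev(p)
    c(min(p[1], b[1]), max(p[2], b[2]))
  }
  k_ci <- exp(union_ci(log(fit$k_app), log(samples$k_app)))
  fit$bootstrap <- list(
    samples = samples,
    n_effective = nrow(samples),
    k_sd = stats::sd(samples$k_app),
    k_ci = k_ci,
    n_max_sd = stats::sd(samples$n_max_per_particle),
    n_max_ci = union_ci(fit$n_max_per_particle,
                        samples$n_max_per_particle),
    delta_g_sd = stats::sd(samples$delta_g),
    delta_g_ci = sort(gibbs_from_k(k_ci, fit$temperature)),
    delta_g_analytic = gibbs_uncertainty(fit$k_app, stats::sd(samples$k_app),
                                         fit$temperature))
  fit$seed <- as.integer(seed)
  fit
}

#' @export
print.shs_fit <- function(x, ...) {
  cat("<shs_fit> depletion-corrected Langmuir global fit\n")
  fmt <- function(v, s) if (is.finite(s)) sprintf("%.3g +/- %.2g", v, s)
    else sprintf("%.3g", v)
  ns <- if (!is.null(x$bootstrap)) x$bootstrap$n_max_sd else x$n_max_per_particle_se
  gs <- if (!is.null(x$bootstrap)) x$bootstrap$delta_g_sd else x$delta_g_se
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  K_app   : %.3g 1/M, 95%% CI [%.3g, %.3g]  (%.3g x 10^8 mol^-1)\n",
                x$k_app, x$bootstrap$k_ci[1], x$bootstrap$k_ci[2],
                x$k_app / 1e8))
  } else {
    cat(sprintf("  K_app   : %s 1/M  (%.3g x 10^8 mol^-1)\n",
                fmt(x$k_app, x$k_app_se), x$k_app / 1e8))
  }
  cat(sprintf("  N_max   : %s per particle\n", fmt(x$n_max_per_particle, ns)))
  cat(sprintf("  DeltaG  : %s kJ/mol at %g K\n",
              fmt(x$delta_g / 1000, gs / 1000), x$temperature))
  cat(sprintf("  chi^2/dof = %.4g / %d, %d curve(s), link = %s, converged: %s\n",
              x$chi_square, x$dof, nrow(x$amplitudes), x$link, x$converged))
  if (!x$identifiable_k)
    cat("  note: flat curve(s); K_app is not identifiable\n")
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap: %d replicates, K 95%% CI [%.3g, %.3g]\n",
                x$bootstrap$n_effective, x$bootstrap$k_ci[1], x$bootstrap$k_ci[2]))
  invisible(x)
}
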