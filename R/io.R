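# Readers and writers: the flat titration CSV dialect, YAML/JSON
# configuration with strict key validation, and fit reports (schema-
# versioned JSON plus a human-readable table).

REPORT_SCHEMA_VERSION <- "1.0"

#' Read titration curves from CSV
#'
#' Parses the package's flat CSV dialect: mandatory header with columns
#' `concentration_M`, `intensity`, `angle_deg`, `polarization` and
#' optional `intensity_err`; UTF-8, `.` decimal separator. Rows are
#' grouped into one curve per (angle, polarization) pair and curve
#' invariants are enforced. Malformed cells and ordering violations are
#' reported with their row number (header = row 1).
#'
#' @param path Path to the CSV file.
#' @return A list of [titration_curve()] objects (length one if the file
#'   holds a single curve).
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         fileEncoding = "UTF-8")
  need <- c("concentration_M", "intensity", "angle_deg", "polarization")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column %s at row %d",
                   raw[[col]][bad[1]], col, bad[1] + 1L), call. = FALSE)
    v
  }
  conc <- num("concentration_M"); inten <- num("intensity")
  ang <- num("angle_deg"); pol <- raw$polarization
  err <- if ("intensity_err" %in% names(raw)) num("intensity_err") else NULL
  key <- paste(ang, pol, sep = "|")
  rows <- split(seq_len(nrow(raw)), factor(key, levels = unique(key)))
  lapply(rows, function(idx) {
    d <- diff(conc[idx])
    if (any(d <= 0)) {
      at <- idx[which(d <= 0)[1] + 1L]
      stop(sprintf("concentrations not strictly increasing at row %d",
                   at + 1L), call. = FALSE)
    }
    titration_curve(conc[idx], inten[idx],
                    if (!is.null(err)) err[idx],
                    scattering_angle = ang[idx[1]],
                    polarization = pol[idx[1]])
  })
}

#' Write titration curves to CSV
#'
#' Inverse of [read_titration_csv()]; values round-trip at full double
#' precision.
#'
#' @param curves A [titration_curve()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curves, path) {
  curves <- .as_curve_list(curves)
  has_err <- any(vapply(curves, function(cu)
    !is.null(cu$intensity_err), logical(1)))
  tab <- do.call(rbind, lapply(curves, function(cu) {
    d <- data.frame(concentration_M = cu$concentration,
                    intensity = cu$intensity)
    d$intensity_err <- if (!is.null(cu$intensity_err)) cu$intensity_err
      else if (has_err) NA_real_ else NULL
    d$angle_deg <- attr(cu, "scattering_angle")
    d$polarization <- attr(cu, "polarization")
    d
  }))
  utf8 <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  out <- tab
  for (cl in c("concentration_M", "intensity", "intensity_err"))
    if (cl %in% names(out)) out[[cl]] <- utf8(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

.config_schema <- list(
  schema_version = character(),
  solution = c("temperature_K", "relative_permittivity",
               "electrolyte_valence", "ionic_concentration_M"),
  particle = c("diameter_nm", "diameter_m", "number_density_per_L",
               "zeta_potential_mV", "zeta_potential_V", "label"),
  protein = c("name", "net_valence"),
  adsorption = c("k_app_per_M", "n_max_per_particle", "standard_state_M",
                 "charge_efficiency", "solvent_molarity"),
  optics = c("fundamental_wavelength_nm", "refractive_index",
             "chi2", "chi3", "phase", "background"),
  fitting = c("link", "n_boot", "seed", "temperature_K"),
  simulation = c("concentration_grid_M", "noise_model", "noise_level",
                 "replicates", "seed", "i0", "i_sat", "scattering_angles_deg")
)

#' Read an analysis configuration (YAML or JSON)
#'
#' Validates the configuration against the package schema: unknown
#' sections or keys are rejected, and units are fixed by the key names
#' (`_M` mol/L, `_nm`/`_m` lengths, `_mV`/`_V` potentials, `_K`
#' temperatures). Returns the raw list plus constructed package objects
#' for the sections present.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with the validated raw config and, where the relevant
#'   sections are present, `solution` ([solution_conditions()]),
#'   `particle` ([nanoparticle_spec()]), `protein` ([protein_spec()])
#'   and `adsorption` ([adsorption_params()]).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in setdiff(names(cfg), "schema_version")) {
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  # YAML 1.1 treats exponents without a sign (4.55e14) as strings; force
  # the numeric keys back to numbers
  num <- function(x) if (is.null(x)) NULL else {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) stop("non-numeric config value: ", x, call. = FALSE)
    v
  }
  for (sec in intersect(names(cfg), c("solution", "adsorption", "optics")))
    cfg[[sec]] <- lapply(cfg[[sec]], num)
  for (key in c("diameter_nm", "diameter_m", "number_density_per_L",
                "zeta_potential_mV", "zeta_potential_V"))
    if (!is.null(cfg$particle[[key]])) cfg$particle[[key]] <- num(cfg$particle[[key]])
  if (!is.null(cfg$protein$net_valence))
    cfg$protein$net_valence <- num(cfg$protein$net_valence)
  out <- list(config = cfg)
  if (!is.null(cfg$solution)) {
    s <- cfg$solution
    out$solution <- solution_conditions(
      ionic_concentration = s$ionic_concentration_M,
      temperature = s$temperature_K %||% 298.15,
      relative_permittivity = s$relative_permittivity %||% 78.4,
      electrolyte_valence = s$electrolyte_valence %||% 1L)
  }
  if (!is.null(cfg$particle)) {
    p <- cfg$particle
    diam <- if (!is.null(p$diameter_m)) p$diameter_m else p$diameter_nm * 1e-9
    zeta <- if (!is.null(p$zeta_potential_V)) p$zeta_potential_V
      else if (!is.null(p$zeta_potential_mV)) p$zeta_potential_mV * 1e-3
      else NULL
    out$particle <- nanoparticle_spec(diam, p$number_density_per_L,
                                      zeta, p$label %||% "")
  }
  if (!is.null(cfg$protein))
    out$protein <- protein_spec(cfg$protein$name, cfg$protein$net_valence)
  if (!is.null(cfg$adsorption) && !is.null(cfg$adsorption$k_app_per_M))
    out$adsorption <- adsorption_params(cfg$adsorption$k_app_per_M,
                                        cfg$adsorption$n_max_per_particle,
                                        cfg$adsorption$solvent_molarity %||% 55.5)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reports ---------------------------------------------------------------

# flatten an shs_fit into plain lists for serialisation
.fit_to_record <- function(fit) {
  bs <- fit$bootstrap
  list(
    schema_version = REPORT_SCHEMA_VERSION,
    k_app_per_M = fit$k_app,
    k_app_se = if (!is.null(bs)) bs$k_sd else fit$k_app_se,
    n_max_per_particle = fit$n_max_per_particle,
    n_max_se = if (!is.null(bs)) bs$n_max_sd else fit$n_max_per_particle_se,
    n_max_vol_M = fit$n_max_vol,
    delta_g_J_per_mol = fit$delta_g,
    delta_g_se_J_per_mol = if (!is.null(bs)) bs$delta_g_analytic else fit$delta_g_se,
    temperature_K = fit$temperature,
    amplitudes = fit$amplitudes,
    chi_square = fit$chi_square,
    dof = fit$dof,
    link = fit$link,
    number_density_per_L = fit$number_density,
    converged = fit$converged,
    seed = fit$seed,
    bootstrap = if (!is.null(bs))
      list(n_effective = bs$n_effective,
           k_ci = bs$k_ci, n_max_ci = bs$n_max_ci, delta_g_ci = bs$delta_g_ci)
  )
}

#' Write a fit report
#'
#' JSON reports are schema-versioned and machine-readable; text reports
#' mirror the conventional presentation of titration fits: the binding
#' constant in units of 1e8 per molar, the per-particle capacity, and
#' the apparent Gibbs free energy in kJ/mol to one decimal, each with
#' its uncertainty.
#'
#' @param fit An `shs_fit`, or a named list of them (one table row each).
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, format = c("json", "text")) {
  format <- match.arg(format)
  fits <- if (inherits(fit, "shs_fit")) list(fit = fit) else fit
  stopifnot(all(vapply(fits, inherits, logical(1), "shs_fit")))
  if (!all(vapply(fits, `[[`, logical(1), "converged")))
    stop("refusing to report a non-converged fit", call. = FALSE)
  if (format == "json") {
    jsonlite::write_json(lapply(fits, .fit_to_record), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    pm <- function(v, s, fm = "%.3g") {
      if (is.null(s) || !length(s) || !is.finite(s)) sprintf(fm, v)
      else sprintf(paste0(fm, " ± ", fm), v, s)
    }
    lines <- c(sprintf("%-24s %-18s %-18s %s",
                       "system", "K_app (10^8 mol^-1)", "N_max per particle",
                       "DeltaG_app (kJ/mol)"))
    for (nm in names(fits)) {
      f <- fits[[nm]]; r <- .fit_to_record(f)
      lines <- c(lines, sprintf("%-24s %-18s %-18s -(%s)",
        nm,
        pm(r$k_app_per_M / 1e8, r$k_app_se / 1e8),
        pm(r$n_max_per_particle, r$n_max_se, "%.0f"),
        pm(-r$delta_g_J_per_mol / 1000, r$delta_g_se_J_per_mol / 1000, "%.1f")))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a JSON fit report
#'
#' @param path Path to a report written by [write_report()] with
#'   `format = "json"`.
#' @return The report as a named list of records.
#' @export
read_report <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(rec)) {
    if (!identical(rec[[nm]]$schema_version, REPORT_SCHEMA_VERSION))
      warning("report schema version ", rec[[nm]]$schema_version,
              " (reader expects ", REPORT_SCHEMA_VERSION, ")", call. = FALSE)
  }
  rec
}
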