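#' Titration curve
#'
#' A fixed-angle SHS titration: SHS intensity as a function of total
#' protein concentration, tagged by scattering angle and polarization.
#'
#' @param concentration Total protein concentrations (mol/L), >= 0 and
#'   strictly increasing.
#' @param intensity SHS intensities (arbitrary units), >= 0.
#' @param intensity_err Optional standard errors of the intensities,
#'   > 0 where present.
#' @param scattering_angle Detection angle (degrees).
#' @param polarization Polarization tag (e.g. `"ppp"`).
#' @param metadata Named list of free-form references (particle, protein,
#'   solution).
#' @return A data frame of class `titration_curve` with columns
#'   `concentration`, `intensity` and (optionally) `intensity_err`;
#'   angle, polarization and metadata are attributes.
#' @export
titration_curve <- function(concentration, intensity, intensity_err = NULL,
                            scattering_angle = 40, polarization = "ppp",
                            metadata = list()) {
  stopifnot(is.numeric(concentration), is.numeric(intensity),
            length(concentration) == length(intensity),
            all(is.finite(concentration)), all(is.finite(intensity)))
  if (any(concentration < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be >= 0", call. = FALSE)
  out <- data.frame(concentration = concentration, intensity = intensity)
  if (!is.null(intensity_err)) {
    stopifnot(is.numeric(intensity_err),
              length(intensity_err) == length(concentration))
    if (any(!is.finite(intensity_err)) || any(intensity_err <= 0))
      stop("intensity errors must be > 0", call. = FALSE)
    out$intensity_err <- intensity_err
  }
  class(out) <- c("titration_curve", class(out))
  attr(out, "scattering_angle") <- as.numeric(scattering_angle)
  attr(out, "polarization") <- as.character(polarization)
  attr(out, "metadata") <- metadata
  out
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %d points, %g deg %s\n",
              nrow(x), attr(x, "scattering_angle"), attr(x, "polarization")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# normalise a curve or list of curves to a plain list of curves
.as_curve_list <- function(curves) {
  if (inherits(curves, "titration_curve")) return(list(curves))
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "titration_curve")))
  curves
}
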