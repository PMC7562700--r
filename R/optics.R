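#' Scattering-particle specification
#'
#' Bundles the microscopic parameters that determine the bulk scattering
#' coefficient of a particle suspension: particle radius, number density,
#' particle and medium refractive indices, and the illumination wavelength.
#' All lengths are in micrometres, the natural scale for emulsion droplets
#' and optical wavelengths; [mus_from_particles()] converts its result to
#' mm^-1 at the module boundary.
#'
#' @param r Particle radius (um), > 0.
#' @param rho_s Particle number density (um^-3), > 0.
#' @param n_s Particle refractive index, > 0.
#' @param n_m Medium (background) refractive index, > 0.
#' @param wavelength Illumination wavelength (um), > 0.
#'
#' @return An object of class `particle_spec`.
#' @examples
#' particle_spec(r = 0.25, rho_s = 0.01, n_s = 1.46, n_m = 1.33,
#'               wavelength = 0.633)
#' @export
particle_spec <- function(r, rho_s, n_s, n_m, wavelength) {
  for (nm in c("r", "rho_s", "n_s", "n_m", "wavelength")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  structure(
    list(r = r, rho_s = rho_s, n_s = n_s, n_m = n_m,
         wavelength = wavelength),
    class = "particle_spec"
  )
}

#' Bulk scattering coefficient from particle properties
#'
#' Empirical power-law model for the scattering coefficient of a dilute
#' particle suspension,
#' \deqn{\mu_s = 3.28\,\pi r^2 \rho_s (2\pi r/\lambda)^{0.37}
#'       (n_s/n_m - 1)^{2.09},}
#' with all lengths in um so that the intermediate value is in um^-1; the
#' return value is converted to mm^-1. The relative refractive index must
#' satisfy `n_s >= n_m`: the fractional exponent is undefined for a negative
#' base, and media with particles optically rarer than the background are
#' outside the model's calibration, so they are rejected rather than
#' silently absolutized.
#'
#' @param spec A [particle_spec()].
#' @return Scattering coefficient (mm^-1), >= 0.
#' @examples
#' ps <- particle_spec(0.25, 0.01, 1.46, 1.33, 0.633)
#' mus_from_particles(ps)
#' @export
mus_from_particles <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  if (spec$n_s < spec$n_m) {
    stop("n_s < n_m: relative refractive index below 1 is outside the ",
         "model's domain (fractional power of a negative base)",
         call. = FALSE)
  }
  mus_um <- 3.28 * pi * spec$r^2 * spec$rho_s *
    (2 * pi * spec$r / spec$wavelength)^0.37 *
    (spec$n_s / spec$n_m - 1)^2.09
  mus_um * 1000  # um^-1 -> mm^-1
}

#' Fit a linear temperature-to-scattering calibration
#'
#' Ordinary least-squares line through (temperature, mu_s) pairs measured on
#' a scattering phantom. Lipid emulsions have a negative temperature
#' coefficient: heating lowers particle density and index mismatch, so mu_s
#' falls roughly linearly over physiological temperatures. The fitted line
#' maps any temperature to mu_s; predictions outside the fitted temperature
#' range are flagged as extrapolations.
#'
#' @param temperature Temperatures (degrees C), at least two distinct values.
#' @param mus Scattering coefficients (mm^-1), same length.
#' @return An object of class `mus_calibration` with elements `slope`
#'   (mm^-1 per degree C), `intercept` (mm^-1 at 0 C), `valid_range`,
#'   `points` and `residuals`.
#' @examples
#' cal <- fit_mus_calibration(c(22, 32, 37), c(18.4, 16.6, 15.7))
#' cal$slope      # -0.18
#' cal$intercept  # 22.36
#' @seealso [mus_at_temperature()], [cletus_calibration()]
#' @export
fit_mus_calibration <- function(temperature, mus) {
  stopifnot(is.numeric(temperature), is.numeric(mus),
            length(temperature) == length(mus))
  if (length(temperature) < 2L) {
    stop("at least two calibration points are required", call. = FALSE)
  }
  if (anyDuplicated(temperature)) {
    dup <- temperature[duplicated(temperature)]
    conflict <- vapply(unique(dup), function(t) {
      length(unique(mus[temperature == t])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("duplicate temperatures with conflicting mu_s values",
           call. = FALSE)
    }
    keep <- !duplicated(temperature)
    temperature <- temperature[keep]
    mus <- mus[keep]
    if (length(temperature) < 2L) {
      stop("at least two distinct temperatures are required", call. = FALSE)
    }
  }
  fit <- stats::lm(mus ~ temperature)
  cal <- structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      valid_range = range(temperature),
      points = data.frame(temperature = temperature, mus = mus),
      residuals = unname(stats::residuals(fit))
    ),
    class = "mus_calibration"
  )
  lo <- predict_mus(cal, cal$valid_range)
  if (any(lo <= 0)) {
    stop("fitted line predicts non-positive mu_s inside the calibration ",
         "range", call. = FALSE)
  }
  cal
}

predict_mus <- function(cal, temperature) {
  cal$slope * temperature + cal$intercept
}

#' Default lipid-phantom calibration
#'
#' The linear calibration through the published intralipid measurements
#' mu_s = 18.4, 16.6, 15.7 mm^-1 at 22, 32, 37 degrees C (Cletus et al.).
#' The three points are exactly collinear, giving slope -0.18 mm^-1/C and
#' intercept 22.36 mm^-1.
#'
#' @return A `mus_calibration`.
#' @examples
#' mus_at_temperature(cletus_calibration(), 32)  # 16.6
#' @export
cletus_calibration <- function() {
  fit_mus_calibration(c(22, 32, 37), c(18.4, 16.6, 15.7))
}

#' Scattering coefficient at a temperature
#'
#' Evaluates a fitted calibration line at temperature `T_C`. Temperatures
#' outside the calibrated range are permitted (the 42 C heated tunnel sits
#' above the 22-37 C calibration span) but raise an extrapolation warning
#' unless `quiet = TRUE`; a non-positive predicted mu_s is an error.
#'
#' @param cal A [fit_mus_calibration()] result.
#' @param T_C Temperature(s) in degrees C.
#' @param quiet Suppress the extrapolation warning.
#' @return mu_s (mm^-1), same length as `T_C`, with attribute
#'   `extrapolated` (logical vector).
#' @examples
#' cal <- cletus_calibration()
#' mus_at_temperature(cal, 37)               # 15.7
#' mus_at_temperature(cal, 42, quiet = TRUE) # 14.8, extrapolated
#' @export
mus_at_temperature <- function(cal, T_C, quiet = FALSE) {
  stopifnot(inherits(cal, "mus_calibration"), is.numeric(T_C))
  mus <- predict_mus(cal, T_C)
  if (any(mus <= 0)) {
    stop("predicted mu_s <= 0 at T = ",
         paste(T_C[mus <= 0], collapse = ", "),
         " C: outside the physical domain of the calibration",
         call. = FALSE)
  }
  extrap <- T_C < cal$valid_range[1L] | T_C > cal$valid_range[2L]
  if (any(extrap) && !quiet) {
    warning("extrapolating mu_s(T) outside the calibrated range [",
            cal$valid_range[1L], ", ", cal$valid_range[2L], "] C at T = ",
            paste(T_C[extrap], collapse = ", "), " C", call. = FALSE)
  }
  attr(mus, "extrapolated") <- extrap
  mus
}

#' @export
print.mus_calibration <- function(x, ...) {
  cat("Temperature -> scattering calibration (linear)\n")
  cat(sprintf("  mu_s(T) = %.4g + (%.4g) * T  [mm^-1, T in C]\n",
              x$intercept, x$slope))
  cat(sprintf("  valid range: %g to %g C, %d points, max |residual| %.3g\n",
              x$valid_range[1L], x$valid_range[2L], nrow(x$points),
              max(abs(x$residuals))))
  invisible(x)
}

#' Write / read a calibration as JSON
#'
#' Round-trippable plain-JSON serialization of a `mus_calibration`
#' (`{points, slope, intercept, valid_range}`).
#'
#' @param cal A `mus_calibration`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the reconstructed `mus_calibration` (refit from the stored
#'   points, then checked against the stored coefficients).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "mus_calibration"))
  obj <- list(points = cal$points, slope = cal$slope,
              intercept = cal$intercept, valid_range = cal$valid_range)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal <- fit_mus_calibration(obj$points$temperature, obj$points$mus)
  if (abs(cal$slope - obj$slope) > 1e-8 ||
      abs(cal$intercept - obj$intercept) > 1e-8) {
    stop("stored coefficients disagree with a refit of the stored points",
         call. = FALSE)
  }
  cal
}

#' Per-material optical properties
#'
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param mu_s Scattering coefficient (mm^-1), >= 0.
#' @param g Scattering anisotropy (mean cosine), in (-1, 1).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_a = 0.05, mu_s = 16.6, g = 0.9)
#' @export
optical_properties <- function(mu_a, mu_s, g) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, mu_a >= 0,
            is.numeric(mu_s), length(mu_s) == 1L, mu_s >= 0,
            is.numeric(g), length(g) == 1L, g > -1, g < 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %g mm^-1, mu_s = %g mm^-1, g = %g\n",
              x$mu_a, x$mu_s, x$g))
  invisible(x)
}
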