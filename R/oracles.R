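#' Beer-Lambert transmittance
#'
#' Exponential attenuation of unscattered light, `exp(-mu_a * depth)`: the
#' closed-form oracle for the scattering-free limit of the phantom.
#'
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param depth Path length (mm), >= 0.
#' @return Transmittance in (0, 1].
#' @examples
#' beer_lambert(0.05, 5)  # exp(-0.25)
#' @export
beer_lambert <- function(mu_a, depth) {
  stopifnot(mu_a >= 0, depth >= 0)
  exp(-mu_a * depth)
}

#' Diffusion-approximation point-source fluence
#'
#' Steady-state fluence at distance `r` from an isotropic unit point source
#' in an infinite homogeneous medium, in the diffusion approximation:
#' \deqn{\phi(r) = \frac{e^{-\mu_{eff} r}}{4 \pi D r},\quad
#'   D = \frac{1}{3(\mu_a + \mu_s')},\quad
#'   \mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}.}
#' Valid when `mu_s_reduced >> mu_a` and a few transport mean free paths
#' from the source; an attribute flags calls outside that regime.
#'
#' @param r Distance(s) from the source (mm), > 0.
#' @param mu_a Absorption coefficient (mm^-1).
#' @param mu_s_reduced Reduced scattering coefficient `mu_s (1 - g)`
#'   (mm^-1).
#' @return Fluence (mm^-2) per unit source power, with attribute `valid`
#'   (`FALSE` when `mu_s_reduced < 10 mu_a`).
#' @examples
#' diffusion_point_source(3, 0.05, 1.66)
#' @export
diffusion_point_source <- function(r, mu_a, mu_s_reduced) {
  stopifnot(mu_a >= 0, mu_s_reduced > 0)
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  D <- 1 / (3 * (mu_a + mu_s_reduced))
  mu_eff <- sqrt(3 * mu_a * (mu_a + mu_s_reduced))
  phi <- exp(-mu_eff * r) / (4 * pi * D * r)
  attr(phi, "valid") <- mu_s_reduced >= 10 * mu_a
  phi
}

#' Henyey-Greenstein first-moment check
#'
#' Draws `n_samples` deflection cosines from [sample_hg()] and compares
#' their mean against the anisotropy `g` (the phase function's defining
#' identity, mean cosine = g). Passes when the discrepancy is below four
#' standard errors of the sample mean.
#'
#' @param g Anisotropy in (-1, 1).
#' @param n_samples Number of draws.
#' @param seed RNG seed (R's generator; restored on exit).
#' @return An `oracle_report`.
#' @export
hg_moment_check <- function(g, n_samples = 1e6, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ct <- sample_hg(g, stats::runif(n_samples))
  m <- mean(ct)
  se <- stats::sd(ct) / sqrt(n_samples)
  oracle_report(
    scenario = sprintf("henyey-greenstein moment, g = %g", g),
    oracle = g, engine = m, tolerance = 4 * se,
    note = sprintf("sample mean over %g draws, SE %.2g", n_samples, se))
}

#' Construct an oracle comparison report
#'
#' @param scenario Short scenario label.
#' @param oracle Reference value(s) from the closed form.
#' @param engine Value(s) measured from the engine.
#' @param tolerance Maximum tolerated absolute error when `relative =
#'   FALSE`, else maximum |engine/oracle - 1|.
#' @param relative Compare on the relative scale.
#' @param note Free-text annotation.
#' @return An object of class `oracle_report` with `errors` and `pass`.
#' @export
oracle_report <- function(scenario, oracle, engine, tolerance,
                          relative = FALSE, note = "") {
  stopifnot(length(oracle) == length(engine))
  errors <- if (relative) abs(engine / oracle - 1) else abs(engine - oracle)
  structure(
    list(scenario = scenario, oracle = oracle, engine = engine,
         errors = errors, tolerance = tolerance, relative = relative,
         pass = all(errors <= tolerance), note = note),
    class = "oracle_report"
  )
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("oracle check [%s]: %s\n", x$scenario,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  max %s error %.3g (tolerance %.3g)%s\n",
              if (x$relative) "relative" else "absolute",
              max(x$errors), x$tolerance,
              if (nzchar(x$note)) paste0("; ", x$note) else ""))
  invisible(x)
}

#' Shell-averaged radial fluence about a point
#'
#' Averages a fluence map over concentric spherical shells centred on
#' `center`, for comparison against [diffusion_point_source()].
#'
#' @param map A `fluence_map`.
#' @param center Centre (mm, length 3).
#' @param breaks Shell boundary radii (mm), increasing.
#' @return data.frame with `r` (volume-weighted mean voxel-centre radius)
#'   and `fluence` (mean over voxels in the shell).
#' @export
radial_fluence <- function(map, center, breaks) {
  stopifnot(inherits(map, "fluence_map"), length(center) == 3L)
  v <- map$voxel_size
  xc <- (seq_len(map$dims[1L]) - 0.5) * v - center[1L]
  yc <- (seq_len(map$dims[2L]) - 0.5) * v - center[2L]
  zc <- (seq_len(map$dims[3L]) - 0.5) * v - center[3L]
  r <- sqrt(outer(outer(xc^2, yc^2, `+`), zc^2, `+`))
  bin <- cut(as.vector(r), breaks)
  keep <- !is.na(bin)
  data.frame(
    r = tapply(as.vector(r)[keep], bin[keep], mean),
    fluence = tapply(as.vector(map$fluence)[keep], bin[keep], mean),
    row.names = NULL
  )
}

#' Run an end-to-end engine validation scenario
#'
#' Executes one of the oracle presets and compares the engine against the
#' matching closed form:
#' \describe{
#'   \item{`beer-lambert`}{Scattering-free slab; the transmitted weight
#'     inferred from the detector-layer pathlength tally must equal
#'     `exp(-mu_a * depth)` (exact for straight rays, tolerance 1e-9), and
#'     the far-face escape must equal `exp(-mu_a * extent)`.}
#'   \item{`diffusion`}{Isotropic point source in a quasi-infinite medium;
#'     shell-averaged fluence must match the diffusion closed form within
#'     10% for radii between `r_range` transport mean free paths (the
#'     tolerance reflects the approximation's own near-source and
#'     `mu_a/mu_s'` error, not engine noise).}
#' }
#'
#' @param name `"beer-lambert"` or `"diffusion"`.
#' @param config A [run_config()].
#' @param voxel_size Voxel edge (mm).
#' @param r_range Radial comparison window in transport mean free paths
#'   (diffusion only).
#' @return An `oracle_report`.
#' @export
run_validation <- function(name = c("beer-lambert", "diffusion"),
                           config = run_config(n_photons = 2e4),
                           voxel_size = NULL,
                           r_range = c(3, 8)) {
  name <- match.arg(name)
  if (name == "beer-lambert") {
    vs <- if (is.null(voxel_size)) 0.2 else voxel_size
    sc <- preset("validation-beer-lambert", voxel_size = vs)
    fm <- run_scenario(sc, config)
    ph <- sc$phantom
    iz <- fm$det_layer + 1L
    # per-photon pathlength through the tally layer, converted back to the
    # plane-entry weight via the exact in-layer decay factor
    layer_path <- sum(fm$fluence[, , iz]) * vs^3
    t_engine <- layer_path * ph$mu_a / (1 - exp(-ph$mu_a * vs))
    t_oracle <- beer_lambert(ph$mu_a, (iz - 1L) * vs)
    esc_oracle <- beer_lambert(ph$mu_a, ph$extent[3L])
    oracle_report(
      scenario = "beer-lambert slab (mu_s = 0)",
      oracle = c(t_oracle, esc_oracle),
      engine = c(t_engine, fm$ledger$escaped / fm$ledger$launched),
      tolerance = 1e-9, relative = TRUE,
      note = sprintf("transmittance at %g mm and far-face escape",
                     (iz - 1L) * vs))
  } else {
    vs <- if (is.null(voxel_size)) 0.3 else voxel_size
    sc <- preset("validation-diffusion", voxel_size = vs)
    fm <- run_scenario(sc, config)
    ph <- sc$phantom
    musp <- ph$baseline_optics$mu_s * (1 - ph$g)
    ltr <- 1 / (ph$mu_a + musp)
    breaks <- seq(r_range[1L] * ltr, r_range[2L] * ltr, by = vs)
    prof <- radial_fluence(fm, ph$extent / 2, breaks)
    phi <- diffusion_point_source(prof$r, ph$mu_a, musp)
    oracle_report(
      scenario = "diffusion point source, quasi-infinite medium",
      oracle = as.numeric(phi), engine = prof$fluence,
      tolerance = 0.10, relative = TRUE,
      note = sprintf("%d shells in %g-%g transport mfp; escape fraction %.2e",
                     nrow(prof), r_range[1L], r_range[2L],
                     fm$ledger$escaped / fm$ledger$launched))
  }
}
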