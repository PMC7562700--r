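#' Photon packet state
#'
#' @param position Numeric length-3 position (mm).
#' @param direction Numeric length-3 direction; must be unit within 1e-9.
#' @param weight Statistical weight in (0, 1].
#' @return An object of class `photon_state`.
#' @export
photon_state <- function(position, direction, weight = 1) {
  stopifnot(is.numeric(position), length(position) == 3L,
            is.numeric(direction), length(direction) == 3L,
            is.numeric(weight), length(weight) == 1L,
            weight > 0, weight <= 1)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("direction must be a unit vector (|d| = 1 within 1e-9)",
         call. = FALSE)
  }
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction),
                 weight = weight),
            class = "photon_state")
}

#' Sample a Gaussian-beam launch state
#'
#' Box-Muller sampling of the entry position of a collimated Gaussian beam:
#' the lateral offset follows a circular 2-D Gaussian with
#' sigma = FWHM / (2 sqrt(2 ln 2)), the direction is +z, and the weight is
#' exactly 1. This is the same transform the compiled engine applies to its
#' per-photon substream.
#'
#' @param source A [source_spec()] with `type = "gaussian"`.
#' @param u Numeric length-2 vector of uniforms in (0, 1).
#' @param entry Beam-axis entry point (mm, length 2, lateral x/y).
#' @return A [photon_state()].
#' @examples
#' launch_gaussian(source_spec(fwhm = 2), c(0.5, 0.25))
#' @export
launch_gaussian <- function(source, u, entry = c(10, 10)) {
  stopifnot(inherits(source, "source_spec"), source$type == "gaussian",
            is.numeric(u), length(u) == 2L, all(u > 0), all(u < 1))
  sigma <- fwhm_to_sigma(source$fwhm)
  r <- sigma * sqrt(-2 * log(u[1L]))
  photon_state(
    position = c(entry[1L] + r * cos(2 * pi * u[2L]),
                 entry[2L] + r * sin(2 * pi * u[2L]),
                 0),
    direction = c(0, 0, 1),
    weight = 1
  )
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Sample an exponential free-path length
#'
#' Inverse-CDF sampling of the distance to the next interaction in a medium
#' with total interaction coefficient `mu_t`: `s = -log(xi) / mu_t`.
#'
#' @param mu_t Interaction coefficient (mm^-1), > 0 (vacuum voxels are
#'   disallowed in the transport grid).
#' @param xi Uniform deviate(s) in (0, 1).
#' @return Step length(s) in mm.
#' @examples
#' sample_step(16.65, exp(-1))  # 1/16.65
#' @export
sample_step <- function(mu_t, xi) {
  stopifnot(is.numeric(mu_t), length(mu_t) == 1L)
  if (mu_t <= 0) stop("mu_t must be > 0", call. = FALSE)
  stopifnot(all(xi > 0), all(xi < 1))
  -log(xi) / mu_t
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the scattering angle cosine from the
#' Henyey-Greenstein phase function with anisotropy `g` (mean cosine g);
#' `g = 0` reduces to isotropic scattering.
#'
#' @param g Anisotropy factor in (-1, 1).
#' @param xi Uniform deviate(s) in (0, 1].
#' @return cos(theta) value(s) in \[-1, 1\].
#' @examples
#' sample_hg(0, 0.5)    # 0
#' sample_hg(0.9, 1)    # 1 (forward limit)
#' @export
sample_hg <- function(g, xi) {
  stopifnot(is.numeric(g), length(g) == 1L)
  if (abs(g) >= 1) stop("g must lie strictly inside (-1, 1)", call. = FALSE)
  if (g == 0) return(2 * xi - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * xi)
  ct <- (1 + g^2 - tmp^2) / (2 * g)
  pmin(1, pmax(-1, ct))
}

#' Rotate a direction by a scattering deflection
#'
#' Standard local-frame rotation: the new direction makes angle
#' `acos(cos_theta)` with the old one, at azimuth `phi` about it; the
#' near-vertical case uses the +/-z special-case formula. The result is
#' renormalized to unit length.
#'
#' @param direction Unit length-3 vector.
#' @param cos_theta Deflection cosine in \[-1, 1\].
#' @param phi Azimuth (radians).
#' @return Unit length-3 vector.
#' @export
spin_direction <- function(direction, cos_theta, phi) {
  stopifnot(is.numeric(direction), length(direction) == 3L,
            abs(sqrt(sum(direction^2)) - 1) < 1e-9,
            cos_theta >= -1, cos_theta <= 1)
  st <- sqrt(max(0, 1 - cos_theta^2))
  cp <- cos(phi); sp <- sin(phi)
  ux <- direction[1L]; uy <- direction[2L]; uz <- direction[3L]
  if (abs(uz) > 0.99999) {
    out <- c(st * cp, st * sp, cos_theta * sign(uz + (uz == 0)))
  } else {
    den <- sqrt(1 - uz^2)
    out <- c(st * (ux * uz * cp - uy * sp) / den + ux * cos_theta,
             st * (uy * uz * cp + ux * sp) / den + uy * cos_theta,
             -den * st * cp + uz * cos_theta)
  }
  out / sqrt(sum(out^2))
}

phantom_n_rel <- function(phantom) {
  if (is.null(phantom$n_rel)) 1 else phantom$n_rel
}

detector_layer <- function(detector, phantom) {
  t <- detector$depth / phantom$voxel_size
  iz <- if (abs(t - round(t)) < 1e-6) round(t) else floor(t)
  iz <- as.integer(iz)
  if (iz < 0L || iz >= phantom$dims[3L]) {
    stop("detector plane lies outside the grid", call. = FALSE)
  }
  iz  # 0-based deeper-side layer
}

#' Trace a single photon packet through a phantom
#'
#' Runs the hop-drop-spin walk of one packet on the compiled engine and
#' returns its per-voxel pathlength deposits together with the exit record.
#' Intended for oracle tests (e.g. Beer-Lambert single rays) and debugging;
#' production runs use [run_scenario()].
#'
#' @param phantom A [build_cube()] phantom.
#' @param photon A [photon_state()].
#' @param config A [run_config()]; supplies roulette parameters, the step
#'   cap and the seed of the packet's random substream.
#' @param stream Substream index (photon number) within the seed.
#' @return A list with `deposit` (3-D array of weight x pathlength, mm),
#'   `status` (`"escaped"`, `"roulette"` or `"capped"`), exit `position`,
#'   `direction` and `weight`, and the packet's ledger entries.
#' @export
propagate_photon <- function(phantom, photon, config = run_config(),
                             stream = 0) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(photon, "photon_state"),
            inherits(config, "run_config"))
  p <- photon$position
  if (any(p < 0) || any(p > phantom$extent)) {
    stop("photon starts outside the grid", call. = FALSE)
  }
  res <- propagate_photon_cpp(
    phantom$dims, phantom$voxel_size, phantom$mu_a, as.vector(phantom$mu_s),
    phantom$g, p, photon$direction, photon$weight,
    config$seed, stream, config$weight_threshold, config$survival_prob,
    config$max_steps, phantom_n_rel(phantom))
  res$deposit <- array(res$deposit_raw, dim = phantom$dims)
  res$deposit_raw <- NULL
  res
}

#' Run a Monte Carlo transport simulation
#'
#' Launches `config$n_photons` weighted packets from the scenario's source
#' through the phantom's voxel grid and accumulates the per-voxel fluence
#' (pathlength estimator: weight x traversed length per voxel, with
#' continuous absorption `exp(-mu_a l)` folded in, normalized per launched
#' photon and per voxel volume, units mm^-2). Reruns with the same seed are
#' bit-identical. The returned map carries an energy-conservation ledger
#' and per-batch detector-layer tallies for batch-means standard errors.
#'
#' @param scenario A [preset()] or hand-built `scenario`.
#' @param config A [run_config()].
#' @param phantom Optional phantom overriding `scenario$phantom` (e.g. the
#'   tunnel-carved phantom of a heated arm).
#' @param tally_plane Additionally tally the photon weight crossing the
#'   detector-depth plane in the +z direction (a transmitted-flux tally,
#'   the alternative reading of a "detected energy at depth"); read it
#'   with [read_detector_plane()].
#' @return An object of class `fluence_map`: `fluence` (3-D array, mm^-2),
#'   `ledger`, `voxel_size`, `n_photons`, `seed`, `det_layer` (0-based) and
#'   batch tallies.
#' @examples
#' \donttest{
#' sc <- preset("validation-beer-lambert")
#' fm <- run_scenario(sc, run_config(n_photons = 1e4, seed = 1))
#' fm$ledger
#' }
#' @export
run_scenario <- function(scenario, config = run_config(), phantom = NULL,
                         tally_plane = FALSE) {
  stopifnot(inherits(scenario, "scenario"), inherits(config, "run_config"))
  ph <- if (is.null(phantom)) scenario$phantom else phantom
  stopifnot(inherits(ph, "voxel_phantom"))
  src <- scenario$source
  src_type <- if (src$type == "gaussian") 0L else 1L
  src_pos <- if (is.null(src$position)) ph$extent / 2 else src$position
  sigma <- if (src_type == 0L) fwhm_to_sigma(src$fwhm) else 0
  det_layer <- detector_layer(scenario$detector, ph)
  plane_iz <- if (tally_plane) det_layer else -1L

  res <- mc_run_cpp(
    ph$dims, ph$voxel_size, ph$mu_a, as.vector(ph$mu_s), ph$g,
    src_type, src_pos, sigma,
    config$n_photons, config$seed,
    config$weight_threshold, config$survival_prob,
    config$max_steps, config$n_batches, det_layer,
    phantom_n_rel(ph), plane_iz)

  norm <- config$n_photons * ph$voxel_size^3
  ledger <- list(launched = res$launched, absorbed = res$absorbed,
                 escaped = res$escaped, roulette_net = res$roulette_net,
                 capped = res$capped, capped_count = res$capped_count)
  if (res$capped_count > 0) {
    warning(res$capped_count, " photon packet(s) hit the step cap",
            call. = FALSE)
  }
  structure(
    list(
      fluence = array(res$fluence_raw / norm, dim = ph$dims),
      ledger = ledger,
      voxel_size = ph$voxel_size,
      dims = ph$dims,
      n_photons = config$n_photons,
      n_batches = config$n_batches,
      seed = config$seed,
      det_layer = det_layer,
      det_batches = if (!is.null(res$det_batches)) {
        array(res$det_batches, dim = c(ph$dims[1L], ph$dims[2L],
                                       config$n_batches))
      },
      plane = if (!is.null(res$plane_raw)) {
        matrix(res$plane_raw / config$n_photons,
               ph$dims[1L], ph$dims[2L])
      },
      batch_n = res$batch_n
    ),
    class = "fluence_map"
  )
}

#' @export
print.fluence_map <- function(x, ...) {
  led <- x$ledger
  cat(sprintf("fluence map: %d x %d x %d voxels (%g mm), %g photons, seed %d\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$voxel_size,
              x$n_photons, x$seed))
  cat(sprintf("  ledger: absorbed %.4f, escaped %.4f, roulette %.2e, capped %g (closure %.2e)\n",
              led$absorbed / led$launched, led$escaped / led$launched,
              led$roulette_net / led$launched, led$capped_count,
              ledger_closure(x)))
  invisible(x)
}

#' Energy-conservation closure of a run ledger
#'
#' Relative imbalance `(absorbed + escaped + roulette_net + capped -
#' launched) / launched`; should be at floating-point level (< 1e-6) for
#' every run.
#'
#' @param map A `fluence_map`.
#' @return Signed relative closure error.
#' @export
ledger_closure <- function(map) {
  led <- map$ledger
  (led$absorbed + led$escaped + led$roulette_net + led$capped -
     led$launched) / led$launched
}

#' Export a fluence map as text files
#'
#' Writes the 3-D fluence grid as a gzip-compressed CSV of flattened values
#' (column-major, x fastest) plus a JSON sidecar with grid metadata, the
#' seed, photon count and conservation ledger.
#'
#' @param map A `fluence_map`.
#' @param dir Output directory (created if needed).
#' @param stem File stem for the pair of files.
#' @return Invisibly, the paths written.
#' @export
export_fluence <- function(map, dir, stem = "fluence") {
  stopifnot(inherits(map, "fluence_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(dir, paste0(stem, ".csv.gz"))
  con <- gzfile(data_path, "w")
  utils::write.csv(data.frame(fluence = as.vector(map$fluence)), con,
                   row.names = FALSE)
  close(con)
  meta_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(dims = map$dims, voxel_size_mm = map$voxel_size,
         axis_order = "x-fastest (R column-major)",
         units = "per-voxel fluence, mm^-2 per launched photon",
         n_photons = map$n_photons, seed = map$seed,
         ledger = map$ledger),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, meta_path))
}
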