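aperture_axis_overlap <- function(n, voxel, center, half_side) {
  lo <- center - half_side
  hi <- center + half_side
  edges_lo <- (seq_len(n) - 1) * voxel
  edges_hi <- seq_len(n) * voxel
  ov <- pmin(hi, edges_hi) - pmax(lo, edges_lo)
  pmax(0, ov) / voxel
}

#' Read a detector from a fluence map
#'
#' Sums per-voxel fluence over the square aperture of the detector,
#' restricted to the voxel layer containing the detection depth; voxels
#' partially covered by the aperture contribute in proportion to the
#' covered area fraction. The Monte Carlo standard error comes from the
#' run's batch-means tallies when the detector layer matches the one
#' tallied during the run.
#'
#' @param map A [run_scenario()] `fluence_map`.
#' @param det A [detector_spec()].
#' @return An object of class `detector_reading` with `value` (summed
#'   fluence per launched photon), `se` and `batch_values`.
#' @export
read_detector <- function(map, det) {
  stopifnot(inherits(map, "fluence_map"), inherits(det, "detector_spec"))
  v <- map$voxel_size
  dims <- map$dims
  half <- sqrt(det$area) / 2
  cx <- dims[1L] * v / 2
  cy <- dims[2L] * v / 2
  if (cx - half < 0 || cx + half > dims[1L] * v ||
      cy - half < 0 || cy + half > dims[2L] * v) {
    stop("aperture extends outside the grid", call. = FALSE)
  }
  ph <- list(voxel_size = v, dims = dims)
  iz <- detector_layer(det, ph) + 1L  # 1-based
  wx <- aperture_axis_overlap(dims[1L], v, cx, half)
  wy <- aperture_axis_overlap(dims[2L], v, cy, half)
  w <- outer(wx, wy)
  value <- sum(map$fluence[, , iz] * w)

  batch_values <- NULL
  se <- NA_real_
  if (!is.null(map$det_batches) && (iz - 1L) == map$det_layer) {
    nb <- dim(map$det_batches)[3L]
    batch_values <- vapply(seq_len(nb), function(b) {
      sum(map$det_batches[, , b] * w) / (map$batch_n[b] * v^3)
    }, numeric(1))
    se <- stats::sd(batch_values) / sqrt(nb)
  }
  structure(list(value = value, se = se, batch_values = batch_values,
                 depth = det$depth, area = det$area),
            class = "detector_reading")
}

#' @export
print.detector_reading <- function(x, ...) {
  cat(sprintf("detector reading: %.6g (SE %.3g) over %g mm^2 at %g mm depth\n",
              x$value, x$se, x$area, x$depth))
  invisible(x)
}

#' Read the transmitted-flux plane tally
#'
#' Alternative detector reading for sensitivity analysis: the photon
#' weight crossing the detection-depth plane in the +z direction, summed
#' over the aperture (with partial-voxel area weighting). Requires a map
#' from [run_scenario()] with `tally_plane = TRUE`.
#'
#' @param map A `fluence_map` carrying a plane tally.
#' @param det A [detector_spec()].
#' @return A `detector_reading` (no batch-means SE).
#' @export
read_detector_plane <- function(map, det) {
  stopifnot(inherits(map, "fluence_map"), inherits(det, "detector_spec"))
  if (is.null(map$plane)) {
    stop("map has no plane tally; rerun with tally_plane = TRUE",
         call. = FALSE)
  }
  v <- map$voxel_size
  dims <- map$dims
  half <- sqrt(det$area) / 2
  cx <- dims[1L] * v / 2
  cy <- dims[2L] * v / 2
  wx <- aperture_axis_overlap(dims[1L], v, cx, half)
  wy <- aperture_axis_overlap(dims[2L], v, cy, half)
  value <- sum(map$plane * outer(wx, wy))
  structure(list(value = value, se = NA_real_, batch_values = NULL,
                 depth = det$depth, area = det$area),
            class = "detector_reading")
}

#' Percent fluence improvement between paired runs
#'
#' `percent = 100 * (heated - baseline) / baseline`. When both readings
#' carry batch tallies from a common-random-numbers pair, the standard
#' error is the batch-means spread of the per-batch paired percent
#' improvements; otherwise first-order (unpaired) propagation is used.
#'
#' @param baseline,heated [read_detector()] readings.
#' @param descriptor Optional list describing the scenario (diameter,
#'   temperature rise, ...) carried through to results tables.
#' @return An object of class `improvement_result`.
#' @examples
#' b <- structure(list(value = 1, se = 0, batch_values = NULL),
#'                class = "detector_reading")
#' h <- structure(list(value = 1.107, se = 0, batch_values = NULL),
#'                class = "detector_reading")
#' improvement(b, h)$percent  # 10.7
#' @export
improvement <- function(baseline, heated, descriptor = list()) {
  stopifnot(inherits(baseline, "detector_reading"),
            inherits(heated, "detector_reading"))
  if (!(baseline$value > 0)) {
    stop("baseline detector reading must be positive", call. = FALSE)
  }
  percent <- 100 * (heated$value - baseline$value) / baseline$value
  se_percent <- NA_real_
  paired <- !is.null(baseline$batch_values) && !is.null(heated$batch_values) &&
    length(baseline$batch_values) == length(heated$batch_values)
  if (paired) {
    # linearized paired batch means: percent = 100 (H - B)/B propagates the
    # per-batch pairs through d_b = h_b - (H/B) b_b; exactly zero spread for
    # identical arms
    ratio <- heated$value / baseline$value
    p_b <- 100 * (heated$batch_values - ratio * baseline$batch_values) /
      baseline$value
    se_percent <- stats::sd(p_b) / sqrt(length(p_b))
  } else if (is.finite(baseline$se) && is.finite(heated$se)) {
    b <- baseline$value; h <- heated$value
    se_percent <- 100 * sqrt(heated$se^2 / b^2 + h^2 * baseline$se^2 / b^4)
  }
  structure(list(baseline = baseline, heated = heated,
                 percent = percent, se_percent = se_percent,
                 descriptor = descriptor),
            class = "improvement_result")
}

#' @export
print.improvement_result <- function(x, ...) {
  d <- x$descriptor
  if (length(d)) {
    cat(sprintf("scenario: %s\n",
                paste(names(d), unlist(lapply(d, paste, collapse = "/")),
                      sep = " = ", collapse = ", ")))
  }
  cat(sprintf("fluence improvement: %+.2f%% (SE %.2f)  [baseline %.5g, heated %.5g]\n",
              x$percent, x$se_percent, x$baseline$value, x$heated$value))
  invisible(x)
}

#' Paired baseline/heated run of a tunnel scenario
#'
#' Runs the scenario's phantom without and with its heating tunnel under
#' the same seed, so both arms share per-photon random substreams (common
#' random numbers), and returns the percent improvement of the detector
#' reading. This pairing removes most of the launch- and path-sampling
#' noise from the improvement ratio.
#'
#' @param scenario A `scenario` with a non-`NULL` `tunnel`.
#' @param config A [run_config()].
#' @param keep_maps Also return the two fluence maps (large).
#' @return An `improvement_result`; with `keep_maps = TRUE`, the maps are
#'   attached as `$maps`.
#' @export
run_paired <- function(scenario, config = run_config(), keep_maps = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(scenario$tunnel)) {
    stop("scenario has no tunnel to pair against", call. = FALSE)
  }
  heated_ph <- carve_tunnel(scenario$phantom, scenario$tunnel, quiet = TRUE)
  base_map <- run_scenario(scenario, config)
  heat_map <- run_scenario(scenario, config, phantom = heated_ph)
  res <- improvement(
    read_detector(base_map, scenario$detector),
    read_detector(heat_map, scenario$detector),
    descriptor = list(
      name = scenario$name,
      diameter = scenario$tunnel$diameter,
      delta_T = scenario$tunnel$delta_T,
      baseline_T = scenario$phantom$baseline_T,
      seed = config$seed,
      n_photons = config$n_photons
    )
  )
  if (keep_maps) res$maps <- list(baseline = base_map, heated = heat_map)
  res
}

#' Diameter x temperature sweep of the single-layer tunnel
#'
#' Reproduces the single-layer tunnel study: for every temperature rise,
#' the cube baseline is `42 - delta_T` C and the tunnel interior is 42 C;
#' each (diameter, delta_T) cell is a common-random-numbers paired run
#' against the matching unheated cube. One baseline run per temperature is
#' shared across the diameters.
#'
#' @param diameters Tunnel diameters (mm).
#' @param delta_Ts Temperature rises (degrees C).
#' @param config A [run_config()].
#' @param voxel_size Voxel edge (mm).
#' @return A data.frame with one row per (diameter, delta_T):
#'   `diameter_mm`, `delta_T_C`, `baseline`, `heated`, `percent`,
#'   `se_percent`, `seed`, `n_photons`, sorted by `delta_T_C` then
#'   `diameter_mm`.
#' @export
sweep_improvement <- function(diameters, delta_Ts, config = run_config(),
                              voxel_size = 0.2) {
  stopifnot(length(diameters) >= 1L, length(delta_Ts) >= 1L)
  rows <- list()
  for (dT in sort(delta_Ts)) {
    sc <- preset("model1", diameter = diameters[1L], delta_T = dT,
                 voxel_size = voxel_size)
    base_map <- run_scenario(sc, config)
    base_read <- read_detector(base_map, sc$detector)
    for (d in sort(diameters)) {
      tun <- tunnel_spec(d, dT, height = 5, z_start = 0)
      heated_ph <- carve_tunnel(sc$phantom, tun, quiet = TRUE)
      heat_map <- run_scenario(sc, config, phantom = heated_ph)
      imp <- improvement(base_read, read_detector(heat_map, sc$detector))
      rows[[length(rows) + 1L]] <- data.frame(
        diameter_mm = d, delta_T_C = dT,
        baseline = imp$baseline$value, heated = imp$heated$value,
        percent = imp$percent, se_percent = imp$se_percent,
        seed = config$seed, n_photons = config$n_photons)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$delta_T_C, out$diameter_mm), , drop = FALSE]
}
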