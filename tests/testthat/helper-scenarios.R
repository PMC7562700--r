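# Small in-code fixtures shared across the suite. All phantoms are built at
# run time; nothing is read from disk.

fast_cfg <- function(n_photons = 2000, seed = 1, ...) {
  run_config(n_photons = n_photons, seed = seed, ...)
}

# homogeneous phantom with fixed optics (no temperature calibration)
tiny_phantom <- function(extent = 10, voxel = 0.5, mu_a = 0.1, mu_s = 5,
                         g = 0.8, n_rel = 1) {
  build_cube(extent, voxel, baseline_T = 32,
             optical_properties(mu_a, mu_s, g), calibration = NULL,
             n_rel = n_rel)
}

make_scenario <- function(phantom, source = source_spec(fwhm = 1),
                          detector = detector_spec(depth = 2, area = 1),
                          tunnel = NULL, name = "test") {
  structure(list(name = name, phantom = phantom, tunnel = tunnel,
                 source = source, detector = detector, params = list()),
            class = "scenario")
}

# fluence_map with a constant fluence value, for detector arithmetic tests
constant_map <- function(value, dims = c(20L, 20L, 20L), voxel = 0.2) {
  structure(
    list(fluence = array(value, dim = dims), voxel_size = voxel,
         dims = dims, n_photons = 1, n_batches = 1, seed = 0,
         det_layer = 0L, det_batches = NULL, plane = NULL, batch_n = 1,
         ledger = list(launched = 1, absorbed = 0, escaped = 1,
                       roulette_net = 0, capped = 0, capped_count = 0)),
    class = "fluence_map"
  )
}

reading_of <- function(value, se = 0, batches = NULL) {
  structure(list(value = value, se = se, batch_values = batches,
                 depth = 5, area = 1),
            class = "detector_reading")
}
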