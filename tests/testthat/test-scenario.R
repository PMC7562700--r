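test_that("cube phantoms resolve temperature to scattering per voxel", {
  ph <- build_cube(20, 0.2, 32, optical_properties(0.05, 16.6, 0.9),
                   cletus_calibration())
  expect_equal(ph$dims, c(100L, 100L, 100L))
  expect_true(all(ph$mu_s == 16.6))
  expect_equal(ph$mu_a, 0.05)
  expect_equal(ph$g, 0.9)

  # degenerate single-voxel grid
  one <- build_cube(20, 20, 32, optical_properties(0.05, 16.6, 0.9),
                    cletus_calibration())
  expect_equal(one$dims, c(1L, 1L, 1L))

  # baseline outside the calibrated range still builds, with a warning
  expect_warning(
    hot <- build_cube(10, 0.5, 42, optical_properties(0.05, 16.6, 0.9),
                      cletus_calibration()),
    "extrapolating")
  expect_equal(range(hot$mu_s), c(14.8, 14.8), tolerance = 1e-12)

  expect_error(
    build_cube(20, 0.3, 32, optical_properties(0.05, 16.6, 0.9),
               cletus_calibration()),
    "integer multiple")
})

test_that("tunnel carving sets the heated scattering levels", {
  ph <- build_cube(20, 0.2, 32, optical_properties(0.05, 16.6, 0.9),
                   cletus_calibration())

  # null heating leaves the resolved optics untouched
  null_carve <- carve_tunnel(ph, tunnel_spec(4, 0), quiet = TRUE)
  expect_identical(null_carve$mu_s, ph$mu_s)
  expect_identical(null_carve$temperature, ph$temperature)

  heated <- carve_tunnel(ph, tunnel_spec(4, 10, height = 5), quiet = TRUE)
  expect_equal(sort(unique(as.vector(heated$mu_s))), c(14.8, 16.6))
  # tunnel voxels only inside z < 5 mm
  expect_true(all(heated$mu_s[, , 26:100] == 16.6))
  expect_true(any(abs(heated$mu_s[, , 1] - 14.8) < 1e-9))

  # carving is idempotent
  again <- carve_tunnel(heated, tunnel_spec(4, 10, height = 5),
                        quiet = TRUE)
  expect_identical(again$mu_s, heated$mu_s)

  expect_error(carve_tunnel(ph, tunnel_spec(30, 10)), "does not fit")
  expect_error(tunnel_spec(c(4, 2), c(5, 10)), "strictly increasing")
})

test_that("voxelized tunnel volume converges to the analytic cylinder", {
  cal <- cletus_calibration()
  for (case in list(list(voxel = 0.2, tol = 0.04),
                    list(voxel = 0.1, tol = 0.02))) {
    ph <- build_cube(20, case$voxel, 32,
                     optical_properties(0.05, 16.6, 0.9), cal)
    heated <- carve_tunnel(ph, tunnel_spec(4, 10, height = 5),
                           quiet = TRUE)
    vox_volume <- sum(abs(heated$mu_s - 14.8) < 1e-9) * case$voxel^3
    expect_equal(vox_volume, pi * 2^2 * 5, tolerance = case$tol)
  }
})

test_that("layered tunnels resolve k + 1 scattering levels with inner-wins", {
  ph <- build_cube(20, 0.2, 32, optical_properties(0.05, 16.6, 0.9),
                   cletus_calibration())
  spec <- tunnel_spec(c(1, 2, 3, 4), c(10, 7.5, 5, 2.5), height = 5)
  heated <- carve_tunnel(ph, spec, quiet = TRUE)
  levels <- sort(unique(as.vector(heated$mu_s)))
  expect_equal(levels, c(14.8, 15.25, 15.7, 16.15, 16.6))

  # per-layer voxel counts match an independent voxel-centre count oracle
  v <- 0.2
  counts <- vapply(levels[1:4], function(l) {
    sum(abs(heated$mu_s - l) < 1e-9)
  }, numeric(1))
  cc <- (seq_len(100) - 0.5) * v - 10   # voxel-centre lateral offsets
  r2 <- outer(cc^2, cc^2, `+`)
  n_layers <- sum((seq_len(100) - 0.5) * v < 5)
  in_disc <- vapply(spec$diameter / 2, function(r) sum(r2 <= r^2),
                    numeric(1))
  expect_equal(counts, (in_disc - c(0, in_disc[-4])) * n_layers)

  # the outermost (4 mm) cylinder volume is close to analytic
  expect_equal(sum(counts) * v^3, pi * 2^2 * 5, tolerance = 0.04)

  # the core (innermost) is at the hottest level
  centre <- heated$mu_s[50, 50, 1]
  expect_equal(centre, 14.8)
})

test_that("presets build the documented scenarios and round-trip as JSON", {
  m1 <- preset("model1", diameter = 4, delta_T = 10)
  expect_equal(m1$source$fwhm, 2)
  expect_equal(m1$phantom$baseline_T, 32)
  expect_equal(m1$tunnel$diameter, 4)

  m2 <- preset("model2")
  expect_equal(m2$source$fwhm, 1)
  expect_equal(max(m2$tunnel$diameter), 4)
  expect_length(m2$tunnel$delta_T, 4)

  bl <- preset("validation-beer-lambert")
  expect_true(all(bl$phantom$mu_s == 0))
  expect_equal(bl$phantom$mu_a, 0.05)

  expect_error(preset("no-such-model"), "unknown preset")

  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(m1, path)
  back <- read_scenario(path)
  expect_equal(back$phantom$mu_s, m1$phantom$mu_s)
  expect_equal(back$tunnel$delta_T, m1$tunnel$delta_T)
  expect_equal(back$source$fwhm, m1$source$fwhm)
  expect_equal(back$detector$area, m1$detector$area)
})
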