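test_that("particle scattering formula matches its closed form", {
  # index-matched suspension scatters nothing
  matched <- particle_spec(r = 0.3, rho_s = 0.02, n_s = 1.4, n_m = 1.4,
                           wavelength = 0.633)
  expect_identical(mus_from_particles(matched), 0)

  # frozen high-precision evaluation of the closed form
  ps <- particle_spec(r = 0.25, rho_s = 0.01, n_s = 1.46, n_m = 1.33,
                      wavelength = 0.633)
  expect_equal(mus_from_particles(ps), 0.0698618999175386, tolerance = 1e-12)

  # linear in particle density
  ps2 <- particle_spec(r = 0.25, rho_s = 0.02, n_s = 1.46, n_m = 1.33,
                       wavelength = 0.633)
  expect_equal(mus_from_particles(ps2), 2 * mus_from_particles(ps),
               tolerance = 1e-12)

  # optically rarer particles are outside the model's domain
  expect_error(
    mus_from_particles(particle_spec(0.25, 0.01, 1.30, 1.33, 0.633)),
    "n_s < n_m")
  expect_error(particle_spec(-0.1, 0.01, 1.46, 1.33, 0.633), "positive")
})

test_that("particle scattering is monotone in size, density and contrast", {
  base <- list(r = 0.2, rho_s = 0.01, n_s = 1.42, n_m = 1.33, lam = 0.633)
  mus_of <- function(r = base$r, rho = base$rho_s, ns = base$n_s) {
    mus_from_particles(particle_spec(r, rho, ns, base$n_m, base$lam))
  }
  for (grid in list(vapply(seq(0.05, 0.5, length.out = 9),
                           function(r) mus_of(r = r), numeric(1)),
                    vapply(seq(0.005, 0.05, length.out = 9),
                           function(rho) mus_of(rho = rho), numeric(1)),
                    vapply(seq(1.34, 1.6, length.out = 9),
                           function(ns) mus_of(ns = ns), numeric(1)))) {
    expect_true(all(diff(grid) > 0))
  }
})

test_that("temperature calibration fits the lipid-phantom line", {
  cal <- fit_mus_calibration(c(22, 32, 37), c(18.4, 16.6, 15.7))
  expect_equal(cal$slope, -0.18, tolerance = 1e-12)
  expect_equal(cal$intercept, 22.36, tolerance = 1e-12)
  expect_equal(cal$valid_range, c(22, 37))
  expect_true(max(abs(cal$residuals)) < 1e-12)  # points are collinear

  # two-point line through the endpoints has the same slope
  cal2 <- fit_mus_calibration(c(22, 37), c(18.4, 15.7))
  expect_equal(cal2$slope, -0.18, tolerance = 1e-12)

  # flat line
  flat <- fit_mus_calibration(c(0, 10), c(1, 1))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 1)

  expect_error(fit_mus_calibration(25, 17), "at least two")
  expect_error(fit_mus_calibration(c(25, 25), c(17, 16)), "conflicting")
})

test_that("calibration predictions reproduce the measured values exactly", {
  cal <- cletus_calibration()
  expect_equal(as.numeric(mus_at_temperature(cal, c(22, 32, 37))),
               c(18.4, 16.6, 15.7), tolerance = 1e-12)

  # heated-tunnel extrapolation to 42 C
  expect_warning(m42 <- mus_at_temperature(cal, 42), "extrapolating")
  expect_equal(as.numeric(m42), 14.8, tolerance = 1e-12)
  expect_true(attr(m42, "extrapolated"))
  expect_false(any(attr(mus_at_temperature(cal, c(25, 30)), "extrapolated")))

  # strictly decreasing for a negative temperature coefficient
  grid <- as.numeric(mus_at_temperature(cal, seq(10, 60, by = 2.5),
                                        quiet = TRUE))
  expect_true(all(diff(grid) < 0))

  # unphysical prediction is refused
  expect_error(mus_at_temperature(cal, 200, quiet = TRUE), "mu_s <= 0")
})

test_that("calibrations round-trip through JSON", {
  cal <- cletus_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$slope, cal$slope, tolerance = 1e-12)
  expect_equal(back$intercept, cal$intercept, tolerance = 1e-12)
  expect_equal(back$points, cal$points)
})
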