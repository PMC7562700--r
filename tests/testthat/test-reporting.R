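test_that("run_experiment writes results, summary and a complete manifest", {
  out <- withr::local_tempdir()
  imp <- run_experiment("model1", fast_cfg(2000, seed = 3), out,
                        diameter = 4, delta_T = 10, voxel_size = 0.4)
  expect_s3_class(imp, "improvement_result")
  for (f in c("results.csv", "summary.json", "manifest.json",
              "scenario.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 3L)
  expect_true(all(c("results.csv", "summary.json") %in%
                    unlist(man$outputs)))
  expect_match(man$config_md5, "^[0-9a-f]{32}$")

  # reruns with the same config are byte-identical
  out2 <- withr::local_tempdir()
  run_experiment("model1", fast_cfg(2000, seed = 3), out2,
                 diameter = 4, delta_T = 10, voxel_size = 0.4)
  expect_identical(readLines(file.path(out, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
})

test_that("sweep reporting identifies the best diameter per temperature", {
  out <- withr::local_tempdir()
  df <- sweep_model1(c(2, 4), 10, fast_cfg(2000, seed = 4), out,
                     voxel_size = 0.4)
  expect_equal(nrow(df), 2L)
  smry <- jsonlite::read_json(file.path(out, "sweep_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(nrow(smry), 1L)
  expect_true(smry$best_diameter_mm %in% c(2, 4))
  expect_true(file.exists(file.path(out, "sweep_results.csv")))
})

test_that("the layered model reports zero improvement for zero heating", {
  out <- withr::local_tempdir()
  imp <- run_model2(fast_cfg(1500, seed = 5), out,
                    layers = list(diameter = c(1, 2, 3, 4),
                                  delta_T = c(0, 0, 0, 0)),
                    voxel_size = 0.4)
  expect_identical(imp$percent, 0)
})

test_that("fluence maps export as text with a faithful sidecar", {
  sc <- make_scenario(tiny_phantom())
  fm <- run_scenario(sc, fast_cfg(1000))
  out <- withr::local_tempdir()
  paths <- export_fluence(fm, out)
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(meta$dims, fm$dims)
  expect_equal(meta$seed, fm$seed)
  vals <- utils::read.csv(gzfile(paths[1]))$fluence
  expect_equal(vals, as.vector(fm$fluence), tolerance = 1e-12)
})

test_that("the command-line wrapper runs a validation preset end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "phototunnel.R", package = "phototunnel")
  expect_true(nzchar(cli))
  out <- file.path(withr::local_tempdir(), "cli-out")
  status <- system2("Rscript",
                    c(cli, "run", "--preset", "validation-beer-lambert",
                      "--photons", "1000", "--seed", "2",
                      "--out-dir", out),
                    stdout = TRUE, stderr = TRUE,
                    env = paste0("R_LIBS=",
                                 paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(file.path(out, "oracle_report.json")))
  rep <- jsonlite::read_json(file.path(out, "oracle_report.json"))
  expect_true(isTRUE(rep$pass))
})
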