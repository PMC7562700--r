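write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

manifest_for <- function(scenario, config, out_dir, outputs, started) {
  cfg_path <- file.path(out_dir, "scenario.json")
  write_scenario(scenario, cfg_path)
  list(
    scenario = scenario$name,
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("phototunnel")),
    seed = config$seed,
    n_photons = config$n_photons,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(outputs)
  )
}

improvement_row <- function(imp) {
  d <- imp$descriptor
  data.frame(
    scenario = if (is.null(d$name)) NA_character_ else d$name,
    diameter_mm = paste(d$diameter, collapse = "/"),
    delta_T_C = paste(d$delta_T, collapse = "/"),
    baseline = imp$baseline$value, heated = imp$heated$value,
    percent = imp$percent, se_percent = imp$se_percent,
    seed = d$seed, n_photons = d$n_photons,
    stringsAsFactors = FALSE
  )
}

#' Run one scenario end-to-end and write its results
#'
#' Executes a preset (paired baseline/heated for the tunnel models, oracle
#' comparison for validation presets), writing a results CSV, a JSON
#' summary, optionally the fluence grids, and a manifest that makes the
#' outputs regenerable from config + seed alone.
#'
#' @param name Preset name (see [preset()]).
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param export_maps Also export the fluence grids (large text files).
#' @param ... Passed to [preset()] (`diameter`, `delta_T`, `voxel_size`,
#'   `layers`).
#' @return The `improvement_result` or `oracle_report`, invisibly, with
#'   attribute `out_dir`.
#' @export
run_experiment <- function(name, config = run_config(), out_dir = ".",
                           export_maps = FALSE, ...) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (startsWith(name, "validation-")) {
    rep <- run_validation(sub("^validation-", "", name), config)
    out <- file.path(out_dir, "oracle_report.json")
    write_json_file(rep[c("scenario", "oracle", "engine", "errors",
                          "tolerance", "relative", "pass", "note")], out)
    sc <- preset(name, ...)
    man <- manifest_for(sc, config, out_dir, out, started)
    write_json_file(man, file.path(out_dir, "manifest.json"))
    attr(rep, "out_dir") <- out_dir
    return(invisible(rep))
  }
  sc <- preset(name, ...)
  imp <- run_paired(sc, config, keep_maps = export_maps)
  csv <- file.path(out_dir, "results.csv")
  utils::write.csv(improvement_row(imp), csv, row.names = FALSE)
  smry <- file.path(out_dir, "summary.json")
  write_json_file(list(scenario = sc$name, percent = imp$percent,
                       se_percent = imp$se_percent,
                       baseline = imp$baseline$value,
                       heated = imp$heated$value,
                       descriptor = imp$descriptor), smry)
  outputs <- c(csv, smry)
  if (export_maps) {
    outputs <- c(outputs,
                 export_fluence(imp$maps$baseline, out_dir, "fluence_baseline"),
                 export_fluence(imp$maps$heated, out_dir, "fluence_heated"))
  }
  man <- manifest_for(sc, config, out_dir, outputs, started)
  write_json_file(man, file.path(out_dir, "manifest.json"))
  attr(imp, "out_dir") <- out_dir
  invisible(imp)
}

#' Run the single-layer tunnel sweep and write table, summary and figure
#'
#' Drives [sweep_improvement()] over a diameter x temperature grid, writes
#' the full results CSV, a JSON summary grouped by temperature rise (with
#' the maximizing diameter per group), and -- when ggplot2 is available --
#' a grouped bar chart of percent improvement.
#'
#' @param diameters Tunnel diameters (mm).
#' @param delta_Ts Temperature rises (degrees C).
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param voxel_size Voxel edge (mm).
#' @return The sweep data.frame, invisibly.
#' @export
sweep_model1 <- function(diameters = c(1, 2, 4, 8, 16),
                         delta_Ts = c(5, 10, 20),
                         config = run_config(), out_dir = ".",
                         voxel_size = 0.2) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- sweep_improvement(diameters, delta_Ts, config, voxel_size)
  csv <- file.path(out_dir, "sweep_results.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  groups <- lapply(split(df, df$delta_T_C), function(g) {
    list(delta_T_C = g$delta_T_C[1L],
         diameter_mm = g$diameter_mm,
         percent = g$percent,
         se_percent = g$se_percent,
         best_diameter_mm = g$diameter_mm[which.max(g$percent)])
  })
  smry <- file.path(out_dir, "sweep_summary.json")
  write_json_file(unname(groups), smry)
  outputs <- c(csv, smry)
  fig <- plot_sweep(df, file.path(out_dir, "sweep_improvement.pdf"))
  if (!is.null(fig)) outputs <- c(outputs, fig)
  sc <- preset("model1", diameter = diameters[1L], delta_T = delta_Ts[1L],
               voxel_size = voxel_size)
  man <- manifest_for(sc, config, out_dir, outputs, started)
  write_json_file(man, file.path(out_dir, "manifest.json"))
  invisible(df)
}

#' Bar chart of a sweep results table
#'
#' @param df A [sweep_improvement()] data.frame.
#' @param path Output figure path (`NULL` returns the plot object).
#' @return The written path (or the ggplot object), or `NULL` when ggplot2
#'   is not installed.
#' @export
plot_sweep <- function(df, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(NULL)
  df$delta_T_C <- factor(df$delta_T_C,
                         labels = paste0("+", sort(unique(df$delta_T_C)),
                                         " °C"))
  df$diameter_mm <- factor(df$diameter_mm)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter_mm,
                                        y = .data$percent,
                                        fill = .data$delta_T_C)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$percent - .data$se_percent,
                   ymax = .data$percent + .data$se_percent),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = "tunnel diameter (mm)",
                  y = "fluence improvement (%)",
                  fill = "temperature rise") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 6, height = 4)
  path
}

#' Run the four-layer graded-tunnel model and write its report
#'
#' Paired baseline/heated run of the graded (focused-ultrasound-like)
#' tunnel under a 1 mm FWHM beam.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param layers Optional alternative layer parameterization (list with
#'   `diameter`, `delta_T`).
#' @param voxel_size Voxel edge (mm).
#' @return The `improvement_result`, invisibly.
#' @export
run_model2 <- function(config = run_config(), out_dir = ".",
                       layers = NULL, voxel_size = 0.2) {
  run_experiment("model2", config = config, out_dir = out_dir,
                 layers = layers, voxel_size = voxel_size)
}
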