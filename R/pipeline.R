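#' Default pipeline configuration
#'
#' Returns the full configuration of the end-to-end study protocol: the
#' default scenario grids, the four cannula flows at 100% oxygen, the rig
#' geometry with the per-VT dead-space rule, triplicate replicates with
#' 0.15-pp measurement noise, and the chart axes.
#'
#' @return A named list of class \code{"pipeline_config"}.
#' @export
default_config <- function() {
  structure(list(
    dead_space_ml = 5.2,
    lung_residual_ml = 30,
    n_cells = 50L,
    waveform = "half_sine",
    dt_ms = 1,
    tol_pp = 0.01,
    max_breaths = 500L,
    noise_sd_pp = 0.15,
    seed = 1L,
    replicates = 3L,
    supply_o2_percent = 100,
    vt_values = default_vt_grid(),
    rr_values = default_rr_grid(),
    ti_values = default_ti_grid(),
    ratio_lo = 0.5,
    ratio_hi = 1.5,
    flows = c(0.1, 0.3, 0.5, 1),
    vt_per_kg = c(5, 7.5),
    weight_grid = seq(0.5, 6, by = 0.5),
    chart_rr_grid = seq(30, 80, by = 10),
    bias_thresholds_pp = c(3, 5)
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration file, fills in
#' defaults for absent keys, rejects unknown keys, and validates every value.
#' An empty file yields the full default protocol.
#'
#' @param path configuration file path; \code{NULL} returns the defaults.
#' @return A validated \code{"pipeline_config"} list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_pos <- function(k) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("config: ", k, " must be a single positive number")
  }
  if (!is.numeric(cfg$dead_space_ml) || cfg$dead_space_ml < 0)
    stop("config: dead_space_ml must be non-negative")
  if (!is.numeric(cfg$lung_residual_ml) || cfg$lung_residual_ml < 0)
    stop("config: lung_residual_ml must be non-negative")
  if (!is.numeric(cfg$n_cells) || cfg$n_cells < 10)
    stop("config: n_cells must be at least 10")
  if (!cfg$waveform %in% c("half_sine", "square"))
    stop("config: waveform must be 'half_sine' or 'square'")
  for (k in c("dt_ms", "tol_pp", "ratio_lo", "ratio_hi")) num_pos(k)
  if (cfg$ratio_lo >= cfg$ratio_hi)
    stop("config: ratio_lo must be smaller than ratio_hi")
  if (!is.numeric(cfg$noise_sd_pp) || cfg$noise_sd_pp < 0)
    stop("config: noise_sd_pp must be non-negative")
  if (!is.numeric(cfg$replicates) || cfg$replicates < 1)
    stop("config: replicates must be at least 1")
  if (!is.numeric(cfg$max_breaths) || cfg$max_breaths < 1)
    stop("config: max_breaths must be at least 1")
  if (!is.numeric(cfg$supply_o2_percent) || cfg$supply_o2_percent < 21 ||
      cfg$supply_o2_percent > 100)
    stop("config: supply_o2_percent must be in [21, 100]")
  for (k in c("vt_values", "rr_values", "ti_values", "weight_grid",
              "chart_rr_grid", "vt_per_kg", "bias_thresholds_pp")) {
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0))
      stop("config: ", k, " must be positive numbers")
  }
  if (!is.numeric(cfg$flows) || any(cfg$flows < 0))
    stop("config: flows must be non-negative numbers")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a configuration back to YAML
#' @param cfg a \code{"pipeline_config"}.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full study pipeline
#'
#' Executes, in order: scenario-grid enumeration, dataset simulation,
#' power-law fitting per cannula flow, formula-bias evaluation (differences
#' and MV-threshold summaries for both estimators), and predictive-chart
#' construction per (flow, VT-per-kg) pair. All stage outputs are written as
#' CSV under \code{out_dir} along with a JSON run manifest (configuration
#' echo, seed, package version) sufficient to reproduce every file.
#'
#' @param config a \code{"pipeline_config"} (see [load_config()]).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress stage progress messages.
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of all written files.
#' @export
run_pipeline <- function(config = default_config(), out_dir = ".",
                         quiet = FALSE) {
  config <- validate_config(config)
  if (!length(config$flows))
    stop("pipeline stage 'dataset': no cannula flows configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- character(0)
  geometry <- rig_geometry(config$dead_space_ml, config$lung_residual_ml,
                           config$n_cells)
  waveform <- waveform_spec(config$waveform, config$dt_ms)

  say("stage 1/5: enumerating breathing scenarios")
  grid <- tryCatch(
    enumerate_grid(config$vt_values, config$rr_values, config$ti_values,
                   config$ratio_lo, config$ratio_hi),
    error = function(e) stop("pipeline stage 'scenarios': ",
                             conditionMessage(e)))
  paths["scenarios"] <- file.path(out_dir, "scenarios.csv")
  write_scenarios(grid, paths["scenarios"])

  say("stage 2/5: simulating %d scenarios x %d flows x %d replicates",
      nrow(grid), length(config$flows), config$replicates)
  dataset <- tryCatch(
    generate_dataset(grid, config$flows, geometry, waveform,
                     config$noise_sd_pp, config$replicates, config$seed,
                     config$supply_o2_percent / 100, config$tol_pp,
                     config$max_breaths),
    error = function(e) stop("pipeline stage 'dataset': ",
                             conditionMessage(e)))
  paths["dataset"] <- file.path(out_dir, "dataset.csv")
  write_dataset(dataset, paths["dataset"])

  say("stage 3/5: fitting FiO2(MV) power law per flow")
  fits <- tryCatch(fit_power_law_by_flow(dataset),
                   error = function(e) stop("pipeline stage 'power_fit': ",
                                            conditionMessage(e)))
  paths["power_fits"] <- file.path(out_dir, "power_fits.csv")
  utils::write.csv(fits, paths["power_fits"], row.names = FALSE)

  say("stage 4/5: evaluating formula bias")
  bias <- list()
  for (fm in c("benaron_benitz", "finer")) {
    recs <- tryCatch(
      formula_differences(dataset, fm, config$supply_o2_percent),
      error = function(e) stop("pipeline stage 'bias': ",
                               conditionMessage(e)))
    smry <- bias_threshold_summary(recs, config$bias_thresholds_pp)
    paths[paste0("bias_", fm)] <- file.path(out_dir,
                                            paste0("bias_", fm, ".csv"))
    utils::write.csv(recs, paths[paste0("bias_", fm)], row.names = FALSE)
    paths[paste0("bias_summary_", fm)] <-
      file.path(out_dir, paste0("bias_summary_", fm, ".csv"))
    write_bias_summary(smry, paths[paste0("bias_summary_", fm)])
    bias[[fm]] <- list(records = recs, summary = smry)
  }

  say("stage 5/5: building predictive charts")
  charts <- list()
  for (fl in config$flows) {
    for (vpk in config$vt_per_kg) {
      ch <- tryCatch(
        build_chart(fl, vpk, config$weight_grid, config$chart_rr_grid,
                    geometry, waveform,
                    ti_grid = config$ti_values,
                    ratio_lo = config$ratio_lo, ratio_hi = config$ratio_hi,
                    supply_o2_fraction = config$supply_o2_percent / 100,
                    tol_pp = config$tol_pp, max_breaths = config$max_breaths),
        error = function(e) stop("pipeline stage 'charts': ",
                                 conditionMessage(e)))
      key <- sprintf("chart_flow%s_vt%s", fl, vpk)
      charts[[key]] <- ch
      paths[key] <- file.path(out_dir, paste0(key, ".csv"))
      write_chart(ch, paths[key])
    }
  }

  manifest <- list(
    package = "lfncsim",
    version = as.character(utils::packageVersion("lfncsim")),
    config = unclass(config),
    n_scenarios = nrow(grid),
    n_runs = nrow(dataset),
    files = as.list(paths))
  paths["manifest"] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d runs, %d files", nrow(dataset), length(paths))
  invisible(list(grid = grid, dataset = dataset, fits = fits, bias = bias,
                 charts = charts, paths = paths))
}
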