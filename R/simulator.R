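#' Rig geometry: dead-space reservoir and lung compartment
#'
#' Describes the gas-mixing geometry of the breathing simulator: the
#' upper-airway dead-space reservoir between the nares and the breathing
#' compartment, the residual volume of the compartment at end-expiration, and
#' the number of plug-flow cells used to discretise the dead space.
#'
#' The base dead space of 5.2 mL is adjusted per tidal volume by
#' [effective_dead_space()]: a 1-mL reduction for VT < 10 mL (the rig's
#' dead-space rod) and a proportional extension for VT > 50 mL.
#'
#' @param dead_space_ml base upper-airway dead space (mL).
#' @param lung_residual_ml compartment volume at end-expiration (mL). With no
#'   gas exchange this affects wash-in speed, not the steady state.
#' @param n_cells number of plug-flow cells (>= 10).
#' @return A list of class \code{"rig_geometry"}.
#' @export
rig_geometry <- function(dead_space_ml = 5.2, lung_residual_ml = 30,
                         n_cells = 50) {
  if (!is.numeric(dead_space_ml) || dead_space_ml < 0)
    stop("dead_space_ml must be non-negative")
  if (!is.numeric(lung_residual_ml) || lung_residual_ml < 0)
    stop("lung_residual_ml must be non-negative")
  if (dead_space_ml > 0 && (!is.numeric(n_cells) || n_cells < 10))
    stop("n_cells must be at least 10")
  structure(list(dead_space_ml = dead_space_ml,
                 lung_residual_ml = lung_residual_ml,
                 n_cells = as.integer(n_cells)),
            class = "rig_geometry")
}

#' Cannula flow setting
#'
#' @param flow_l_min cannula flow (L/min), non-negative.
#' @param supply_o2_fraction O2 fraction of the supplied gas, in
#'   \code{[0.21, 1]}; the default 1 is a 100% oxygen supply.
#' @return A list of class \code{"cannula_setting"}.
#' @export
cannula_setting <- function(flow_l_min, supply_o2_fraction = 1) {
  if (!is.numeric(flow_l_min) || flow_l_min < 0)
    stop("flow_l_min must be non-negative")
  if (!is.numeric(supply_o2_fraction) ||
      supply_o2_fraction < 0.21 || supply_o2_fraction > 1)
    stop("supply_o2_fraction must be in [0.21, 1]")
  structure(list(flow_l_min = flow_l_min,
                 supply_o2_fraction = supply_o2_fraction),
            class = "cannula_setting")
}

#' Tidal-volume-dependent effective dead space
#'
#' Reproduces the rig's dead-space adjustments: a pliant rod (volume 1 mL)
#' reduces the reservoir for small tidal volumes (< 10 mL), and an expandable
#' tube extends it for large ones (> 50 mL). The extension follows the
#' anatomical-dead-space proportionality VD = 0.10 x VT, floored at the base
#' volume.
#'
#' @param vt_ml tidal volume (mL), positive.
#' @param geometry a [rig_geometry()].
#' @return Effective dead space (mL).
#' @examples
#' effective_dead_space(5)   # 4.2
#' effective_dead_space(30)  # 5.2
#' effective_dead_space(80)  # 8.0
#' @export
effective_dead_space <- function(vt_ml, geometry = rig_geometry()) {
  stopifnot(inherits(geometry, "rig_geometry"))
  if (!is.numeric(vt_ml) || any(vt_ml <= 0)) stop("vt_ml must be positive")
  base <- geometry$dead_space_ml
  ifelse(vt_ml < 10, base - 1.0,
         ifelse(vt_ml <= 50, base, pmax(base, 0.10 * vt_ml)))
}

#' Simulate wash-in to steady-state effective FiO2
#'
#' Time-steps the plug-flow dead space + well-mixed lung gas-mixing model for
#' one breathing scenario and cannula setting until the end-inspiratory lung
#' O2 fraction stabilises (change below \code{tol_pp} percentage points for
#' three consecutive breaths). The dead space is used exactly as given in
#' \code{geometry}; apply [effective_dead_space()] first when emulating the
#' rig's per-VT dead-space adjustments (as [generate_dataset()] and
#' [build_chart()] do).
#'
#' @param scenario one-row scenario, as from [breathing_scenario()].
#' @param cannula a [cannula_setting()].
#' @param geometry a [rig_geometry()]; \code{dead_space_ml} is taken literally.
#' @param waveform a [waveform_spec()].
#' @param tol_pp convergence tolerance (percentage points).
#' @param max_breaths maximum number of simulated breaths.
#' @param start_fio2 initial O2 concentration (%) of all compartments; 21 is
#'   room air, 100 reproduces the wash-out protocol between bench runs.
#' @return A list of class \code{"sim_result"}: \code{fio2_percent},
#'   \code{n_breaths}, \code{converged}, \code{per_breath_fio2} and
#'   \code{mass_rel_error} (largest relative O2 bookkeeping error seen at any
#'   time step).
#' @examples
#' s <- breathing_scenario(5, 30, 900)
#' simulate_steady_state(s, cannula_setting(0.1))
#' @export
simulate_steady_state <- function(scenario,
                                  cannula,
                                  geometry = rig_geometry(),
                                  waveform = waveform_spec(),
                                  tol_pp = 0.01,
                                  max_breaths = 500,
                                  start_fio2 = 21) {
  scenario <- as.data.frame(scenario)
  stopifnot(nrow(scenario) == 1, inherits(cannula, "cannula_setting"),
            inherits(geometry, "rig_geometry"),
            inherits(waveform, "waveform_spec"))
  if (tol_pp <= 0) stop("tol_pp must be positive")
  if (waveform$dt_ms > scenario$ti_ms / 10)
    stop("dt_ms must be at most Ti/10 for this scenario")
  shape_code <- if (waveform$shape == "square") 0L else 1L
  res <- .sim_steady_state_cpp(
    vt_ml = scenario$vt_ml, ti_ms = scenario$ti_ms, te_ms = scenario$te_ms,
    flow_l_min = cannula$flow_l_min, supply_frac = cannula$supply_o2_fraction,
    dead_space_ml = geometry$dead_space_ml,
    lung_residual_ml = geometry$lung_residual_ml,
    n_cells = geometry$n_cells, shape = shape_code, dt_ms = waveform$dt_ms,
    tol_pp = tol_pp, max_breaths = as.integer(max_breaths),
    start_frac = start_fio2 / 100, track_mass = TRUE)
  res$scenario <- scenario
  res$flow_l_min <- cannula$flow_l_min
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Steady-state effective FiO2: %.2f%% (flow %.1f L/min, VT %.0f mL, Ti %.0f ms, RR %.0f)\n",
    x$fio2_percent, x$flow_l_min, x$scenario$vt_ml, x$scenario$ti_ms,
    x$scenario$rr_bpm))
  cat(sprintf("  %d breaths to convergence (%s)\n", x$n_breaths,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Generate the synthetic bench dataset
#'
#' Runs the gas-mixing simulator for every scenario x cannula-flow cell,
#' applies the rig's per-VT dead-space rule, and replicates each cell with
#' small Gaussian measurement noise (clipped to \code{[21, 100]}). With the
#' default grids, four flows and triplicates this emulates the full
#' 1200-experiment bench protocol.
#'
#' @param scenarios scenario grid from [enumerate_grid()].
#' @param flows cannula flows (L/min).
#' @param geometry base [rig_geometry()].
#' @param waveform a [waveform_spec()].
#' @param noise_sd_pp replicate noise SD (percentage points); the default
#'   0.15 matches bench replicate SDs of 0.1--0.2 pp.
#' @param replicates replicates per cell.
#' @param seed integer RNG seed; a fixed seed reproduces the dataset exactly.
#' @param supply_o2_fraction O2 fraction of the supply gas.
#' @param tol_pp,max_breaths convergence controls, as in
#'   [simulate_steady_state()].
#' @param vt_rule apply [effective_dead_space()] per tidal volume (default);
#'   set \code{FALSE} to use \code{geometry$dead_space_ml} unmodified.
#' @return Data frame with columns \code{vt_ml}, \code{rr_bpm}, \code{ti_ms},
#'   \code{te_ms}, \code{mv_ml_min}, \code{flow_l_min}, \code{replicate},
#'   \code{fio2_percent}.
#' @export
generate_dataset <- function(scenarios,
                             flows = c(0.1, 0.3, 0.5, 1),
                             geometry = rig_geometry(),
                             waveform = waveform_spec(),
                             noise_sd_pp = 0.15,
                             replicates = 3,
                             seed = 1L,
                             supply_o2_fraction = 1,
                             tol_pp = 0.01,
                             max_breaths = 500,
                             vt_rule = TRUE) {
  scenarios <- as.data.frame(scenarios)
  if (noise_sd_pp < 0) stop("noise_sd_pp must be non-negative")
  if (replicates < 1) stop("replicates must be at least 1")
  if (!length(flows)) stop("at least one cannula flow is required")
  empty <- data.frame(vt_ml = numeric(0), rr_bpm = numeric(0),
                      ti_ms = numeric(0), te_ms = numeric(0),
                      mv_ml_min = numeric(0), flow_l_min = numeric(0),
                      replicate = integer(0), fio2_percent = numeric(0))
  if (!nrow(scenarios)) return(empty)

  cells <- do.call(rbind, lapply(sort(flows), function(fl) {
    s <- scenarios
    s$flow_l_min <- fl
    s
  }))
  fio2 <- vapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    geo <- geometry
    if (vt_rule)
      geo$dead_space_ml <- effective_dead_space(row$vt_ml, geometry)
    simulate_steady_state(row, cannula_setting(row$flow_l_min,
                                               supply_o2_fraction),
                          geo, waveform, tol_pp, max_breaths)$fio2_percent
  }, numeric(1))

  out <- cells[rep(seq_len(nrow(cells)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), nrow(cells))
  base_fio2 <- rep(fio2, each = replicates)
  if (noise_sd_pp > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    noise <- stats::rnorm(length(base_fio2), 0, noise_sd_pp)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    base_fio2 <- pmin(100, pmax(21, base_fio2 + noise))
  }
  out$fio2_percent <- base_fio2
  out <- out[, c("vt_ml", "rr_bpm", "ti_ms", "te_ms", "mv_ml_min",
                 "flow_l_min", "replicate", "fio2_percent")]
  rownames(out) <- NULL
  out
}

#' Write / read a simulated dataset as CSV
#' @param dataset data frame from [generate_dataset()].
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path)
  need <- c("vt_ml", "rr_bpm", "ti_ms", "flow_l_min", "fio2_percent")
  if (!all(need %in% names(d))) stop("not a simulated-dataset CSV")
  d
}
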