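#' Enumerate the breathing-scenario grid
#'
#' Builds every combination of tidal volume, respiratory rate and inspiratory
#' time, derives expiratory time (Te), the Ti/Te ratio and minute ventilation
#' (MV), and keeps only physiologically feasible combinations: Te must be
#' positive and the Ti/Te ratio must fall in the half-open window
#' \code{[ratio_lo, ratio_hi)}.
#'
#' With the default grids (VT 5--80 mL, RR 30--80 breaths/min, Ti 300--900 ms,
#' ratio window \[0.5, 1.5)) the enumeration retains 100 scenarios spanning
#' minute ventilations of 150--6400 mL/min; crossed with four cannula flows and
#' triplicate runs this is the 1200-experiment protocol the simulator emulates.
#'
#' @param vt_values tidal volumes (mL).
#' @param rr_values respiratory rates (breaths/min).
#' @param ti_values inspiratory times (ms).
#' @param ratio_lo,ratio_hi Ti/Te feasibility window; the lower bound is
#'   inclusive, the upper bound exclusive.
#' @return A data frame of class \code{"breathing_grid"} with columns
#'   \code{vt_ml}, \code{rr_bpm}, \code{ti_ms}, \code{te_ms},
#'   \code{ti_te_ratio}, \code{mv_ml_min}, ordered VT-major, then RR, then Ti.
#' @seealso [scenario_from_weight()], [make_waveform()]
#' @examples
#' g <- enumerate_grid()
#' nrow(g)          # 100
#' range(g$mv_ml_min)
#' @export
enumerate_grid <- function(vt_values = default_vt_grid(),
                           rr_values = default_rr_grid(),
                           ti_values = default_ti_grid(),
                           ratio_lo = 0.5, ratio_hi = 1.5) {
  stopifnot(is.numeric(vt_values), is.numeric(rr_values), is.numeric(ti_values))
  if (any(vt_values <= 0) || any(rr_values <= 0) || any(ti_values <= 0))
    stop("all grid values must be positive")
  if (!is.finite(ratio_lo) || !is.finite(ratio_hi) || ratio_lo <= 0 || ratio_hi <= 0)
    stop("ratio bounds must be positive")
  if (ratio_lo >= ratio_hi) stop("ratio_lo must be smaller than ratio_hi")

  if (!length(vt_values) || !length(rr_values) || !length(ti_values))
    return(empty_grid())

  # VT-major ordering, then RR, then Ti: expand.grid varies its first factor
  # fastest, so list axes in reverse.
  g <- expand.grid(ti_ms = sort(ti_values), rr_bpm = sort(rr_values),
                   vt_ml = sort(vt_values), KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("vt_ml", "rr_bpm", "ti_ms")]
  g$te_ms <- 60000 / g$rr_bpm - g$ti_ms
  g$ti_te_ratio <- g$ti_ms / g$te_ms
  g$mv_ml_min <- g$vt_ml * g$rr_bpm
  keep <- g$te_ms > 0 & g$ti_te_ratio >= ratio_lo & g$ti_te_ratio < ratio_hi
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("breathing_grid", "data.frame")
  g
}

empty_grid <- function() {
  g <- data.frame(vt_ml = numeric(0), rr_bpm = numeric(0), ti_ms = numeric(0),
                  te_ms = numeric(0), ti_te_ratio = numeric(0),
                  mv_ml_min = numeric(0))
  class(g) <- c("breathing_grid", "data.frame")
  g
}

#' @rdname enumerate_grid
#' @export
default_vt_grid <- function() c(5, 10, 15, 20, 30, 40, 50, 60, 70, 80)

#' @rdname enumerate_grid
#' @export
default_rr_grid <- function() seq(30, 80, by = 10)

#' @rdname enumerate_grid
#' @export
default_ti_grid <- function() c(300, 500, 700, 900)

#' Build a single breathing scenario
#'
#' @param vt_ml tidal volume (mL).
#' @param rr_bpm respiratory rate (breaths/min).
#' @param ti_ms inspiratory time (ms).
#' @return One-row data frame with the same columns as [enumerate_grid()].
#' @export
breathing_scenario <- function(vt_ml, rr_bpm, ti_ms) {
  stopifnot(length(vt_ml) == 1, length(rr_bpm) == 1, length(ti_ms) == 1)
  if (vt_ml <= 0 || rr_bpm <= 0 || ti_ms <= 0)
    stop("vt_ml, rr_bpm and ti_ms must all be positive")
  te_ms <- 60000 / rr_bpm - ti_ms
  if (te_ms <= 0)
    stop(sprintf(
      "infeasible scenario: Te = %.1f ms (Ti %.0f ms exceeds the %.1f ms cycle at RR %.0f)",
      te_ms, ti_ms, 60000 / rr_bpm, rr_bpm))
  s <- data.frame(vt_ml = vt_ml, rr_bpm = rr_bpm, ti_ms = ti_ms, te_ms = te_ms,
                  ti_te_ratio = ti_ms / te_ms, mv_ml_min = vt_ml * rr_bpm)
  class(s) <- c("breathing_grid", "data.frame")
  s
}

#' Derive a breathing scenario from infant weight
#'
#' Converts a body weight and a weight-normalised tidal volume (typically 5 or
#' 7.5 mL/kg) into an absolute-volume breathing scenario.
#'
#' @param weight_kg infant body weight (kg).
#' @param vt_per_kg tidal volume per kilogram (mL/kg).
#' @param rr_bpm respiratory rate (breaths/min).
#' @param ti_ms inspiratory time (ms).
#' @return One-row scenario data frame; errors if the implied expiratory time
#'   is not positive.
#' @examples
#' scenario_from_weight(2, 5, 30, 900)  # VT 10 mL, MV 300 mL/min
#' @export
scenario_from_weight <- function(weight_kg, vt_per_kg, rr_bpm, ti_ms) {
  if (!is.numeric(weight_kg) || weight_kg <= 0) stop("weight_kg must be positive")
  if (!is.numeric(vt_per_kg) || vt_per_kg <= 0) stop("vt_per_kg must be positive")
  breathing_scenario(weight_kg * vt_per_kg, rr_bpm, ti_ms)
}

#' Waveform specification for the piston drive
#'
#' Describes the instantaneous flow profile used to move each tidal volume.
#' \code{"half_sine"} (the default) ramps flow smoothly from zero to a peak
#' and back, giving near-zero flow at the phase boundaries as a velocity-ramped
#' piston would; \code{"square"} is constant flow, the degenerate profile under
#' which the simulator reduces to the classical closed-form estimator.
#'
#' @param shape \code{"half_sine"} or \code{"square"}.
#' @param dt_ms integration time step (ms); must not exceed Ti/10 for any
#'   scenario the spec is applied to.
#' @return A list of class \code{"waveform_spec"}.
#' @export
waveform_spec <- function(shape = c("half_sine", "square"), dt_ms = 1) {
  shape <- match.arg(shape)
  if (!is.numeric(dt_ms) || length(dt_ms) != 1 || dt_ms <= 0)
    stop("dt_ms must be a single positive number")
  structure(list(shape = shape, dt_ms = dt_ms), class = "waveform_spec")
}

#' Instantaneous-flow function for one scenario
#'
#' Returns the piecewise flow profile (mL/s) over one respiratory cycle:
#' positive during inspiration (\code{[0, Ti)}) and positive in magnitude
#' during expiration (\code{[Ti, Ti + Te)}). By construction the inspired and
#' expired volumes both integrate to the scenario's tidal volume.
#'
#' @param scenario one-row scenario as from [breathing_scenario()].
#' @param spec a [waveform_spec()].
#' @return A function \code{f(t_ms)} giving flow magnitude in mL/s, with
#'   attribute \code{"phase"}: a function returning \code{"insp"} or
#'   \code{"exp"} for a time in the cycle.
#' @export
make_waveform <- function(scenario, spec = waveform_spec()) {
  stopifnot(inherits(spec, "waveform_spec"))
  scenario <- as.data.frame(scenario)
  vt <- scenario$vt_ml[1]; ti <- scenario$ti_ms[1]; te <- scenario$te_ms[1]
  if (spec$dt_ms > ti / 10)
    stop("dt_ms must be at most Ti/10 for this scenario")
  shape <- spec$shape
  f <- function(t_ms) {
    t_ms <- t_ms %% (ti + te)
    insp <- t_ms < ti
    dur <- ifelse(insp, ti, te)           # phase duration, ms
    tau <- ifelse(insp, t_ms, t_ms - ti)  # time within phase, ms
    if (shape == "square") {
      vt / (dur / 1000)
    } else {
      (pi / 2) * (vt / (dur / 1000)) * sin(pi * tau / dur)
    }
  }
  attr(f, "phase") <- function(t_ms) {
    ifelse((t_ms %% (ti + te)) < ti, "insp", "exp")
  }
  f
}

#' Write / read a scenario grid as CSV
#'
#' @param grid a \code{breathing_grid} data frame.
#' @param path file path.
#' @return \code{write_scenarios} returns \code{path} invisibly;
#'   \code{read_scenarios} returns the grid.
#' @export
write_scenarios <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  g <- utils::read.csv(path)
  need <- c("vt_ml", "rr_bpm", "ti_ms", "te_ms", "ti_te_ratio", "mv_ml_min")
  if (!all(need %in% names(g))) stop("not a scenario grid CSV")
  class(g) <- c("breathing_grid", "data.frame")
  g
}
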