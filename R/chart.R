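#' Feasible inspiratory times for a respiratory rate
#'
#' Ti values from the grid that leave a positive expiratory time and a Ti/Te
#' ratio inside the feasibility window at the given respiratory rate — the
#' same rule [enumerate_grid()] applies.
#'
#' @param rr_bpm respiratory rate (breaths/min).
#' @param ti_grid candidate inspiratory times (ms).
#' @param ratio_lo,ratio_hi Ti/Te window (half-open upper bound).
#' @return Feasible Ti values (ms); may be empty.
#' @examples
#' feasible_ti(30)  # 700, 900
#' feasible_ti(60)  # 500
#' feasible_ti(80)  # 300
#' @export
feasible_ti <- function(rr_bpm, ti_grid = default_ti_grid(),
                        ratio_lo = 0.5, ratio_hi = 1.5) {
  if (rr_bpm <= 0) stop("rr_bpm must be positive")
  te <- 60000 / rr_bpm - ti_grid
  ratio <- ti_grid / te
  sort(ti_grid[te > 0 & ratio >= ratio_lo & ratio < ratio_hi])
}

#' Build a predictive FiO2 chart
#'
#' Produces the weight x respiratory-rate lookup table of steady-state
#' effective FiO2 for one cannula flow and one weight-normalised tidal volume
#' (5 or 7.5 mL/kg), under a 100% oxygen supply. Each cell is the mean of the
#' gas-mixing simulation over the feasible inspiratory times for that RR;
#' cells whose tidal volume would exceed \code{vt_cap_ml} (30 mL — the
#' validity limit of the underlying protocol) are left absent (\code{NA})
#' rather than extrapolated.
#'
#' @param flow_l_min cannula flow (L/min).
#' @param vt_per_kg tidal volume per kilogram (mL/kg), typically 5 or 7.5.
#' @param weight_grid infant weights (kg).
#' @param rr_grid respiratory rates (breaths/min).
#' @param geometry base [rig_geometry()]; the per-VT dead-space rule is
#'   applied to every cell.
#' @param waveform a [waveform_spec()].
#' @param vt_cap_ml largest tidal volume charted (mL).
#' @param ti_grid,ratio_lo,ratio_hi feasibility rule for [feasible_ti()].
#' @param supply_o2_fraction supply O2 fraction.
#' @param tol_pp,max_breaths convergence controls.
#' @return An object of class \code{"fio2_chart"}: a list with \code{cells}
#'   (weight x RR matrix of FiO2 %), \code{long} (long-format data frame with
#'   an \code{in_band} flag for 30--60 breaths/min) and the chart metadata.
#' @export
build_chart <- function(flow_l_min, vt_per_kg,
                        weight_grid = seq(0.5, 6, by = 0.5),
                        rr_grid = seq(30, 80, by = 10),
                        geometry = rig_geometry(),
                        waveform = waveform_spec(),
                        vt_cap_ml = 30,
                        ti_grid = default_ti_grid(),
                        ratio_lo = 0.5, ratio_hi = 1.5,
                        supply_o2_fraction = 1,
                        tol_pp = 0.01, max_breaths = 500,
                        band = c(30, 60)) {
  stopifnot(flow_l_min >= 0, vt_per_kg > 0, length(weight_grid) >= 1,
            length(rr_grid) >= 1)
  weight_grid <- sort(weight_grid); rr_grid <- sort(rr_grid)
  cells <- matrix(NA_real_, nrow = length(weight_grid),
                  ncol = length(rr_grid),
                  dimnames = list(weight_kg = weight_grid, rr_bpm = rr_grid))
  cannula <- cannula_setting(flow_l_min, supply_o2_fraction)
  for (j in seq_along(rr_grid)) {
    tis <- feasible_ti(rr_grid[j], ti_grid, ratio_lo, ratio_hi)
    if (!length(tis)) {
      warning(sprintf("no feasible Ti for RR %.0f; column left absent",
                      rr_grid[j]))
      next
    }
    for (i in seq_along(weight_grid)) {
      vt <- vt_per_kg * weight_grid[i]
      if (vt > vt_cap_ml) next  # beyond the charted VT range
      geo <- geometry
      geo$dead_space_ml <- effective_dead_space(vt, geometry)
      vals <- vapply(tis, function(ti) {
        s <- breathing_scenario(vt, rr_grid[j], ti)
        simulate_steady_state(s, cannula, geo, waveform, tol_pp,
                              max_breaths)$fio2_percent
      }, numeric(1))
      cells[i, j] <- mean(vals)
    }
  }
  long <- data.frame(
    weight_kg = rep(weight_grid, times = length(rr_grid)),
    rr_bpm = rep(rr_grid, each = length(weight_grid)),
    fio2_percent = as.vector(cells))
  long$in_band <- long$rr_bpm >= band[1] & long$rr_bpm <= band[2]
  structure(list(cells = cells, long = long, flow_l_min = flow_l_min,
                 vt_per_kg = vt_per_kg, weight_grid = weight_grid,
                 rr_grid = rr_grid, band = band, vt_cap_ml = vt_cap_ml,
                 geometry = geometry, waveform = waveform),
            class = "fio2_chart")
}

#' @export
print.fio2_chart <- function(x, ...) {
  cat(sprintf(
    "Predictive FiO2 chart: flow %.1f L/min, VT %.1f mL/kg (100%% O2 supply)\n",
    x$flow_l_min, x$vt_per_kg))
  print(round(x$cells, 1))
  cat(sprintf("rows: weight (kg); columns: RR (breaths/min); VT capped at %.0f mL\n",
              x$vt_cap_ml))
  invisible(x)
}

#' Plot a predictive FiO2 chart
#'
#' Draws the chart as FiO2 against weight, one line per respiratory rate,
#' with the 30--60 breaths/min band shaded grey.
#'
#' @param x an \code{fio2_chart}.
#' @param ... passed to \code{matplot}.
#' @export
plot.fio2_chart <- function(x, ...) {
  in_band <- x$rr_grid >= x$band[1] & x$rr_grid <= x$band[2]
  graphics::matplot(x$weight_grid, x$cells, type = "n",
                    xlab = "Infant weight (kg)", ylab = "Effective FiO2 (%)",
                    main = sprintf("Flow %.1f L/min, VT %.1f mL/kg",
                                   x$flow_l_min, x$vt_per_kg), ...)
  if (any(in_band)) {
    band_vals <- x$cells[, in_band, drop = FALSE]
    lo <- apply(band_vals, 1, function(v) suppressWarnings(min(v, na.rm = TRUE)))
    hi <- apply(band_vals, 1, function(v) suppressWarnings(max(v, na.rm = TRUE)))
    keep <- is.finite(lo) & is.finite(hi)
    if (any(keep))
      graphics::polygon(c(x$weight_grid[keep], rev(x$weight_grid[keep])),
                        c(lo[keep], rev(hi[keep])),
                        col = "grey85", border = NA)
  }
  graphics::matlines(x$weight_grid, x$cells, type = "b", pch = 16, lty = 1)
  graphics::legend("topright", legend = paste(x$rr_grid, "bpm"),
                   col = seq_along(x$rr_grid), pch = 16, lty = 1, cex = 0.8)
  invisible(x)
}

#' Write / read a predictive chart as long-format CSV
#'
#' Columns \code{weight_kg}, \code{rr_bpm}, \code{fio2_percent},
#' \code{in_band}; absent cells are written as empty fields, not zeros.
#'
#' @param chart an \code{fio2_chart} (or its \code{long} data frame).
#' @param path file path.
#' @export
write_chart <- function(chart, path) {
  long <- if (inherits(chart, "fio2_chart")) chart$long else chart
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_chart
#' @export
read_chart <- function(path) {
  d <- utils::read.csv(path)
  need <- c("weight_kg", "rr_bpm", "fio2_percent", "in_band")
  if (!all(need %in% names(d))) stop("not a chart CSV")
  d
}
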