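#' Closed-form effective-FiO2 estimators
#'
#' The two classical nasal-cannula estimators, written for an arbitrary supply
#' oxygen concentration (100% by default).
#'
#' \code{benaron_benitz_fio2()} assumes the upper airway stores no oxygen: the
#' cannula contributes the volume it delivers during inspiration,
#' \eqn{v = F_c \times T_i}, capped at the tidal volume, so
#' \deqn{FiO_2 = 21 + (supply - 21) \, v / V_T.}
#'
#' \code{finer_fio2()} is a flow-weighted mixture over minute ventilation,
#' \deqn{FiO_2 = 100 (f \cdot s + (MV - f) \times 0.21) / MV}
#' with \eqn{f} the cannula flow in mL/min and \eqn{s} the supply fraction.
#' It is deliberately \emph{not} capped: for low MV and high flow it returns
#' values above 100%, a known flaw that the bias analysis must be able to
#' observe.
#'
#' \code{stoprop_fio2()} is the STOP-ROP convention: Benaron-Benitz with a
#' fixed Ti of 300 ms and a fixed VT of 5 mL/kg body weight.
#'
#' @param flow_l_min cannula flow (L/min).
#' @param ti_ms inspiratory time (ms).
#' @param vt_ml tidal volume (mL).
#' @param mv_ml_min minute ventilation (mL/min).
#' @param weight_kg infant body weight (kg).
#' @param supply_o2_percent supply oxygen concentration (%), default 100.
#' @return A list of class \code{"formula_estimate"} with \code{fio2_percent},
#'   \code{formula_name} and \code{capped} (whether the cannula volume was
#'   capped at VT; always \code{FALSE} for Finer).
#' @examples
#' benaron_benitz_fio2(0.1, 900, 5)   # 44.7%
#' finer_fio2(1, 400)                 # 218.5%, above 100 by design
#' stoprop_fio2(0.1, 2)               # 24.95%
#' @export
benaron_benitz_fio2 <- function(flow_l_min, ti_ms, vt_ml,
                                supply_o2_percent = 100) {
  if (any(vt_ml <= 0)) stop("vt_ml must be positive")
  if (any(ti_ms <= 0)) stop("ti_ms must be positive")
  if (any(flow_l_min < 0)) stop("flow_l_min must be non-negative")
  v <- (flow_l_min * 1000 / 60) * (ti_ms / 1000)  # cannula mL per inspiration
  capped <- v >= vt_ml - 1e-9  # the cap engages at (and numerically around) v = VT
  v <- pmin(v, vt_ml)
  estimate(21 + (supply_o2_percent - 21) * v / vt_ml, "benaron_benitz", capped)
}

#' @rdname benaron_benitz_fio2
#' @export
finer_fio2 <- function(flow_l_min, mv_ml_min, supply_o2_percent = 100) {
  if (any(mv_ml_min <= 0)) stop("mv_ml_min must be positive")
  if (any(flow_l_min < 0)) stop("flow_l_min must be non-negative")
  f <- flow_l_min * 1000  # mL/min
  s <- supply_o2_percent / 100
  fio2 <- 100 * (f * s + (mv_ml_min - f) * 0.21) / mv_ml_min
  estimate(fio2, "finer", rep(FALSE, length(fio2)))
}

#' @rdname benaron_benitz_fio2
#' @export
stoprop_fio2 <- function(flow_l_min, weight_kg, supply_o2_percent = 100) {
  if (any(weight_kg <= 0)) stop("weight_kg must be positive")
  est <- benaron_benitz_fio2(flow_l_min, ti_ms = 300, vt_ml = 5 * weight_kg,
                             supply_o2_percent = supply_o2_percent)
  est$formula_name <- "stoprop"
  est
}

estimate <- function(fio2, name, capped) {
  structure(list(fio2_percent = fio2, formula_name = name, capped = capped),
            class = "formula_estimate")
}

#' @export
print.formula_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: %s%%%s\n", x$formula_name,
              paste(formatC(x$fio2_percent, digits = 4, format = "fg"),
                    collapse = ", "),
              if (any(x$capped)) " (capped)" else ""))
  invisible(x)
}

#' Blender correction for sub-100% supply
#'
#' Rescales a 100%-supply chart FiO2 to the effective FiO2 under an oxygen
#' blender set below 100%:
#' \deqn{FiO_2 = 21 + (FiO_2^{chart} - 21) \times FiO_2^{blender} / 100.}
#' The correction is linear in the blender setting, fixes the room-air point
#' 21, and is the identity at a blender setting of 100%.
#'
#' @param chart_fio2_percent effective FiO2 from a 100%-supply chart (%),
#'   at least 21.
#' @param blender_fio2_percent blender setting (%), in \code{[21, 100]}.
#' @return Corrected effective FiO2 (%).
#' @examples
#' blender_corrected_fio2(30, 50)  # 25.5
#' @export
blender_corrected_fio2 <- function(chart_fio2_percent, blender_fio2_percent) {
  if (any(chart_fio2_percent < 21))
    stop("chart_fio2_percent must be at least 21")
  if (any(blender_fio2_percent < 21 | blender_fio2_percent > 100))
    stop("blender_fio2_percent must be in [21, 100]")
  21 + (chart_fio2_percent - 21) * blender_fio2_percent / 100
}
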