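#' Fit the power-law model of FiO2 against minute ventilation
#'
#' Fits \deqn{FiO_2(MV) = 21 + k \cdot MV^{-a}} by least squares in the
#' original (untransformed) residual space. Starting values come from an
#' ordinary linear regression of \eqn{\log(FiO_2 - 21)} on \eqn{\log MV};
#' points within 0.05 percentage points of the 21% room-air floor are excluded
#' from that initialisation (their logs are unstable) but retained in the
#' nonlinear objective. Parameters are bounded: \eqn{k \in (0, 10^7]},
#' \eqn{a \in (0, 5]}.
#'
#' @param mv_values minute ventilations (mL/min).
#' @param fio2_values effective FiO2 values (%), same length.
#' @param flow_l_min optional cannula flow the data belong to (metadata only).
#' @return An object of class \code{"power_fit"} with components \code{k},
#'   \code{a}, \code{r2}, \code{n_points}, \code{flow_l_min}, \code{fitted},
#'   \code{residuals} and \code{data}; supports \code{print()},
#'   \code{summary()}, \code{coef()}, \code{predict()} and \code{plot()}.
#' @examples
#' mv <- seq(150, 6400, length.out = 50)
#' fio2 <- 21 + 1000 * mv^-0.8
#' fit <- fit_power_law(mv, fio2)
#' coef(fit)
#' @export
fit_power_law <- function(mv_values, fio2_values, flow_l_min = NA_real_) {
  mv <- as.numeric(mv_values); fio2 <- as.numeric(fio2_values)
  if (length(mv) != length(fio2)) stop("mv and fio2 must have equal length")
  ok <- is.finite(mv) & is.finite(fio2)
  mv <- mv[ok]; fio2 <- fio2[ok]
  if (any(mv <= 0)) stop("mv values must be positive")
  above <- fio2 > 21 + 0.05  # off the room-air floor
  if (length(mv) < 3 || sum(above) < 3)
    stop("degenerate fit: fewer than 3 points above the 21% floor")

  init <- stats::lm(log(fio2[above] - 21) ~ log(mv[above]))
  k0 <- min(1e7, max(1e-6, exp(stats::coef(init)[[1]])))
  a0 <- min(5, max(1e-6, -stats::coef(init)[[2]]))

  df <- data.frame(mv = mv, fio2 = fio2)
  fit <- minpack.lm::nlsLM(
    fio2 ~ 21 + k * mv^(-a), data = df,
    start = list(k = k0, a = a0),
    lower = c(k = 1e-12, a = 1e-12), upper = c(k = 1e7, a = 5),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 500))
  k <- stats::coef(fit)[["k"]]; a <- stats::coef(fit)[["a"]]
  pred <- 21 + k * mv^(-a)
  r2 <- r_squared(fio2, pred)
  structure(list(k = k, a = a, r2 = r2, n_points = length(mv),
                 flow_l_min = flow_l_min, fitted = pred,
                 residuals = fio2 - pred, data = df),
            class = "power_fit")
}

#' Coefficient of determination on the original scale
#'
#' \eqn{R^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \bar{obs})^2}.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return R-squared (can be negative for fits worse than the mean).
#' @examples
#' r_squared(c(22, 24, 26), c(22, 25, 26))  # 0.875
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("lengths differ")
  if (length(observed) < 2) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' @export
coef.power_fit <- function(object, ...) c(k = object$k, a = object$a)

#' @export
print.power_fit <- function(x, ...) {
  cat("Power-law fit: FiO2(MV) = 21 + k * MV^-a\n")
  if (is.finite(x$flow_l_min))
    cat(sprintf("  cannula flow: %.1f L/min\n", x$flow_l_min))
  cat(sprintf("  k = %.4g, a = %.4g, R^2 = %.3f  (n = %d)\n",
              x$k, x$a, x$r2, x$n_points))
  invisible(x)
}

#' @export
summary.power_fit <- function(object, ...) {
  cat("Power-law model of effective FiO2 vs minute ventilation\n\n")
  print(object)
  cat(sprintf("  residuals (pp): min %.3f, median %.3f, max %.3f\n",
              min(object$residuals), stats::median(object$residuals),
              max(object$residuals)))
  invisible(object)
}

#' @export
predict.power_fit <- function(object, newdata = NULL, ...) {
  mv <- if (is.null(newdata)) object$data$mv
        else if (is.data.frame(newdata)) newdata$mv
        else as.numeric(newdata)
  if (any(mv <= 0)) stop("mv values must be positive")
  21 + object$k * mv^(-object$a)
}

#' @export
residuals.power_fit <- function(object, ...) object$residuals

#' @export
plot.power_fit <- function(x, ...) {
  ord <- order(x$data$mv)
  graphics::plot(x$data$mv, x$data$fio2, xlab = "Minute ventilation (mL/min)",
                 ylab = "Effective FiO2 (%)", pch = 16, col = "grey40", ...)
  graphics::lines(x$data$mv[ord], x$fitted[ord], col = "firebrick", lwd = 2)
  graphics::abline(h = 21, lty = 3)
  invisible(x)
}

#' Fit the power law per cannula flow of a simulated dataset
#'
#' Replicate-averages each scenario x flow cell, then fits
#' [fit_power_law()] separately for every cannula flow present.
#'
#' @param dataset data frame from [generate_dataset()].
#' @return Data frame with columns \code{flow_l_min}, \code{k}, \code{a},
#'   \code{r2}, \code{n_points}, plus attribute \code{"fits"} holding the
#'   individual \code{power_fit} objects.
#' @export
fit_power_law_by_flow <- function(dataset) {
  cells <- replicate_average(dataset)
  flows <- sort(unique(cells$flow_l_min))
  fits <- lapply(flows, function(fl) {
    d <- cells[cells$flow_l_min == fl, ]
    fit_power_law(d$mv_ml_min, d$fio2_percent, flow_l_min = fl)
  })
  out <- data.frame(flow_l_min = flows,
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    a = vapply(fits, `[[`, numeric(1), "a"),
                    r2 = vapply(fits, `[[`, numeric(1), "r2"),
                    n_points = vapply(fits, `[[`, integer(1), "n_points"))
  attr(out, "fits") <- fits
  out
}

# average replicates within each scenario x flow cell
replicate_average <- function(dataset) {
  cols <- intersect(c("vt_ml", "rr_bpm", "ti_ms", "te_ms", "mv_ml_min",
                      "flow_l_min"), names(dataset))
  agg <- stats::aggregate(dataset$fio2_percent, by = dataset[cols], FUN = mean)
  names(agg)[ncol(agg)] <- "fio2_percent"
  agg <- agg[order(agg$flow_l_min, agg$vt_ml, agg$rr_bpm, agg$ti_ms), ]
  rownames(agg) <- NULL
  agg
}
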