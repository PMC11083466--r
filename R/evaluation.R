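#' Formula bias against simulated effective FiO2
#'
#' Replicate-averages the simulated dataset and computes, for every scenario x
#' flow cell, the signed difference (percentage points) between a closed-form
#' estimator and the simulated steady-state FiO2. Negative differences mean
#' the formula underestimates the effective FiO2; positive, that it
#' overestimates.
#'
#' @param dataset data frame from [generate_dataset()].
#' @param formula_name \code{"benaron_benitz"} or \code{"finer"}.
#' @param supply_o2_percent supply oxygen concentration (%).
#' @return Data frame of class \code{"bias_records"} with columns
#'   \code{mv_ml_min}, \code{flow_l_min}, \code{formula_name},
#'   \code{formula_fio2}, \code{sim_fio2}, \code{diff_pp}.
#' @export
formula_differences <- function(dataset,
                                formula_name = c("benaron_benitz", "finer"),
                                supply_o2_percent = 100) {
  formula_name <- match.arg(formula_name)
  cells <- replicate_average(dataset)
  pred <- if (formula_name == "benaron_benitz") {
    benaron_benitz_fio2(cells$flow_l_min, cells$ti_ms, cells$vt_ml,
                        supply_o2_percent)$fio2_percent
  } else {
    finer_fio2(cells$flow_l_min, cells$mv_ml_min,
               supply_o2_percent)$fio2_percent
  }
  out <- data.frame(mv_ml_min = cells$mv_ml_min,
                    flow_l_min = cells$flow_l_min,
                    formula_name = formula_name,
                    formula_fio2 = pred,
                    sim_fio2 = cells$fio2_percent,
                    diff_pp = pred - cells$fio2_percent)
  class(out) <- c("bias_records", "data.frame")
  out
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test with midranks for ties. The U statistic is
#' computed from the rank sum of \code{x}; the two-sided p-value is exact (by
#' enumeration of all group assignments of the pooled sample) when
#' \eqn{n_1 + n_2 \le 12}, and otherwise uses the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @return A list of class \code{"rank_sum_result"}: \code{u_statistic},
#'   \code{p_value}, \code{n1}, \code{n2}, \code{method}.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n <= 12) {
    # exact: recursively enumerate which pooled positions belong to sample 1
    u_all <- enumerate_rank_u(r, n1)
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)  # continuity corrected
      p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  structure(list(u_statistic = u, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "rank_sum_result")
}

# all U values over assignments of n1 of the pooled ranks to sample 1,
# by depth-first recursion over positions
enumerate_rank_u <- function(r, n1) {
  n <- length(r)
  offset <- n1 * (n1 + 1) / 2
  out <- numeric(choose(n, n1))
  cnt <- 0L
  recurse <- function(pos, left, acc) {
    if (left == 0L) {
      cnt <<- cnt + 1L
      out[cnt] <<- acc - offset
      return(invisible())
    }
    if (n - pos + 1L < left) return(invisible())
    recurse(pos + 1L, left - 1L, acc + r[pos])
    recurse(pos + 1L, left, acc)
  }
  recurse(1L, as.integer(n1), 0)
  out
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s)\n", x$method))
  cat(sprintf("  U = %.1f (n1 = %d, n2 = %d), two-sided p = %.4g\n",
              x$u_statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' MV thresholds below which a formula's bias exceeds a tolerance
#'
#' For each cannula flow and each tolerance, bins the bias records at the
#' exact grid MV values and reports the smallest grid MV above which (strictly)
#' every bin's mean absolute bias is below the tolerance. When every bin is
#' already below the tolerance the smallest grid MV is reported; when the
#' largest-MV bin still exceeds it, no MV qualifies and \code{NA} is reported
#' (serialised as \code{"none"}).
#'
#' @param records data frame from [formula_differences()].
#' @param thresholds_pp bias tolerances (percentage points).
#' @param mv_grid MV bin values; defaults to the distinct MVs in
#'   \code{records}.
#' @return Data frame with columns \code{flow_l_min}, \code{formula_name},
#'   \code{threshold_pp}, \code{min_mv_ml_min}.
#' @export
bias_threshold_summary <- function(records, thresholds_pp = c(3, 5),
                                   mv_grid = NULL) {
  if (!nrow(records)) stop("records must be non-empty")
  if (is.null(mv_grid)) mv_grid <- sort(unique(records$mv_ml_min))
  mv_grid <- sort(mv_grid)
  flows <- sort(unique(records$flow_l_min))
  rows <- list()
  for (fl in flows) {
    rf <- records[records$flow_l_min == fl & records$mv_ml_min %in% mv_grid, ]
    mean_abs <- vapply(mv_grid, function(m) {
      d <- rf$diff_pp[rf$mv_ml_min == m]
      if (!length(d)) NA_real_ else abs(mean(d))
    }, numeric(1))
    present <- !is.na(mean_abs)
    for (th in thresholds_pp) {
      fails <- present & mean_abs >= th
      min_mv <- if (!any(fails)) {
        min(mv_grid[present])
      } else if (fails[max(which(present))]) {
        NA_real_  # even the largest MV bin exceeds the tolerance
      } else {
        max(mv_grid[fails])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        flow_l_min = fl, formula_name = records$formula_name[1],
        threshold_pp = th, min_mv_ml_min = min_mv)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a bias-threshold summary as CSV
#'
#' Absent thresholds (\code{NA}) are written as the sentinel \code{"none"}.
#'
#' @param summary data frame from [bias_threshold_summary()].
#' @param path file path.
#' @export
write_bias_summary <- function(summary, path) {
  out <- summary
  out$min_mv_ml_min <- ifelse(is.na(out$min_mv_ml_min), "none",
                              as.character(out$min_mv_ml_min))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Per-cell rank-sum tests of formula vs simulated replicates
#'
#' For each scenario x flow cell, compares the triplicate simulated FiO2
#' readings with the (constant) formula prediction by [rank_sum_test()].
#' Mirrors a per-cell significance assessment of the formula bias.
#'
#' @param dataset replicate-level data frame from [generate_dataset()].
#' @param formula_name \code{"benaron_benitz"} or \code{"finer"}.
#' @param supply_o2_percent supply oxygen concentration (%).
#' @return Data frame with one row per cell: scenario keys, \code{diff_pp},
#'   \code{u_statistic}, \code{p_value}.
#' @export
cellwise_rank_sum <- function(dataset,
                              formula_name = c("benaron_benitz", "finer"),
                              supply_o2_percent = 100) {
  formula_name <- match.arg(formula_name)
  key <- interaction(dataset$vt_ml, dataset$rr_bpm, dataset$ti_ms,
                     dataset$flow_l_min, drop = TRUE)
  rows <- lapply(split(dataset, key), function(cell) {
    pred <- if (formula_name == "benaron_benitz") {
      benaron_benitz_fio2(cell$flow_l_min[1], cell$ti_ms[1], cell$vt_ml[1],
                          supply_o2_percent)$fio2_percent
    } else {
      finer_fio2(cell$flow_l_min[1], cell$mv_ml_min[1],
                 supply_o2_percent)$fio2_percent
    }
    ts <- rank_sum_test(rep(pred, nrow(cell)), cell$fio2_percent)
    data.frame(vt_ml = cell$vt_ml[1], rr_bpm = cell$rr_bpm[1],
               ti_ms = cell$ti_ms[1], flow_l_min = cell$flow_l_min[1],
               mv_ml_min = cell$mv_ml_min[1],
               diff_pp = pred - mean(cell$fio2_percent),
               u_statistic = ts$u_statistic, p_value = ts$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$flow_l_min, out$mv_ml_min), ]
}
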