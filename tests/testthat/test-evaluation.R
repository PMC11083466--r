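test_that("rank-sum test reproduces hand-enumerated small cases", {
  ts <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(ts$u_statistic, 0)
  expect_equal(ts$p_value, 1 / 3)  # 2 of the 6 assignments are as extreme
  # swapping the samples mirrors U and keeps p
  ts2 <- rank_sum_test(c(3, 4), c(1, 2))
  expect_equal(ts2$u_statistic, ts$n1 * ts$n2 - ts$u_statistic)
  expect_equal(ts2$p_value, ts$p_value)
  # fully tied samples: U at its null centre, p = 1
  ts3 <- rank_sum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ts3$u_statistic, 4.5)
  expect_equal(ts3$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact p-values match full enumeration for all n1 + n2 <= 8", {
  set.seed(3)
  for (n1 in 1:6) {
    for (n2 in 1:(8 - n1)) {
      if (n2 < 1) next
      x <- sample(1:4, n1, replace = TRUE)  # small support forces ties
      y <- sample(2:5, n2, replace = TRUE)
      got <- rank_sum_test(x, y)
      want <- oracle_rank_sum(x, y)
      expect_equal(got$u_statistic, want$u, info = paste(n1, n2))
      expect_equal(got$p_value, want$p, info = paste(n1, n2))
    }
  }
})

test_that("rank-sum agrees with wilcox.test in its comparable regimes", {
  # exact, no ties
  x <- c(1.1, 2.3, 3.7); y <- c(0.4, 2.9, 5.1, 6.2)
  got <- rank_sum_test(x, y)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(got$u_statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  # large samples: normal approximation with tie correction
  set.seed(9)
  x <- round(rnorm(15, 0, 2), 1); y <- round(rnorm(12, 1, 2), 1)
  got <- rank_sum_test(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("formula differences vanish when the simulator equals the formula", {
  # zero dead space + square waveform is the closed-form regime
  g <- enumerate_grid(c(10, 40), c(30, 60), c(500, 900))
  d <- generate_dataset(g, flows = 0.1, geometry = rig_geometry(0, 30, 50),
                        waveform = waveform_spec("square"), noise_sd_pp = 0,
                        vt_rule = FALSE)
  fd <- formula_differences(d, "benaron_benitz")
  expect_true(all(abs(fd$diff_pp) < 0.1))
  expect_error(formula_differences(d, "nope"))
})

test_that("bias signs at low MV match the reservoir mechanism", {
  # default geometry, MV = 150 (VT 5, RR 30): the airway reservoir pushes the
  # simulated FiO2 above Benaron-Benitz and below Finer
  g <- enumerate_grid(5, 30, c(700, 900))
  d <- generate_dataset(g, flows = 0.1, noise_sd_pp = 0)
  bb <- formula_differences(d, "benaron_benitz")
  fi <- formula_differences(d, "finer")
  expect_true(all(bb$diff_pp < 0))  # underestimation
  expect_true(all(fi$diff_pp > 0))  # overestimation
})

test_that("bias threshold summary scans MV bins as specified", {
  mk <- function(mv, diff, flow = 0.1) {
    structure(data.frame(mv_ml_min = mv, flow_l_min = flow,
                         formula_name = "benaron_benitz",
                         formula_fio2 = NA, sim_fio2 = NA, diff_pp = diff),
              class = c("bias_records", "data.frame"))
  }
  grid <- c(150, 200, 400, 667, 1000, 2000, 6400)
  # all-zero bias: every flow clears every threshold from the smallest MV
  s0 <- bias_threshold_summary(mk(grid, 0), thresholds_pp = c(3, 5))
  expect_equal(s0$min_mv_ml_min, c(150, 150))
  # synthetic decay 2000/MV: |diff| >= 5 up to 400, >= 3 up to 666.7
  dec <- mk(grid, 2000 / grid)
  sd5 <- bias_threshold_summary(dec, thresholds_pp = 5)
  expect_equal(sd5$min_mv_ml_min, 400)
  sd3 <- bias_threshold_summary(dec, thresholds_pp = 3)
  expect_equal(sd3$min_mv_ml_min, 400)  # largest failing grid MV below 666.7
  # with a grid point at the boundary the scan lands on it
  sd3b <- bias_threshold_summary(mk(c(grid, 600), c(2000 / grid, 2000 / 600)),
                                 thresholds_pp = 3)
  expect_equal(sd3b$min_mv_ml_min, 600)
  # constant large bias: no MV qualifies
  sc <- bias_threshold_summary(mk(grid, 10), thresholds_pp = 5)
  expect_true(is.na(sc$min_mv_ml_min))
  expect_error(bias_threshold_summary(mk(grid, 0)[0, ]), "non-empty")
})

test_that("bias summaries serialise absent thresholds as 'none'", {
  smry <- data.frame(flow_l_min = c(0.1, 1), formula_name = "finer",
                     threshold_pp = 5, min_mv_ml_min = c(400, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_bias_summary(smry, path)
  back <- utils::read.csv(path, colClasses = "character")
  expect_identical(back$min_mv_ml_min, c("400", "none"))
})

test_that("cellwise rank-sum compares triplicates against the formula", {
  g <- enumerate_grid(5, 30, c(700, 900))
  d <- generate_dataset(g, flows = 0.1, noise_sd_pp = 0.15, seed = 5)
  rs <- cellwise_rank_sum(d, "benaron_benitz")
  expect_identical(nrow(rs), 2L)
  expect_true(all(rs$diff_pp < 0))  # reservoir effect at MV 150
  expect_true(all(rs$p_value > 0 & rs$p_value <= 1))
  # formula constant vs three distinct readings: U is extreme
  expect_true(all(rs$u_statistic %in% c(0, 9)))
})
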