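test_that("effective dead space follows the rod / extension rules", {
  expect_equal(effective_dead_space(5), 4.2)    # rod removes 1 mL below 10 mL
  expect_equal(effective_dead_space(9.99), 4.2)
  expect_equal(effective_dead_space(10), 5.2)
  expect_equal(effective_dead_space(30), 5.2)
  expect_equal(effective_dead_space(50), 5.2)
  expect_equal(effective_dead_space(60), 6.0)   # 10% of VT above 50 mL
  expect_equal(effective_dead_space(80), 8.0)
  expect_equal(effective_dead_space(51), 5.2)   # floored at the base volume
  expect_equal(effective_dead_space(c(5, 30, 80)), c(4.2, 5.2, 8))
  expect_error(effective_dead_space(0), "positive")
})

test_that("zero cannula flow washes out to room air from either direction", {
  s <- breathing_scenario(5, 30, 900)
  r <- simulate_steady_state(s, cannula_setting(0), geo_for_vt(5))
  expect_equal(r$fio2_percent, 21)
  # wash-out protocol: start fully oxygenated, no flow -> back toward 21
  w <- simulate_steady_state(s, cannula_setting(0), geo_for_vt(5),
                             tol_pp = 0.001, start_fio2 = 100)
  expect_lt(abs(w$fio2_percent - 21), 0.2)
  expect_true(all(diff(w$per_breath_fio2) <= 1e-9))  # monotone decay
})

test_that("zero dead space + square waveform matches the closed form", {
  # Benaron-Benitz is exact when nothing is stored in the airway and
  # inspiratory flow is constant (and exceeds the cannula flow)
  set.seed(42)
  for (i in 1:20) {
    vt <- runif(1, 5, 80)
    rr <- runif(1, 30, 80)
    ti <- runif(1, 300, min(900, 0.55 * 60000 / rr))
    q_insp <- vt / (ti / 1000)                 # mL/s
    fl <- runif(1, 0.05, min(1, 0.9 * q_insp / (1000 / 60)))
    r <- simulate_steady_state(breathing_scenario(vt, rr, ti),
                               cannula_setting(fl), rig_geometry(0, 30, 50),
                               waveform_spec("square"))
    bb <- benaron_benitz_fio2(fl, ti, vt)$fio2_percent
    expect_lt(abs(r$fio2_percent - bb), 0.1)
  }
})

test_that("the airway reservoir raises FiO2 above the closed form", {
  s <- breathing_scenario(5, 30, 900)
  r <- simulate_steady_state(s, cannula_setting(0.1), geo_for_vt(5))
  expect_gt(r$fio2_percent, 44.7)
  expect_lte(r$fio2_percent, 100)
  expect_true(r$converged)
  # wash-in trace rises monotonically from room air
  expect_true(all(diff(r$per_breath_fio2) >= -1e-9))
  expect_gte(r$per_breath_fio2[1], 21)
})

test_that("O2 volume bookkeeping is conserved to 1e-9 at every step", {
  runs <- list(
    list(vt = 5, rr = 30, ti = 900, fl = 0.1, shape = "half_sine"),
    list(vt = 20, rr = 60, ti = 500, fl = 1, shape = "half_sine"),
    list(vt = 80, rr = 80, ti = 300, fl = 0.3, shape = "square"),
    list(vt = 10, rr = 40, ti = 500, fl = 0.5, shape = "half_sine"))
  for (p in runs) {
    r <- simulate_steady_state(breathing_scenario(p$vt, p$rr, p$ti),
                               cannula_setting(p$fl), geo_for_vt(p$vt),
                               waveform_spec(p$shape))
    expect_lt(r$mass_rel_error, 1e-9)
  }
})

test_that("steady-state FiO2 is monotone in flow, VT and Ti", {
  # non-decreasing in cannula flow
  by_flow <- vapply(c(0.1, 0.3, 0.5, 1), function(f) sim_fio2(10, 60, 500, f),
                    numeric(1))
  expect_true(all(diff(by_flow) >= 0))
  # non-increasing in tidal volume (fixed Ti, RR, flow)
  by_vt <- vapply(c(5, 10, 20, 40, 80), function(v) sim_fio2(v, 30, 900, 0.1),
                  numeric(1))
  expect_true(all(diff(by_vt) <= 0))
  # non-decreasing in inspiratory time (fixed VT, RR, flow)
  by_ti <- vapply(c(300, 500, 700, 900), function(ti) sim_fio2(10, 30, ti, 0.1),
                  numeric(1))
  expect_true(all(diff(by_ti) >= 0))
})

test_that("Ti = 300 ms gives the lowest FiO2 across the Ti grid", {
  for (vt in c(5, 40)) {
    for (fl in c(0.1, 1)) {
      vals <- vapply(default_ti_grid(), function(ti) sim_fio2(vt, 30, ti, fl),
                     numeric(1))
      expect_equal(which.min(vals), 1L)
    }
  }
})

test_that("FiO2 approaches room air as minute ventilation grows", {
  mv_seq <- vapply(list(c(10, 30), c(40, 60), c(80, 80)),
                   function(p) sim_fio2(p[1], p[2], 300, 0.1), numeric(1))
  expect_true(all(diff(mv_seq) < 0))
  expect_lt(mv_seq[3], 22)
})

test_that("steady state is insensitive to lung residual volume and time step", {
  base <- simulate_steady_state(breathing_scenario(5, 30, 900),
                                cannula_setting(0.1), geo_for_vt(5))
  doubled <- simulate_steady_state(breathing_scenario(5, 30, 900),
                                   cannula_setting(0.1),
                                   geo_for_vt(5, lung_residual_ml = 60))
  expect_lt(abs(base$fio2_percent - doubled$fio2_percent), 0.05)
  finer_dt <- simulate_steady_state(breathing_scenario(5, 30, 900),
                                    cannula_setting(0.1), geo_for_vt(5),
                                    waveform_spec("half_sine", dt_ms = 0.5))
  expect_lt(abs(base$fio2_percent - finer_dt$fio2_percent), 0.05)
})

test_that("simulator rejects invalid inputs", {
  s <- breathing_scenario(5, 30, 900)
  expect_error(simulate_steady_state(s, cannula_setting(0.1), geo_for_vt(5),
                                     waveform_spec("half_sine", dt_ms = 100)),
               "Ti/10")
  expect_error(simulate_steady_state(s, cannula_setting(0.1), geo_for_vt(5),
                                     tol_pp = 0), "positive")
  expect_error(rig_geometry(-1), "non-negative")
  expect_error(rig_geometry(5.2, n_cells = 5), "at least 10")
  expect_error(cannula_setting(-0.1), "non-negative")
  expect_error(cannula_setting(0.1, 0.1), "\\[0.21, 1\\]")
})

test_that("generate_dataset builds replicate rows deterministically", {
  g <- small_grid()
  d <- generate_dataset(g, flows = c(0.1, 1), replicates = 3, seed = 7)
  expect_identical(nrow(d), nrow(g) * 2L * 3L)
  expect_setequal(unique(d$replicate), 1:3)
  # identical seed reproduces rows exactly
  d2 <- generate_dataset(g, flows = c(0.1, 1), replicates = 3, seed = 7)
  expect_identical(d, d2)
  # different seed moves the noisy readings
  d3 <- generate_dataset(g, flows = c(0.1, 1), replicates = 3, seed = 8)
  expect_false(isTRUE(all.equal(d$fio2_percent, d3$fio2_percent)))
  # replicate SDs sit at the configured noise scale
  cellsd <- tapply(d$fio2_percent,
                   interaction(d$vt_ml, d$rr_bpm, d$ti_ms, d$flow_l_min,
                               drop = TRUE), stats::sd)
  expect_lt(median(cellsd), 0.5)
  expect_true(all(d$fio2_percent >= 21 & d$fio2_percent <= 100))
})

test_that("noise-free replicates are identical and empty grids yield no rows", {
  g <- enumerate_grid(5, 30, c(700, 900))
  d <- generate_dataset(g, flows = 0.1, noise_sd_pp = 0)
  expect_identical(nrow(d), 6L)
  for (cell in split(d$fio2_percent, d$ti_ms))
    expect_identical(length(unique(cell)), 1L)
  expect_identical(nrow(generate_dataset(empty <- g[0, ], flows = 0.1)), 0L)
  expect_error(generate_dataset(g, flows = numeric(0)), "flow")
  expect_error(generate_dataset(g, flows = 0.1, noise_sd_pp = -1),
               "non-negative")
})

test_that("datasets round-trip through CSV", {
  g <- enumerate_grid(5, 30, c(700, 900))
  d <- generate_dataset(g, flows = 0.1, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  expect_equal(read_dataset(path), d, tolerance = 1e-12)
})
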