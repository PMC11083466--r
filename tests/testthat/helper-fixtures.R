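# shared shorthand for tests

# geometry with the per-VT dead-space rule already applied
geo_for_vt <- function(vt, lung_residual_ml = 30, n_cells = 50) {
  g <- rig_geometry(lung_residual_ml = lung_residual_ml, n_cells = n_cells)
  g$dead_space_ml <- effective_dead_space(vt, g)
  g
}

# steady-state FiO2 under default (rig-emulating) conditions
sim_fio2 <- function(vt, rr, ti, flow, ...) {
  simulate_steady_state(breathing_scenario(vt, rr, ti),
                        cannula_setting(flow), geo_for_vt(vt), ...)$fio2_percent
}

# independent oracle: two-sided rank-sum p by direct enumeration over all
# C(n1+n2, n1) assignments of the pooled midranks
oracle_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  mu <- n1 * n2 / 2
  obs_u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
  list(u = obs_u, p = mean(abs(us - mu) >= abs(obs_u - mu) - 1e-12))
}

# a small scenario grid that still spans low and high minute ventilation
small_grid <- function() {
  enumerate_grid(vt_values = c(5, 20, 80), rr_values = c(30, 60, 80),
                 ti_values = c(300, 500, 700, 900))
}
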