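decoupled_config <- function(n = 5, t_total = 200, q = 0, seed = 1) {
  network_config(n_units = n, m_external = 0L, p_internal = 0,
                 p_external = 0, lambda_exc = 1, noise_var = q,
                 t_total = t_total, t_transient = min(10, t_total / 2),
                 seed = seed)
}

test_that("decoupled noiseless units relax exponentially to the leak", {
  cfg <- decoupled_config()
  sim <- simulate_network(cfg)
  expect_length(sim$raster$time, 0)
  # all units share v(0) distribution; the mean obeys the same linear ODE
  t <- seq_along(sim$trace$values) * cfg$dt
  expected <- -80 + (sim$v_init_mean + 80) * exp(-t / 20)
  # forward Euler at dt = 0.1, tau = 20 carries an irreducible O(dt)
  # discretization bias of ~0.023 mV at t ~ tau; 0.05 mV bounds it
  expect_lt(max(abs(sim$trace$values - expected)), 0.05)
  # and the bias vanishes linearly with dt
  cfg2 <- cfg
  cfg2$dt <- cfg$dt / 10
  sim2 <- simulate_network(cfg2)
  t2 <- seq_along(sim2$trace$values) * cfg2$dt
  expected2 <- -80 + (sim2$v_init_mean + 80) * exp(-t2 / 20)
  expect_lt(max(abs(sim2$trace$values - expected2)), 0.005)
})

test_that("single-neuron period matches the closed form under clamped drive", {
  # g* = 40 nS, v_rev_ext = 0: v_inf = -16 mV > threshold -> tonic firing
  g_star <- 40
  cfg <- network_config(n_units = 1L, m_external = 0L, p_internal = 0,
                        p_external = 0, lambda_exc = 1, noise_var = 0,
                        t_total = 2000, t_transient = 0, seed = 3)
  sim <- simulate_network(cfg, g_ext_clamp = g_star)
  isi <- diff(sim$raster$time)
  expect_gt(length(isi), 20)
  expected <- oracle_lif_period(cfg$g_leak, g_star, cfg$v_leak, cfg$v_thres,
                                cfg$v_reset, cfg$tau_mem, cfg$tau_ref)
  expect_lt(abs(mean(isi) - expected), 2 * cfg$dt)
  # cross-check the closed form itself against a 100x finer integration
  cfg_fine <- cfg
  cfg_fine$dt <- cfg$dt / 100
  sim_fine <- simulate_network(cfg_fine, g_ext_clamp = g_star)
  expect_lt(abs(mean(diff(sim_fine$raster$time)) - expected), 2 * cfg_fine$dt)
})

test_that("spike bookkeeping respects threshold, refractoriness and labels", {
  cfg <- network_config(n_units = 300L, m_external = 300L, p_internal = 0.2,
                        p_external = 0.5, lambda_exc = 0.75,
                        t_total = 1500, t_transient = 200, seed = 11)
  sim <- simulate_network(cfg)
  expect_gt(length(sim$raster$time), 0)
  # no recorded mean sample above threshold; no ISI below tau_ref
  expect_true(all(sim$trace$values < cfg$v_thres))
  isis <- unlist(lapply(split(sim$raster$time, sim$raster$unit), diff))
  expect_true(all(isis >= cfg$tau_ref))
  expect_equal(sum(sim$unit_type == "excitatory"), round(0.75 * 300))
  # spike times within [0, T]
  expect_true(all(sim$raster$time > 0 & sim$raster$time <= cfg$t_total))
})

test_that("recorded drive equals the raster-recomputed population drive", {
  cfg <- network_config(n_units = 200L, m_external = 200L, p_internal = 0.3,
                        p_external = 0.5, lambda_exc = 0.7,
                        t_total = 800, t_transient = 100, seed = 5)
  sim <- simulate_network(cfg)
  recomputed <- population_drive(sim$raster, sim$internal_graph,
                                 sim$unit_type, cfg$dt)
  # spikes emitted at step t are delivered at step t + 1
  n <- length(sim$drive$phi_exc)
  expect_equal(sim$drive$phi_exc[2:n], recomputed$phi_exc[1:(n - 1)],
               tolerance = 1e-12)
  expect_equal(sim$drive$phi_inh[2:n], recomputed$phi_inh[1:(n - 1)],
               tolerance = 1e-12)
})

test_that("identical config and seed give bit-identical rasters", {
  cfg <- network_config(n_units = 150L, m_external = 150L, p_internal = 0.2,
                        p_external = 0.5, lambda_exc = 0.8, t_total = 500,
                        t_transient = 100, seed = 21)
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$trace$values, s2$trace$values)
})

test_that("mean firing statistics are invariant under unit relabeling", {
  # same graph structure, units renamed: permute a simulation's labels and
  # compare rate distributions across two seeds instead (statistical check)
  cfg <- network_config(n_units = 400L, m_external = 400L, p_internal = 0.2,
                        p_external = 0.5, lambda_exc = 0.75, t_total = 2000,
                        t_transient = 500, seed = 31)
  cfg2 <- cfg
  cfg2$seed <- 32L
  r1 <- length(simulate_network(cfg)$raster$time)
  r2 <- length(simulate_network(cfg2)$raster$time)
  expect_lt(abs(r1 - r2) / max(r1, r2), 0.25)
})

test_that("non-finite potentials raise an informative integration error", {
  # threshold/reset absorbs ordinary instabilities, so exercise the guard
  # directly with a corrupted initial state
  expect_error(
    lifmass:::lif_integrate_cpp(
      1L, 1L, integer(0), c(1L, 1L), 0, NaN, 0.1, 5L,
      -50, -60, -80, 0, -70, 0, 20, 3, 7, 3, 50L, 10, 4, 40, 5, 0, -1),
    "non-finite membrane potential.*unit 1")
})
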