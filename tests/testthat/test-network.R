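cfg_small <- reference_config()   # 400 E + 100 I, conductance-compensated

test_that("connectivity has binomial in-degrees and respects class rules", {
  g <- build_connectivity(cfg_small)
  n <- g$n
  expect_equal(n, 500)
  # mean excitatory in-degree ~ N_E * P_E within 3 binomial sigma
  indeg_E <- tabulate(g$adj[g$cls == 0L] + 1L, nbins = n)
  mu <- (cfg_small$N_E - 1) * cfg_small$P_E
  sig <- sqrt(cfg_small$N_E * cfg_small$P_E * (1 - cfg_small$P_E) / n)
  expect_lt(abs(mean(indeg_E) - mu), 3 * sig)
  # rebuilding with the same seeds is identical
  g2 <- build_connectivity(cfg_small)
  expect_identical(g$adj, g2$adj)
})

test_that("two-area graphs have no inhibitory or non-excitatory cross edges", {
  cfg <- reference_config(n_areas = 2, P_ChR2 = 0.25)
  g <- build_connectivity(cfg)
  src <- rep(seq_len(g$n), diff(g$adj_ptr))
  tgt <- g$adj + 1L
  cross <- g$area[src] != g$area[tgt]
  expect_true(all(g$is_exc[src[cross]]))          # only E cross areas
  expect_true(all(g$cls[cross] == 2L))            # tagged long-range
  expect_true(all(!cross | g$area[src] != g$area[tgt]))
  # inhibitory sources never project across
  expect_equal(sum(!g$is_exc[src] & cross), 0)
  # transduction restricted to area 1 with about P_ChR2 prevalence
  expect_true(all(g$kappa[g$area == 1L] == 0))
  expect_gt(mean(g$kappa[g$area == 0L]), 0.25 - 3 * sqrt(0.25 * 0.75 / 500))
  expect_lt(mean(g$kappa[g$area == 0L]), 0.25 + 3 * sqrt(0.25 * 0.75 / 500))
  # P_ChR2 = 0: no transduction anywhere
  g0 <- build_connectivity(reference_config())
  expect_true(all(g0$kappa == 0))
})

test_that("synaptic kernel is peak-normalised, causal, and validated", {
  tpk <- 1 * 3 / (3 - 1) * log(3)    # closed-form peak time, tau 1/3 ms
  expect_equal(synaptic_kernel(tpk), 1, tolerance = 1e-12)
  expect_equal(tpk, 1.5 * log(3), tolerance = 1e-12)
  tt <- seq(0, 20, by = 0.01)
  k <- synaptic_kernel(tt, 1, 3, d_syn = 1.5)
  expect_lte(max(k), 1)
  expect_equal(max(k), 1, tolerance = 1e-6)
  expect_true(all(k[tt <= 1.5] == 0))
  expect_error(synaptic_kernel(1, 2, 2), "tau_decay > tau_rise")
})

test_that("quiescent network relaxes to the single-neuron fixed point", {
  cfg <- reference_config(nu_noise = 0)
  sim <- simulate_network(cfg, 300, record_v = TRUE)
  # initial conditions may fire a brief transient volley; silence afterwards
  expect_equal(sum(sim$spikes$t > 100), 0)
  v_rest <- wb_resting_potential(cfg)   # steady-state root-finding oracle
  v_end <- sim$v[nrow(sim$v), ]
  expect_lt(max(abs(v_end - v_rest)), 0.1)
})

test_that("identical seeds give bit-identical rasters and frozen-noise pairs", {
  g <- build_connectivity(cfg_small)
  a <- simulate_network(cfg_small, 600, graph = g, checkpoint_times = 300)
  b <- simulate_network(cfg_small, 600, graph = g)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp, b$lfp)
  # a run restarted from a checkpoint continues the trajectory exactly
  cont <- simulate_network(cfg_small, 300, graph = g,
                           state = a$checkpoints[[1]])
  late <- a$spikes[a$spikes$t > 300 + 1e-9, ]
  expect_equal(late$t, cont$spikes$t)
  expect_equal(late$id, cont$spikes$id)
  ia <- which(a$lfp_t > 300 + 1e-6)
  expect_equal(a$lfp[ia, 1], cont$lfp[, 1])
})

test_that("synchronisation index behaves like a variance ratio", {
  set.seed(1)
  x <- matrix(rnorm(200 * 50), 200, 50)
  # identical traces: chi = 1
  ident <- matrix(rep(x[, 1], 10), 200, 10)
  expect_equal(synchronization_index(ident), 1)
  # independent white noise: chi ~ 1/N
  expect_lt(synchronization_index(x), 2.5 / 50)
  expect_gt(synchronization_index(x), 0.25 / 50)
  expect_error(synchronization_index(x[1:50, ]), "100 samples")
  expect_error(synchronization_index(x[, 1, drop = FALSE]), "2 neurons")
  expect_error(synchronization_index(matrix(1, 200, 5)), "zero")
})

test_that("halving the integration step changes rates by < 2%", {
  sim1 <- simulate_network(cfg_small, 5300)
  cfg2 <- cfg_small
  cfg2$dt <- 0.025
  sim2 <- simulate_network(cfg2, 5300)
  r1 <- sum(sim1$spikes$t > 300) / 500 / 5
  r2 <- sum(sim2$spikes$t > 300) / 500 / 5
  expect_lt(abs(r1 - r2) / r1, 0.02)
})

test_that("light on a non-transduced area is rejected", {
  expect_error(
    simulate_network(reference_config(), 100,
                     light = light_stimulus(50, 3, 0.2)),
    "non-transduced")
})

test_that("scaled networks preserve in-degree times conductance", {
  full <- network_config()
  scaled <- network_config(scale_factor = 0.1)
  expect_equal(scaled$N_E * scaled$g_E, full$N_E * full$g_E)
  expect_equal(scaled$N_I * scaled$g_I, full$N_I * full$g_I)
  expect_equal(scaled$g_noise, full$g_noise)  # per-neuron drive unscaled
})
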