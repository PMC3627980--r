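test_that("intensity laws reproduce the tabulated dependence", {
  k1 <- chr2_kinetics(1.0)
  # tau_act at full intensity: 0.74 + 12 exp(-25) -> sub-millisecond activation
  expect_equal(k1$tau_act, 0.74 + 12 * exp(-25), tolerance = 1e-10)
  expect_lt(k1$tau_act, 1)

  k018 <- chr2_kinetics(0.18)
  expect_equal(k018$d, 0.27 - 0.05 * 0.18 + 0.0126 / 0.18, tolerance = 1e-12)

  # complement rule holds for any intensity
  W <- seq(0.01, 1, length.out = 50)
  kk <- chr2_kinetics(W)
  expect_equal(kk$A_persist + kk$A_inact_1 + kk$A_inact_2, rep(1, 50))
  expect_true(all(kk$A_persist >= 0 & kk$A_persist < 1))

  # activation accelerates with intensity
  expect_true(all(diff(kk$tau_act) < 0))

  # domain errors
  expect_error(chr2_kinetics(0), "W must be > 0")
  expect_error(chr2_kinetics(-0.1), "W must be > 0")
  expect_error(chr2_kinetics(1.2), "<= 1")
})

test_that("conductance trace is causal, non-negative and decays with tau_off", {
  p <- chr2_params()
  tt <- seq(0, 60, by = 0.02)
  stim <- light_stimulus(5, 3, 0.18)
  tr <- chr2_conductance(stim, tt, p)
  k <- chr2_kinetics(0.18, p)

  expect_true(all(tr$F >= 0))
  expect_true(all(tr$F[tt <= 5 + k$d] == 0))
  expect_gt(max(tr$F), 0.5)

  # single-exponential off-decay: F(t_off + 10) / F(t_off) = exp(-1)
  F_off <- tr$F[which.min(abs(tt - 8.02))]
  F_off10 <- tr$F[which.min(abs(tt - 18.02))]
  expect_equal(F_off10 / F_off, exp(-1), tolerance = 1e-3)

  # empty stimulus: all-zero trace, not an error
  z <- chr2_conductance(light_stimulus(), tt, p)
  expect_true(all(z$F == 0))
})

test_that("photocurrent follows -g F (V - V_rev)", {
  tt <- seq(0, 10, by = 0.05)
  tr <- chr2_conductance(light_stimulus(0, 3, 0.18), tt)
  p <- chr2_params()
  expect_equal(chr2_photocurrent(tr, V = 0, p, g = 10), rep(0, length(tt)))
  I <- chr2_photocurrent(tr, V = -60, p, g = 10)
  expect_true(all(I >= 0))       # depolarising at rest
  expect_gt(max(I), 0)
  expect_equal(chr2_photocurrent(tr, V = -60, p, g = 20), 2 * I)
  expect_error(chr2_photocurrent(tr, V = -60, p, g = -1), "negative")
})

test_that("peak photocurrent is maximised near 18% intensity", {
  W3 <- chr2_optimal_intensity(3)
  expect_equal(as.numeric(W3), 0.18, tolerance = 0.015)

  # long pulses: optimum drops into the 10-20% band
  W500 <- chr2_optimal_intensity(500, dt = 0.1, n_grid = 120)
  expect_gte(as.numeric(W500), 0.10)
  expect_lte(as.numeric(W500), 0.20)

  # unique interior maximum: monotone rise below the optimum
  scan <- attr(W3, "scan")
  below <- scan$peak[scan$W <= as.numeric(W3)]
  expect_true(all(diff(below) > 0))
})

test_that("light stimulus validates segments and ramps sample correctly", {
  expect_error(light_stimulus(c(0, 1), c(2, 1), c(0.5, 0.5)), "overlap")
  expect_error(light_stimulus(0, 1, 1.5), "\\[0, 1\\]")
  r <- light_ramp(0, 100, from = 0, to = 1, resolution = 1)
  expect_equal(nrow(r), 100)
  expect_equal(sum(r$duration), 100)
  expect_true(all(diff(r$intensity) > 0))
})

test_that("ramps keep conductance state continuous across segments", {
  tt <- seq(0, 220, by = 0.05)
  tr <- chr2_conductance(light_ramp(5, 205, 0.02, 0.6), tt)
  on <- tt > 7 & tt < 203
  expect_true(all(abs(diff(tr$F[on])) < 0.02)) # no jumps at 1 ms boundaries
  expect_gt(max(tr$F), 0.3)
})

test_that("calibrated gain reproduces the 2 nA peak rule", {
  p <- chr2_params()
  g <- chr2_gain(p)
  v_rest <- wb_resting_potential()
  tt <- seq(0, 30, by = 0.02)
  W <- as.numeric(chr2_optimal_intensity(3, p, V_clamp = v_rest))
  F <- chr2_conductance(light_stimulus(0, 3, W), tt, p)$F
  expect_equal(max(g * F * abs(v_rest)), 2000, tolerance = 1e-6)
  # printed mode returns the tabulated value
  expect_equal(chr2_gain(chr2_params(g_mode = "printed")), 7)
})
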