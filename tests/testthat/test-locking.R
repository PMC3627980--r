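fs <- 1000

test_that("phase differences recover constructed delays", {
  sp <- surrogate_spec(T_bar = 20, a = 0.2, sigma = 0.4, seed = 4)
  rs <- render_signal(generate_periods(sp, 300), sp)
  x <- rs$signal
  pd0 <- phase_difference_series(x, x, fs)
  expect_lt(max(abs(phaseloop:::.circ_dist(pd0$dphi, 0))), 1e-6)
  # b delayed by a quarter period: a leads by 0.25
  lag <- 5
  xb <- c(rep(0, lag), x[1:(length(x) - lag)])
  pd <- phase_difference_series(x[500:5500], xb[500:5500], fs)
  m <- phaseloop:::.circ_mean(pd$dphi) %% 1
  expect_equal(m, 0.25, tolerance = 0.03)
  # disjoint rhythms are rejected
  t <- seq_along(x) / fs
  expect_error(phase_difference_series(sin(2 * pi * 30 * t),
                                       sin(2 * pi * 80 * t), fs),
               "common spectral peak")
})

test_that("locking modes are detected and symmetric on bimodal data", {
  set.seed(7)
  dphi <- c(rnorm(2000, 0.22, 0.03), rnorm(1500, 0.78, 0.03)) %% 1
  md <- locking_modes(dphi)
  expect_equal(length(md$modes), 2)
  expect_equal(md$dphi_locked, 0.22, tolerance = 0.02)
  expect_equal(sum(md$modes), 1, tolerance = 0.04)   # mirror modes
  expect_equal(md$occupancy[1], 2000 / 3500, tolerance = 0.02)
})

test_that("cross-correlogram locates constructed lags and the leader", {
  sp <- surrogate_spec(T_bar = 20, a = 0, sigma = 0.3, seed = 5)
  rs <- render_signal(generate_periods(sp, 60), sp)
  x <- rs$signal[1:500]
  xc0 <- cross_correlogram(x, x, fs)
  expect_equal(xc0$peak_lag_ms, 0)
  # b = a delayed by 3 ms -> a leads, peak at +3 ms
  xb <- c(rep(0, 3), x[1:497])
  xc <- cross_correlogram(x[100:500], xb[100:500], fs)
  expect_equal(xc$peak_lag_ms, 3, tolerance = 1e-9)
  expect_equal(xc$leader, 1L)
  xc2 <- cross_correlogram(xb[100:500], x[100:500], fs)
  expect_equal(xc2$leader, 2L)
  # leader agrees with the sign of the circular-mean phase difference
  pd <- phase_difference_series(x[100:500], xb[100:500], fs, f_peak = 50)
  expect_gt(phaseloop:::.circ_mean(pd$dphi), 0)
})

test_that("switching statistics recover a synthetic telegraph process", {
  # two-mode telegraph signal with known mean dwell time, in a rotating frame
  set.seed(11)
  Tbar <- 20                      # ms per cycle
  dwell_cycles <- 120
  n_cycles <- 6000
  state <- numeric(n_cycles)
  s <- 1
  for (i in seq_len(n_cycles)) {
    if (runif(1) < 1 / dwell_cycles) s <- -s
    state[i] <- s
  }
  dphi_cycle <- ifelse(state > 0, 0.25, 0.75)
  dphi <- rep(dphi_cycle, each = 20) + rnorm(n_cycles * 20, 0, 0.02)
  st <- spontaneous_switching_stats(dphi %% 1, f_s = 1000, f_peak = 50,
                                    smooth_cycles = 50)
  expect_gt(st$n_switches, 10)
  expect_lt(abs(st$mean_waiting_periods - dwell_cycles) / dwell_cycles, 0.25)
  # monostable signal: lower-bound report, no switches
  mono <- rep(0.25, 40000) + rnorm(40000, 0, 0.02)
  st0 <- spontaneous_switching_stats(mono %% 1, f_s = 1000, f_peak = 50)
  expect_equal(st0$n_switches, 0)
  expect_true(st0$lower_bound)
})

test_that("shifting probability flags null stimulation as baseline-level", {
  cfg <- reference_config(n_areas = 2, P_ChR2 = 0.25)
  ex <- locking_experiments(cfg, n_onsets = 6, W_light = 0, lock_tol = 0.35)
  expect_s3_class(ex$experiments, "data.frame")
  # zero-intensity pulses leave the frozen-noise pair identical, so the
  # "induced" change equals the spontaneous change in the matched window
  sh <- shifting_probability(ex)
  pooled <- sum(sh$probability * sh$n, na.rm = TRUE) / sum(sh$n)
  expect_lt(abs(pooled - attr(sh, "baseline")), 0.35)
  # delta-monotonicity of switching: tighter tolerance, fewer hits
  sw05 <- switching_probability(ex, delta = 0.05)
  sw01 <- switching_probability(ex, delta = 0.01)
  p05 <- sum(sw05$probability * sw05$n, na.rm = TRUE)
  p01 <- sum(sw01$probability * sw01$n, na.rm = TRUE)
  expect_lte(p01, p05)
})
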