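fs <- 1000

test_that("testing stage detects oscillations only when present in both areas", {
  set.seed(2)
  t <- (1:1024) / fs
  osc <- sin(2 * pi * 55 * t) + rnorm(1024, 0, 0.3)
  noise <- rnorm(1024)
  expect_null(testing_stage(noise, f_s = fs))
  f1 <- testing_stage(osc, f_s = fs)
  expect_equal(f1, 55, tolerance = 0.05)
  # both-areas requirement
  expect_null(testing_stage(osc, noise, f_s = fs))
  f2 <- testing_stage(osc, osc + rnorm(1024, 0, 0.3), f_s = fs)
  expect_equal(f2, 55, tolerance = 0.05)
  expect_error(testing_config(window_ms = 50), "4 cycles")
})

test_that("resonator has the prescribed pole radius and passband", {
  y <- recursive_bandpass(c(1, rep(0, 1999)), 55, fs)
  # envelope (analytic-signal modulus) decays by sqrt(0.99) per sample
  env <- Mod(phaseloop:::.analytic_signal(y))
  decay <- (env[1200] / env[400])^(1 / 800)
  expect_equal(decay, sqrt(0.99), tolerance = 1e-3)
  # white-noise output peaks at f_peak
  set.seed(3)
  yn <- recursive_bandpass(rnorm(20000), 55, fs)
  expect_equal(as.numeric(spectral_peak(yn, fs, band = c(20, 120))), 55,
               tolerance = 2 / 55)
  # maximal gain among tones at the pass frequency
  t <- (1:4000) / fs
  gains <- vapply(c(40, 55, 70), function(f0) {
    stats::sd(recursive_bandpass(sin(2 * pi * f0 * t), 55, fs)[2000:4000])
  }, numeric(1))
  expect_equal(which.max(gains), 2L)
  expect_error(recursive_bandpass(1:10, 600, fs), "Nyquist")
  # causal: output up to t unaffected by later samples
  x <- rnorm(500)
  y1 <- recursive_bandpass(x, 55, fs)
  y2 <- recursive_bandpass(x[1:300], 55, fs)
  expect_equal(y1[1:300], y2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the two alpha1 conventions agree in magnitude at alpha2 = -0.99", {
  a1r <- attr(recursive_bandpass(1:10, 50, fs), "alpha1")
  a1t <- attr(recursive_bandpass(1:10, 50, fs, form = "tabulated"), "alpha1")
  expect_equal(abs(2 * sqrt(0.99)), 4 * 0.99 / 1.99, tolerance = 1e-4)
  expect_equal(abs(a1r), 2 * sqrt(0.99) * cos(2 * pi * 0.05), tolerance = 1e-12)
  # the resonator form actually passes the nominal frequency
  set.seed(4)
  yr <- recursive_bandpass(rnorm(20000), 50, fs)
  expect_lt(abs(as.numeric(spectral_peak(yr, fs, band = c(10, 490))) - 50), 2)
})

test_that("period extraction is sub-sample accurate on a pure tone", {
  t <- (1:2000) / fs
  buf <- extract_periods(sin(2 * pi * 50 * t), fs)
  expect_true(all(abs(buf$periods - 20) < 0.05))
  expect_equal(buf$T_bar, 20, tolerance = 1e-3)
  expect_error(extract_periods(sin(2 * pi * 50 * t[1:30])), "3 upward")
})

test_that("AR(1) estimator equals the brute-force autocovariance formula", {
  brute <- function(T) {
    k <- length(T); Tb <- mean(T)
    num <- 0
    for (i in 1:(k - 1)) num <- num + (T[i] - Tb) * (T[i + 1] - Tb)
    k / (k - 1) * num / sum((T - Tb)^2)
  }
  expect_equal(ar1_coefficient(c(10, 12, 10, 12, 10, 12)),
               brute(c(10, 12, 10, 12, 10, 12)))
  expect_lt(ar1_coefficient(c(10, 12, 10, 12, 10, 12)), -0.9)
  set.seed(6)
  for (rep in 1:10) {
    T <- rnorm(sample(5:50, 1), 20, 1)
    expect_equal(ar1_coefficient(T), brute(T), tolerance = 1e-12)
  }
  # long i.i.d. sequence: a -> 0 within sampling bounds
  T <- rnorm(2000, 20, 1)
  expect_lt(abs(ar1_coefficient(T)), 3 / sqrt(2000))
  # surrogate ground truth recovered
  gp <- generate_periods(surrogate_spec(a = 0.4, sigma = 1, seed = 8), 5000)
  expect_lt(abs(ar1_coefficient(gp$periods) - 0.4), 0.05)
  expect_error(ar1_coefficient(rep(10, 10)), "zero period variance")
  expect_error(ar1_coefficient(1:3), "at least 5")
})

test_that("onset prediction variants behave as forecast theory requires", {
  mk_buf <- function(per) {
    structure(list(crossings = c(0, cumsum(per)), periods = per,
                   T_bar = mean(per), k = length(per)),
              class = "monitoring_buffer")
  }
  per <- c(20, 21, 19, 20.5, 19.5, 20, 21, 19, 20.5, 19.8)
  buf <- mk_buf(per)
  m_lin <- prediction_model("linear", s = 3, phi_target = 0.2)
  m_ar <- prediction_model("ar1", s = 3, phi_target = 0.2)
  a_hat <- ar1_coefficient(per)
  geo <- (a_hat^4 - a_hat) / (a_hat - 1)
  c_lin <- predict_onset(m_lin, buf)
  c_ar <- predict_onset(m_ar, buf)
  # deviation form: correction applied to T_k - T_bar
  expect_equal(c_ar$t_on - c_lin$t_on, geo * (per[10] - mean(per)),
               tolerance = 1e-9)
  # literal printed form multiplies the full last period
  m_lit <- prediction_model("ar1", s = 3, phi_target = 0.2,
                            variant = "literal")
  c_lit <- predict_onset(m_lit, buf)
  expect_equal(c_lit$t_on - c_lin$t_on, geo * per[10], tolerance = 1e-9)
  # a = 0 exactly (deviations 1,0,-1,0,... have zero lag-1 autocovariance):
  # the geometric correction vanishes and the schemes coincide
  per0 <- 20 + c(1, 0, -1, 0, 1, 0, -1, 0)
  buf0 <- mk_buf(per0)
  expect_equal(ar1_coefficient(per0), 0)
  expect_equal(predict_onset(m_ar, buf0)$t_on,
               predict_onset(m_lin, buf0)$t_on)
  # constant periods: linear prediction is exact for any horizon
  bufc <- mk_buf(rep(20, 8))
  cc <- predict_onset(m_lin, bufc)
  expect_equal(cc$t_on, bufc$crossings[9] + 3 * 20 + 0.2 * 20)
  expect_error(predict_onset(m_lin, bufc, now = 1e6), "not in the future")
})

test_that("AR(1) one-step error ratio approaches sqrt(1 - a^2) on Gaussian surrogates", {
  for (a in c(0, 0.4, 0.7)) {
    sp <- surrogate_spec(T_bar = 20, a = a, sigma = 0.8, seed = 21)
    pe <- prediction_error_surrogate(sp, s = 1, n_windows = 4000,
                                     use_true_a = TRUE)
    expect_equal(attr(pe, "ratio"), sqrt(1 - a^2), tolerance = 0.04)
  }
})

test_that("rule of thumb: below a = 0.3 the AR(1) improvement is marginal", {
  sp <- surrogate_spec(T_bar = 20, a = 0.25, sigma = 0.8, seed = 22)
  pe <- prediction_error_surrogate(sp, s = 1, n_windows = 4000,
                                   use_true_a = TRUE)
  expect_gt(attr(pe, "ratio"), 1 - 0.08)   # < ~5-8% improvement
})

test_that("resonator lag compensation matches the measured crossing delay", {
  t <- (1:10000) / fs
  x <- sin(2 * pi * 50 * t)
  y <- recursive_bandpass(x, 50, fs)
  bx <- extract_periods(x[5001:10000], fs)
  by <- extract_periods(as.numeric(y[5001:10000]), fs)
  delay <- (by$crossings[10] - bx$crossings[10]) %% 20
  expect_equal(delay / 20, resonator_lag(50, fs), tolerance = 0.005)
})
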