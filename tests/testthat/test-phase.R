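fs <- 1000

test_that("Hilbert phase of a sinusoid follows the stated conventions", {
  t <- seq(0, 2, by = 1 / fs)[-1]
  x <- cos(2 * pi * 50 * t)
  ph <- hilbert_phase(x, fs)
  # instantaneous period recovered everywhere
  d <- diff(ph$phase) %% 1
  expect_equal(1 / mean(d) / fs * 1000, 20, tolerance = 1e-3)
  # phase 0.25 at the waveform maximum (0 at the upward zero crossing)
  i_max <- 900 + which.max(x[901:1100])
  expect_equal(ph$phase[i_max], 0.25, tolerance = 0.03)
  expect_error(hilbert_phase(rep(1, 100), fs), "flat")
})

test_that("linear phase interpolates between crossings", {
  cross <- c(0, 20, 40, 65)
  lp <- linear_phase(cross, c(10, 30, 52.5))
  expect_equal(lp$phase, c(0.5, 0.5, 0.5))
  expect_error(linear_phase(cross, 70), "outside")
  expect_error(linear_phase(0, 0), "at least 2")
  # sinusoid: linear and Hilbert phase agree up to the common origin
  t <- seq(0, 2, by = 1 / fs)[-1]
  x <- sin(2 * pi * 40 * t)
  ph <- hilbert_phase(x, fs)
  crossings <- extract_periods(x, fs)$crossings
  q <- ph$time > crossings[2] & ph$time < crossings[length(crossings) - 1]
  lp2 <- linear_phase(crossings, ph$time[q])
  dd <- (lp2$phase - ph$phase[q]) %% 1
  dd[dd > 0.5] <- dd[dd > 0.5] - 1
  expect_lt(max(abs(dd)), 0.03)
})

test_that("measured phase shift recovers constructed shifts", {
  sp <- surrogate_spec(T_bar = 20, a = 0.2, sigma = 0.5, seed = 3)
  rs <- render_signal(generate_periods(sp, 120), sp)
  x <- rs$signal
  # identical pair: zero shift
  expect_equal(measure_phase_shift(x, x, t_on = 200, f_s = fs), 0,
               tolerance = 1e-9)
  # advancing the perturbed trace by a quarter period: shift = +0.25
  adv <- round(20 / 4)
  xp <- c(x[-(1:adv)], rep(0, adv))
  sh <- measure_phase_shift(xp, x, t_on = 200, f_s = fs)
  expect_equal(sh, 0.25, tolerance = 0.03)
  expect_error(measure_phase_shift(x, x, t_on = 2000, f_s = fs),
               "insufficient")
})

test_that("phase-binned waveform localises extrema of asymmetric cycles", {
  sp <- surrogate_spec(T_bar = 20, a = 0, sigma = 0.2, waveform = "gamma",
                       skew = 0.3, noise_sd = 0.05, seed = 9)
  rs <- render_signal(generate_periods(sp, 400), sp)
  wf <- waveform_by_phase(rs$signal, fs)
  # skewed template: maximum displaced past a quarter cycle,
  # minimum past the maximum by less than half a cycle
  expect_gt(wf$phase_max, 0.2)
  expect_lt(wf$phase_max, 0.5)
  expect_gt(wf$separation, 0.2)
  expect_lt(wf$separation, 0.5)
})

test_that("zero-intensity pulses induce exactly zero phase shift", {
  # frozen noise makes the null pulse pair bit-identical, so the whole
  # pair-simulation / Hilbert / circular-averaging pipeline must return 0
  cfg <- reference_config(P_ChR2 = 0.25)
  prc <- estimate_prc(cfg, W_light = 0, n_onsets = 10)
  expect_true(all(attr(prc, "onsets")$shift == 0))
})
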