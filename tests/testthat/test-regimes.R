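# regime mapping, ramp stimulation and regime-dependent prediction error

test_that("regime scan reports bounded synchrony and gamma-band peaks", {
  cfg <- reference_config()
  scan <- regime_scan(cfg, nu_noise_grid = c(2, 4), P_I_grid = 0.3,
                      duration_ms = 1500, settle_ms = 500)
  expect_equal(nrow(scan), 2)
  expect_true(all(scan$chi >= 0 & scan$chi <= 1))
  expect_true(all(scan$f_peak > 20 & scan$f_peak < 120))
  expect_true(all(scan$rate_E > 0 & scan$rate_I > 0))
  # stronger drive pushes the rhythm faster (monotone drive dependence)
  expect_gt(scan$f_peak[scan$nu_noise == 4], scan$f_peak[scan$nu_noise == 2])
})

test_that("ramp photostimulation raises synchrony and gamma power", {
  # weak-synchrony operating point (low drive, sparse inhibition); a gentle
  # ramp recruits the rhythm. Stronger ramps overdrive the transduced
  # subpopulation and desynchronise instead, so the drive is kept small.
  cfg <- reference_config(nu_noise = 2, P_I = 0.2, P_ChR2 = 0.5)
  ramp <- light_ramp(600, 2800, from = 0, to = 0.03, resolution = 2)
  rs <- ramp_stimulation(cfg, ramp, duration_ms = 3000, settle_ms = 500)
  expect_gt(rs$chi_stim, rs$chi_base)
  expect_gt(mean(rs$gamma_power_stim), mean(rs$gamma_power_base))
  expect_s3_class(rs$spectrogram_stim, "spectrogram")
})

test_that("a zero-amplitude ramp leaves the frozen-noise run unchanged", {
  cfg <- reference_config(nu_noise = 2, P_ChR2 = 0.25)
  ramp0 <- light_ramp(600, 1400, from = 0, to = 0, resolution = 5)
  rs <- ramp_stimulation(cfg, ramp0, duration_ms = 1500, settle_ms = 400)
  expect_identical(rs$stimulated$lfp, rs$baseline$lfp)
  expect_equal(rs$chi_stim, rs$chi_base)
})

test_that("network prediction error is finite and scheme-comparable", {
  cfg <- reference_config()
  pe <- prediction_error_network(cfg, nu_noise_grid = 3, P_I_grid = 0.3,
                                 duration_ms = 6000, s = 3, k = 20)
  expect_equal(nrow(pe), 1)
  expect_true(is.finite(pe$sd_linear) && pe$sd_linear > 0)
  expect_true(is.finite(pe$ratio) && pe$ratio > 0)
  expect_true(pe$chi > 0 && pe$chi <= 1)
})
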