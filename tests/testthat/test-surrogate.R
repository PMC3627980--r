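test_that("AR(1) period generator matches stationary theory", {
  sp <- surrogate_spec(T_bar = 18, a = 0.6, sigma = 1, seed = 2)
  gp <- generate_periods(sp, 5000)
  expect_equal(mean(gp$periods), 18, tolerance = 0.05)
  expect_equal(stats::sd(gp$periods), 1 / sqrt(1 - 0.36), tolerance = 0.05)
  expect_equal(gp$crossings, c(0, cumsum(gp$periods)))
  # a = 0: i.i.d. periods, negligible lag-1 autocorrelation
  gp0 <- generate_periods(surrogate_spec(a = 0, sigma = 1, seed = 3), 5000)
  expect_lt(abs(ar1_coefficient(gp0$periods)), 3 / sqrt(5000))
  expect_error(surrogate_spec(a = 1.2), "stationary")
  # reproducible from the seed
  gp2 <- generate_periods(sp, 5000)
  expect_identical(gp$periods, gp2$periods)
})

test_that("round trip: generate, render, extract, estimate", {
  sp <- surrogate_spec(T_bar = 18, a = 0.4, sigma = 1, waveform = "sine",
                       noise_sd = 0, seed = 7)
  gp <- generate_periods(sp, 5000)
  rs <- render_signal(gp, sp)
  buf <- extract_periods(rs$signal, sp$f_s)
  # crossing times recovered to sub-sample accuracy
  n_cmp <- min(length(buf$crossings), length(gp$crossings) - 1)
  expect_lt(max(abs(buf$crossings[2:n_cmp] - gp$crossings[2:n_cmp])), 0.35)
  expect_equal(buf$T_bar, mean(gp$periods), tolerance = 0.01)
  # the AR coefficient survives the render/extract round trip
  expect_lt(abs(ar1_coefficient(buf) - 0.4), 0.05)
  # Hilbert phase matches the linear ground-truth phase up to a small offset
  ph <- hilbert_phase(rs$signal, sp$f_s, bandpass = FALSE)
  mid <- 2000:40000
  d <- (ph$phase[mid] - rs$phase[mid]) %% 1
  d[d > 0.5] <- d[d > 0.5] - 1
  expect_lt(phaseloop:::.circ_sd(d), 0.02)
  expect_lt(abs(phaseloop:::.circ_mean(d)), 0.01)
})

test_that("degenerate fixtures trigger the documented downstream errors", {
  sp <- surrogate_spec(T_bar = 20, a = 0, sigma = 0, seed = 1)
  rs <- render_signal(rep(20, 50), sp)
  flat <- rs$signal * 0
  expect_error(hilbert_phase(flat), "flat")
  expect_error(extract_periods(flat), "3 upward")
})

test_that("prediction-error theory holds on rendered surrogates end to end", {
  # render -> extract periods -> windowed forecasts, against true boundaries
  sp <- surrogate_spec(T_bar = 20, a = 0.5, sigma = 1, seed = 13)
  gp <- generate_periods(sp, 1500)
  rs <- render_signal(gp, sp)
  buf <- extract_periods(rs$signal, sp$f_s)
  P <- buf$periods; cross <- buf$crossings
  k <- 30; s <- 1
  nw <- length(P) - k - s
  el <- ea <- numeric(nw)
  for (w in seq_len(nw)) {
    Tb <- mean(P[w:(w + k - 1)])
    tk <- cross[w + k]; truth <- cross[w + k + s]
    el[w] <- tk + s * Tb - truth
    a <- 0.5
    ea[w] <- tk + s * Tb + (a^(s + 1) - a) / (a - 1) * (P[w + k - 1] - Tb) -
      truth
  }
  ratio <- stats::sd(ea) / stats::sd(el)
  expect_equal(ratio, sqrt(1 - 0.25), tolerance = 0.06)
})
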