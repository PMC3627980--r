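#' Testing-stage configuration
#'
#' Parameters of the oscillation-detection stage: a windowed FFT is applied
#' to demeaned LFP chunks and the monitoring stage starts only when the
#' gamma-band spectral peak exceeds a threshold (relative to the median
#' broadband power) in both recorded areas at a common frequency.
#'
#' @param window_ms FFT window length (ms); must cover at least 4 cycles of
#'   the lowest gamma frequency.
#' @param band gamma band (Hz).
#' @param power_ratio required ratio of gamma-peak power to median broadband
#'   power.
#' @param f_tol maximal peak-frequency mismatch between areas (Hz).
#' @return Object of class `testing_config`.
#' @export
testing_config <- function(window_ms = 256, band = c(30, 100),
                           power_ratio = 5, f_tol = 5) {
  if (window_ms < 4000 / band[1]) {
    stop("window must cover at least 4 cycles of the lowest gamma frequency")
  }
  structure(list(window_ms = window_ms, band = band,
                 power_ratio = power_ratio, f_tol = f_tol),
            class = "testing_config")
}

#' Oscillation detection (testing stage)
#'
#' @param lfp_a LFP chunk of the stimulation target area.
#' @param lfp_b optional LFP chunk of the second area (both-areas criterion;
#'   when supplied, detection requires a common peak in both).
#' @param f_s sampling rate (Hz).
#' @param config a [testing_config()].
#' @return The common gamma peak frequency `f_peak` (Hz), or `NULL` when the
#'   criterion is not met.
#' @export
testing_stage <- function(lfp_a, lfp_b = NULL, f_s = 1000,
                          config = testing_config()) {
  one <- function(x) {
    n <- round(config$window_ms * f_s / 1000)
    if (length(x) < n) n <- length(x)
    # average the periodograms of as many whole windows as the chunk holds
    n_win <- max(length(x) %/% n, 1)
    x <- x[(length(x) - n_win * n + 1):length(x)]
    if (stats::sd(x) == 0) return(NULL)
    pw <- 0
    for (w in seq_len(n_win)) {
      seg <- x[((w - 1) * n + 1):(w * n)]
      seg <- seg - mean(seg)
      pw <- pw + Mod(stats::fft(seg)[2:(n %/% 2)])^2 / n_win
    }
    fr <- (seq_len(n %/% 2 - 1)) * f_s / n
    inb <- fr >= config$band[1] & fr <= config$band[2]
    if (!any(inb)) return(NULL)
    i <- which.max(pw[inb])
    if (pw[inb][i] < config$power_ratio * stats::median(pw)) return(NULL)
    fr[inb][i]
  }
  fa <- one(lfp_a)
  if (is.null(fa)) return(NULL)
  if (is.null(lfp_b)) return(fa)
  fb <- one(lfp_b)
  if (is.null(fb) || abs(fa - fb) > config$f_tol) return(NULL)
  (fa + fb) / 2
}

#' Causal two-pole resonator band-pass filter
#'
#' Low-order recursive filter
#' \eqn{y_t = x_t + \alpha_1 y_{t-1} + \alpha_2 y_{t-2}} with
#' \eqn{\alpha_2 = -0.99}, i.e. pole radius \eqn{\sqrt{0.99}}, centred on the
#' oscillation frequency; constant per-sample cost, suitable for online use.
#' The default `"resonator"` form sets
#' \eqn{\alpha_1 = 2\sqrt{-\alpha_2}\cos(2\pi f_{peak}/f_s)}, placing the
#' conjugate pole pair at the pass frequency; the `"tabulated"` form
#' \eqn{\alpha_1 = 4\alpha_2\cos(2\pi(1 - f_{peak}/f_s))/(1 - \alpha_2)}
#' (equal in magnitude at \eqn{\alpha_2 = -0.99}: \eqn{4\cdot0.99/1.99 =
#' 2\sqrt{0.99}}, opposite sign convention) is selectable for comparison.
#'
#' @param x input samples.
#' @param f_peak pass frequency (Hz), must be below Nyquist.
#' @param f_s sampling rate (Hz, nominally 1000).
#' @param alpha2 second feedback coefficient (pole radius squared, negated).
#' @param form `"resonator"` (default) or `"tabulated"`.
#' @return Filtered series (same length), with attributes `alpha1`, `alpha2`.
#' @export
recursive_bandpass <- function(x, f_peak, f_s = 1000, alpha2 = -0.99,
                               form = c("resonator", "tabulated")) {
  form <- match.arg(form)
  if (f_peak >= f_s / 2) stop("f_peak must be below the Nyquist frequency")
  if (alpha2 >= 0) stop("alpha2 must be negative (complex pole pair)")
  alpha1 <- switch(form,
    resonator = 2 * sqrt(-alpha2) * cos(2 * pi * f_peak / f_s),
    tabulated = 4 * alpha2 * cos(2 * pi * (1 - f_peak / f_s)) / (1 - alpha2))
  y <- stats::filter(as.numeric(x), c(alpha1, alpha2), method = "recursive")
  structure(as.numeric(y), alpha1 = alpha1, alpha2 = alpha2)
}

#' Phase lag of the resonator at its pass frequency
#'
#' A causal two-pole resonator delays its output relative to the input; at
#' the pass frequency the delay is close to a quarter cycle. Zero-crossing
#' times extracted from the filtered signal are systematically late by this
#' (known) amount, so an online pipeline anchored to the raw-LFP phase
#' convention must subtract it.
#'
#' @inheritParams recursive_bandpass
#' @param f_eval frequency at which the lag is evaluated (Hz); by default
#'   the filter centre, but for an off-centre oscillation the lag at its
#'   actual frequency is the relevant one.
#' @return Lag in cycles (positive = output delayed).
#' @export
resonator_lag <- function(f_peak, f_s = 1000, alpha2 = -0.99,
                          form = c("resonator", "tabulated"),
                          f_eval = f_peak) {
  form <- match.arg(form)
  alpha1 <- switch(form,
    resonator = 2 * sqrt(-alpha2) * cos(2 * pi * f_peak / f_s),
    tabulated = 4 * alpha2 * cos(2 * pi * (1 - f_peak / f_s)) / (1 - alpha2))
  z <- exp(2i * pi * f_eval / f_s)
  H <- 1 / (1 - alpha1 / z - alpha2 / z^2)
  -Arg(H) / (2 * pi)
}

#' Period extraction from a monitored LFP (monitoring stage)
#'
#' Demeans the band-passed series, locates its upward zero crossings with
#' linear sub-sample interpolation, and returns the crossing times, the
#' estimated period lengths and their mean.
#'
#' @param x band-passed LFP samples of the monitoring window.
#' @param f_s sampling rate (Hz).
#' @param t0 time of the first sample (ms).
#' @return Object of class `monitoring_buffer`: list with `crossings` (ms),
#'   `periods` (ms), `T_bar`, `k` (number of periods).
#' @export
extract_periods <- function(x, f_s = 1000, t0 = 0) {
  x <- as.numeric(x) - mean(x)
  up <- which(x[-length(x)] <= 0 & x[-1] > 0)
  if (length(up) < 3) stop("fewer than 3 upward zero crossings in the window")
  frac <- -x[up] / (x[up + 1] - x[up])
  cross <- t0 + (up - 1 + frac) * 1000 / f_s
  periods <- diff(cross)
  structure(list(crossings = cross, periods = periods,
                 T_bar = mean(periods), k = length(periods)),
            class = "monitoring_buffer")
}

#' @export
print.monitoring_buffer <- function(x, ...) {
  cat(sprintf("monitoring_buffer: k = %d periods, T_bar = %.2f ms (f = %.1f Hz)\n",
              x$k, x$T_bar, 1000 / x$T_bar))
  invisible(x)
}

#' AR(1) coefficient of a period series
#'
#' The lag-1 autoregression coefficient estimated as
#' \deqn{a = \frac{k}{k-1}\,
#'   \frac{\sum_{i=1}^{k-1} (T_i - \bar T)(T_{i+1} - \bar T)}
#'        {\sum_{i=1}^{k} (T_i - \bar T)^2}}
#'
#' @param periods numeric vector of period lengths (or a
#'   `monitoring_buffer`), `k >= 5`.
#' @return The coefficient `a`.
#' @export
ar1_coefficient <- function(periods) {
  if (inherits(periods, "monitoring_buffer")) periods <- periods$periods
  k <- length(periods)
  if (k < 5) stop("need at least 5 periods to estimate the AR(1) coefficient")
  Tb <- mean(periods)
  d <- periods - Tb
  den <- sum(d^2)
  if (den == 0) {
    stop("zero period variance: AR model unusable, fall back to linear extrapolation")
  }
  k / (k - 1) * sum(d[-k] * d[-1]) / den
}

#' Prediction model for the stimulation onset time
#'
#' @param scheme `"ar1"` or `"linear"`.
#' @param s prediction-window length in oscillation cycles (default 3, about
#'   50 ms of a 40-70 Hz rhythm).
#' @param phi_target target onset phase (cycle fraction).
#' @param variant for the AR(1) scheme: `"deviation"` (default) applies the
#'   geometric correction \eqn{(a^{s+1} - a)/(a - 1)} to the deviation
#'   \eqn{T_k - \bar T} (the standard s-step AR(1) forecast); `"literal"`
#'   applies it to the full last period \eqn{T_k}.
#' @return Object of class `prediction_model`.
#' @export
prediction_model <- function(scheme = c("ar1", "linear"), s = 3,
                             phi_target = 0.18,
                             variant = c("deviation", "literal")) {
  scheme <- match.arg(scheme); variant <- match.arg(variant)
  stopifnot(s >= 1)
  structure(list(scheme = scheme, s = s, phi_target = phi_target,
                 variant = variant),
            class = "prediction_model")
}

#' Predict the stimulation onset time
#'
#' Forecasts the beginning of the cycle `s` cycles past the last monitored
#' crossing and adds the target-phase offset. The linear scheme extrapolates
#' with the mean period, \eqn{t_{k+s} = t_k + s\bar T}; the AR(1) scheme
#' adds the geometric correction term, which vanishes at `a = 0` (the two
#' schemes then coincide exactly).
#'
#' @param model a [prediction_model()].
#' @param buffer a `monitoring_buffer` from [extract_periods()].
#' @param now current stream time (ms); an onset in the past raises an error.
#' @return Object of class `stimulation_command`: list with `t_on` (ms),
#'   `t_pred` (forecast cycle boundary), `scheme`, `a` (estimated AR(1)
#'   coefficient, `NA` for the linear scheme), `phi_target`.
#' @export
predict_onset <- function(model, buffer, now = NULL) {
  stopifnot(inherits(model, "prediction_model"),
            inherits(buffer, "monitoring_buffer"))
  t_k <- buffer$crossings[length(buffer$crossings)]
  Tb <- buffer$T_bar
  s <- model$s
  a <- NA_real_
  t_pred <- t_k + s * Tb
  if (model$scheme == "ar1") {
    a <- ar1_coefficient(buffer$periods)
    if (abs(a) < 1) {
      coefgeo <- (a^(s + 1) - a) / (a - 1)
      t_pred <- t_pred + coefgeo *
        (if (model$variant == "deviation") {
          buffer$periods[buffer$k] - Tb
        } else {
          buffer$periods[buffer$k]
        })
    } # |a| >= 1: unusable model, keep the linear forecast
  }
  t_on <- t_pred + model$phi_target * Tb
  if (!is.null(now) && t_on <= now) {
    stop(sprintf("predicted onset %.2f ms is not in the future of %.2f ms (prediction window too short)",
                 t_on, now))
  }
  structure(list(t_on = t_on, t_pred = t_pred, scheme = model$scheme,
                 a = a, phi_target = model$phi_target),
            class = "stimulation_command")
}

#' @export
print.stimulation_command <- function(x, ...) {
  cat(sprintf("stimulation_command: t_on = %.2f ms (%s%s, target phase %.2f)\n",
              x$t_on, x$scheme,
              if (!is.na(x$a)) sprintf(", a = %.2f", x$a) else "",
              x$phi_target))
  invisible(x)
}

#' Closed-loop phase-targeted stimulation of the two-area motif
#'
#' Runs the full testing - monitoring - prediction - stimulation workflow
#' against the streaming simulated two-area network. Per trial: (1) the
#' stream is extended until the windowed-FFT testing criterion is met in
#' both areas; (2) a monitoring window of about 20 cycles is recorded and
#' band-passed online with the two-pole resonator; (3) the onset time of the
#' target phase is forecast `s` cycles ahead; (4) the stream is advanced to
#' the onset (checkpointing the state there), the realised onset phase is
#' measured post hoc on the unperturbed continuation (frozen noise), and the
#' light pulse is delivered from the checkpoint; (5) pre/post phase locking
#' is compared to classify switching. On failed switching the loop proceeds
#' with a new testing stage.
#'
#' @param config a two-area [network_config()] with `P_ChR2 > 0` on area 1.
#' @param model a [prediction_model()]; `phi_target` should be the PRC-peak
#'   phase.
#' @param n_trials number of stimulation trials.
#' @param W_light,T_light pulse parameters (protocol defaults 0.20, 3 ms).
#' @param monitor_cycles monitoring-window length (cycles).
#' @param settle_ms initial settle time before the first testing stage.
#' @param testing a [testing_config()].
#' @param progress print progress.
#' @return Object of class `closed_loop_log`: data frame with one row per
#'   trial (`f_peak`, `a`, `t_on`, `realized_phase`, `pre_dphi`,
#'   `post_dphi`, `switched`), plus attributes `model`, `dphi_locked`.
#' @export
run_closed_loop <- function(config, model = prediction_model(),
                            n_trials = 10, W_light = 0.20, T_light = 3,
                            monitor_cycles = 20, settle_ms = 1000,
                            testing = testing_config(), progress = FALSE) {
  stopifnot(config$n_areas == 2, config$P_ChR2 > 0)
  graph <- build_connectivity(config)
  fs <- 1000
  sim <- simulate_network(config, settle_ms, graph = graph)
  state <- sim$state
  lfp <- sim$lfp; lfp_t <- sim$lfp_t
  extend <- function(state, dur, light = NULL, cps = numeric(0)) {
    simulate_network(config, dur, light = light, graph = graph,
                     state = state, checkpoint_times = cps)
  }
  dphi_locked <- NULL
  rows <- vector("list", n_trials)
  for (trial in seq_len(n_trials)) {
    # --- testing stage
    f_peak <- NULL
    for (try in 1:20) {
      n_test <- min(nrow(lfp), round(4 * testing$window_ms * fs / 1000))
      idx <- (nrow(lfp) - n_test + 1):nrow(lfp)
      f_peak <- testing_stage(lfp[idx, 1], lfp[idx, 2], fs, testing)
      if (!is.null(f_peak)) break
      sim <- extend(state, testing$window_ms)
      state <- sim$state
      lfp <- rbind(lfp, sim$lfp); lfp_t <- c(lfp_t, sim$lfp_t)
    }
    if (is.null(f_peak)) stop("oscillation not detected after 20 testing windows")
    Tb0 <- 1000 / f_peak
    # --- monitoring stage
    sim <- extend(state, monitor_cycles * Tb0)
    state <- sim$state
    lfp <- rbind(lfp, sim$lfp); lfp_t <- c(lfp_t, sim$lfp_t)
    # filter with a pre-roll so the monitoring window is past the resonator
    # ring-in transient (pole radius sqrt(0.99): time constant ~200 samples)
    n_mon <- nrow(sim$lfp)
    n_pre <- min(length(lfp_t) - n_mon, 500)
    seg <- lfp[(length(lfp_t) - n_mon - n_pre + 1):length(lfp_t), 1]
    xf <- recursive_bandpass(seg - mean(seg), f_peak, fs)
    buf <- tryCatch(extract_periods(xf[(n_pre + 1):length(xf)], fs,
                                    t0 = sim$lfp_t[1]),
                    error = function(e) NULL)
    if (is.null(buf)) next  # oscillation lost: back to testing
    # compensate the known phase lag of the causal filter. The lag is
    # evaluated at an entrainment-free frequency estimate (spectral peak of
    # the raw window): the buffer's own mean period is pulled toward the
    # filter centre and would misplace the lag when the testing-stage
    # estimate is off-centre.
    f_raw <- tryCatch(as.numeric(spectral_peak(seg, fs, band = testing$band)),
                      error = function(e) 1000 / buf$T_bar)
    lag <- resonator_lag(f_peak, fs, f_eval = f_raw)
    buf$crossings <- buf$crossings - lag * buf$T_bar
    # --- prediction stage
    cmd <- tryCatch(predict_onset(model, buf, now = state$t),
                    error = function(e) NULL)
    if (is.null(cmd)) next
    t_on <- round(cmd$t_on / config$dt) * config$dt
    # --- advance to onset (checkpoint there), then past it unperturbed
    post_ms <- 65 * Tb0
    sim <- extend(state, (t_on - state$t) + post_ms, cps = t_on)
    cp <- sim$checkpoints[[1]]
    unp <- sim$lfp; unp_t <- sim$lfp_t
    # realised phase on the unperturbed continuation, measured offline with
    # the robust long-window spectral peak (not the coarse testing estimate)
    seg <- unp_t > t_on - 40 * Tb0
    xseg <- c(lfp[lfp_t > t_on - 40 * Tb0, 1], unp[seg, 1])
    f_off <- as.numeric(spectral_peak(xseg, fs))
    ph <- hilbert_phase(xseg, fs, f_peak = f_off)
    tseg <- c(lfp_t[lfp_t > t_on - 40 * Tb0], unp_t[seg])
    realized <- ph$phase[which.min(abs(tseg - t_on))]
    # --- deliver the pulse from the checkpoint
    pert <- extend(cp, post_ms,
                   light = light_stimulus(t_on, T_light, W_light))
    # pre/post locking
    pre_win <- lfp_t > t_on - 20 * Tb0
    pd_pre <- phase_difference_series(lfp[pre_win, 1], lfp[pre_win, 2], fs,
                                      f_peak = f_peak)
    tl <- pert$lfp_t   # absolute sample times
    post_win <- tl > t_on + 10 * Tb0 & tl <= t_on + 60 * Tb0
    pd_post <- phase_difference_series(pert$lfp[post_win, 1],
                                       pert$lfp[post_win, 2], fs,
                                       f_peak = f_peak)
    pre_m <- .circ_mean(pd_pre$dphi) %% 1
    post_m <- .circ_mean(pd_post$dphi) %% 1
    if (is.null(dphi_locked)) {
      dphi_locked <- min(pre_m, 1 - pre_m)
    }
    switched <- (pre_m <= 0.5) != (post_m <= 0.5)
    rows[[trial]] <- data.frame(trial = trial, f_peak = f_peak, a = cmd$a,
                                t_on = t_on, realized_phase = realized,
                                pre_dphi = pre_m, post_dphi = post_m,
                                switched = switched)
    # continue the stream from the perturbed state
    state <- pert$state
    lfp <- pert$lfp; lfp_t <- tl
    if (progress) message("trial ", trial, ": phase ", round(realized, 3),
                          if (switched) " [switched]" else "")
  }
  out <- do.call(rbind, rows)
  structure(out, model = model, dphi_locked = dphi_locked,
            class = c("closed_loop_log", "data.frame"))
}

#' @export
print.closed_loop_log <- function(x, ...) {
  cat(sprintf(paste0("closed_loop_log: %d trials, median realised phase = ",
                     "%.3f (target %.2f), switched %d/%d\n"),
              nrow(x), stats::median(x$realized_phase),
              attr(x, "model")$phi_target, sum(x$switched), nrow(x)))
  invisible(x)
}

#' Phase-prediction error on surrogate oscillations
#'
#' Monte-Carlo evaluation of the onset-phase prediction error for the linear
#' and AR(1) schemes on surrogate AR(1) period series: for each window, `k`
#' periods are observed, the cycle boundary `s` cycles ahead is forecast,
#' and the error is the discrepancy to the true boundary in units of the mean
#' period. For Gaussian AR(1) periods and `s = 1` the theoretical ratio of
#' AR(1) to linear error standard deviations is \eqn{\sqrt{1 - a^2}}.
#'
#' @param spec a [surrogate_spec()] (the waveform fields are ignored: the
#'   evaluation uses the ground-truth periods directly).
#' @param s prediction-window length (cycles).
#' @param k monitoring-window length (periods).
#' @param n_windows number of evaluation windows.
#' @param use_true_a use the generating AR coefficient instead of the
#'   windowed estimate (isolates forecast error from estimation error).
#' @return Data frame with one row per scheme: `scheme`, `sd_phase_error`,
#'   plus attribute `ratio` (AR1 / linear).
#' @export
prediction_error_surrogate <- function(spec, s = 1, k = 20,
                                       n_windows = 2000, use_true_a = FALSE) {
  gp <- generate_periods(
    surrogate_spec(spec$T_bar, spec$a, spec$sigma, seed = spec$seed),
    n_windows + k + s + 1)
  P <- gp$periods; cross <- gp$crossings
  err_lin <- err_ar <- numeric(n_windows)
  for (w in seq_len(n_windows)) {
    idx <- w:(w + k - 1)              # observed periods
    Tb <- mean(P[idx])
    t_k <- cross[w + k]               # last observed crossing
    truth <- cross[w + k + s]
    err_lin[w] <- (t_k + s * Tb - truth) / Tb
    a <- if (use_true_a) spec$a else ar1_coefficient(P[idx])
    coefgeo <- (a^(s + 1) - a) / (a - 1)
    err_ar[w] <- (t_k + s * Tb + coefgeo * (P[w + k - 1] - Tb) - truth) / Tb
  }
  out <- data.frame(scheme = c("linear", "ar1"),
                    sd_phase_error = c(stats::sd(err_lin), stats::sd(err_ar)))
  structure(out, ratio = out$sd_phase_error[2] / out$sd_phase_error[1])
}

#' Phase-prediction error across network regimes
#'
#' Simulates the network over a grid of drive and inhibition parameters and
#' evaluates, per grid point, the standard deviation of the onset-phase
#' prediction error (in units of the mean period) for the linear and AR(1)
#' schemes on sliding monitoring windows of the recorded LFP, together with
#' the synchronisation index.
#'
#' @param config base [network_config()].
#' @param nu_noise_grid,P_I_grid parameter grids.
#' @param duration_ms simulated duration per point.
#' @param s,k prediction- and monitoring-window lengths (cycles).
#' @return Data frame with columns `nu_noise`, `P_I`, `chi`, `f_peak`,
#'   `sd_linear`, `sd_ar1`, `ratio`, `a_mean`.
#' @export
prediction_error_network <- function(config, nu_noise_grid = c(2, 3, 4),
                                     P_I_grid = 0.3, duration_ms = 8000,
                                     s = 3, k = 20) {
  grid <- expand.grid(nu_noise = nu_noise_grid, P_I = P_I_grid)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$nu_noise <- grid$nu_noise[g]; cfg$P_I <- grid$P_I[g]
    sim <- simulate_network(cfg, duration_ms, record_v = TRUE)
    keep <- sim$lfp_t > 500
    lfp <- sim$lfp[keep, 1]
    chi <- synchronization_index(sim$v[keep, , drop = FALSE])
    f_peak <- as.numeric(spectral_peak(lfp, sim$sample_rate))
    xf <- recursive_bandpass(lfp - mean(lfp), f_peak, sim$sample_rate)
    buf <- extract_periods(xf, sim$sample_rate)
    P <- buf$periods; cross <- buf$crossings
    nw <- length(P) - k - s
    if (nw < 10) stop("run too short for the requested windows")
    el <- ea <- av <- numeric(nw)
    for (w in seq_len(nw)) {
      idx <- w:(w + k - 1)
      Tb <- mean(P[idx]); t_k <- cross[w + k]; truth <- cross[w + k + s]
      el[w] <- (t_k + s * Tb - truth) / Tb
      a <- ar1_coefficient(P[idx]); av[w] <- a
      ea[w] <- (t_k + s * Tb + (a^(s + 1) - a) / (a - 1) * (P[w + k - 1] - Tb) -
                  truth) / Tb
    }
    data.frame(nu_noise = cfg$nu_noise, P_I = cfg$P_I, chi = chi,
               f_peak = f_peak, sd_linear = stats::sd(el),
               sd_ar1 = stats::sd(ea), ratio = stats::sd(ea) / stats::sd(el),
               a_mean = mean(av))
  })
  do.call(rbind, out)
}
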