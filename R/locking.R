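#' Instantaneous inter-areal phase difference
#'
#' Hilbert-phase difference between the LFPs of two areas on the cyclic unit
#' interval, with its histogram. For two coupled gamma-oscillating
#' populations the distribution over a long run is bimodal: the two
#' out-of-phase locking modes at \eqn{\Delta\phi_{locked}} and
#' \eqn{1 - \Delta\phi_{locked}}, either area leading.
#'
#' @param lfp_a,lfp_b LFP vectors of the two areas (common sampling).
#' @param f_s sampling rate (Hz).
#' @param n_bins histogram bins.
#' @param f_tol maximal spectral-peak mismatch (Hz) before the two areas are
#'   declared not to share a common rhythm.
#' @param f_peak optional known common oscillation frequency (Hz); when
#'   supplied the per-area spectral-peak estimation (and the common-rhythm
#'   check) is skipped, which is appropriate for short windows.
#' @return Object of class `phase_difference`: data frame with `time` (ms)
#'   and `dphi` in `[0, 1)`; attributes `histogram` (data frame `bin_centre`,
#'   `density`), `f_peak`.
#' @export
phase_difference_series <- function(lfp_a, lfp_b, f_s = 1000, n_bins = 36,
                                    f_tol = 15, f_peak = NULL) {
  if (is.null(f_peak)) {
    fa <- as.numeric(spectral_peak(lfp_a, f_s))
    fb <- as.numeric(spectral_peak(lfp_b, f_s))
    if (abs(fa - fb) > f_tol) {
      stop(sprintf("no common spectral peak: %.1f vs %.1f Hz", fa, fb))
    }
    f0 <- (fa + fb) / 2
  } else {
    f0 <- f_peak
  }
  pa <- hilbert_phase(lfp_a, f_s, f_peak = f0)
  pb <- hilbert_phase(lfp_b, f_s, f_peak = f0)
  dphi <- (pa$phase - pb$phase) %% 1
  h <- graphics::hist(dphi, breaks = seq(0, 1, length.out = n_bins + 1),
                      plot = FALSE)
  structure(data.frame(time = pa$time, dphi = dphi),
            histogram = data.frame(bin_centre = h$mids, density = h$density),
            f_peak = f0,
            class = c("phase_difference", "data.frame"))
}

#' @export
print.phase_difference <- function(x, ...) {
  cat(sprintf("phase_difference: %d samples, f_peak = %.1f Hz, circ mean = %.3f\n",
              nrow(x), attr(x, "f_peak"), .circ_mean(x$dphi) %% 1))
  invisible(x)
}

#' Detect the two phase-locking modes
#'
#' Kernel-density peak detection on the circular phase-difference histogram.
#' The two out-of-phase modes of the symmetric two-area motif are mirror
#' images, summing to one full cycle.
#'
#' @param dphi phase differences in `[0, 1)` (vector or a
#'   [phase_difference_series()] result).
#' @param bw kernel bandwidth (cycle fraction).
#' @return List with `modes` (sorted mode locations), `dphi_locked` (the mode
#'   below 0.5), and `occupancy` (fraction of samples nearer each mode on the
#'   circle).
#' @export
locking_modes <- function(dphi, bw = 0.02) {
  if (inherits(dphi, "phase_difference")) dphi <- dphi$dphi
  # periodic kernel density on a circular grid
  grid <- seq(0, 1, length.out = 361)[-361]
  dens <- vapply(grid, function(g) {
    d <- abs(dphi - g); d <- pmin(d, 1 - d)
    mean(stats::dnorm(d, 0, bw))
  }, numeric(1))
  # local maxima on the circle
  nb <- length(grid)
  up <- dens > dens[c(nb, 1:(nb - 1))] & dens >= dens[c(2:nb, 1)]
  peaks <- grid[up][order(dens[up], decreasing = TRUE)]
  if (length(peaks) == 0) stop("no density mode found")
  modes <- sort(utils::head(peaks, 2))
  d1 <- abs(dphi - modes[1]); d1 <- pmin(d1, 1 - d1)
  d2 <- if (length(modes) > 1) pmin(abs(dphi - modes[2]),
                                    1 - abs(dphi - modes[2])) else Inf
  occ1 <- mean(d1 <= d2)
  list(modes = modes,
       dphi_locked = modes[modes <= 0.5][1],
       occupancy = c(occ1, 1 - occ1))
}

# circular distance of unit-interval phases to a reference (signed, (-0.5,0.5])
.circ_dist <- function(ph, ref = 0) {
  d <- (ph - ref) %% 1
  d[d > 0.5] <- d[d > 0.5] - 1
  d
}

#' Normalised cross-correlogram of two LFPs and leader call
#'
#' Cross-correlation over lags up to half an oscillation period, computed on
#' a window of the two signals. The leader is the area whose oscillation
#' temporally precedes the other: a positive peak lag of
#' \eqn{XC(\ell) = corr(a_t, b_{t+\ell})} means `b` reaches the same phase
#' later, i.e. area `a` leads.
#'
#' @param lfp_a,lfp_b LFP vectors (a window, e.g. 500 ms).
#' @param f_s sampling rate (Hz).
#' @param f_peak oscillation frequency (Hz), for the lag range; estimated
#'   when `NULL`.
#' @return List with `lag_ms`, `xc`, `peak_lag_ms`, `leader` (1 if `a`
#'   leads, 2 if `b` leads).
#' @export
cross_correlogram <- function(lfp_a, lfp_b, f_s = 1000, f_peak = NULL) {
  if (is.null(f_peak)) f_peak <- as.numeric(spectral_peak(lfp_a, f_s))
  max_lag <- ceiling(0.5 * f_s / f_peak)
  cc <- stats::ccf(as.numeric(lfp_a), as.numeric(lfp_b), lag.max = max_lag,
                   plot = FALSE, demean = TRUE)
  lag_ms <- as.numeric(cc$lag) * 1000 / f_s
  xc <- as.numeric(cc$acf)
  i <- which.max(xc)
  # ccf(a, b) at positive lag correlates a_{t+lag} with b_t: a lags b there,
  # so a positive peak lag means b leads under ccf's convention; flip to ours
  peak_lag_ms <- -lag_ms[i]
  list(lag_ms = -rev(lag_ms), xc = rev(xc), peak_lag_ms = peak_lag_ms,
       leader = if (peak_lag_ms >= 0) 1L else 2L)
}

#' Spontaneous switching statistics of the two-area motif
#'
#' Detects spontaneous changes of the phase-locking mode in an unperturbed
#' run by smoothing the signed circular phase difference over a sliding
#' window and recording sign changes, and reports waiting-time statistics in
#' units of the oscillation period.
#'
#' @param dphi a [phase_difference_series()] result (or vector of phase
#'   differences in `[0, 1)`).
#' @param f_s sampling rate (Hz).
#' @param f_peak oscillation frequency (Hz); taken from the series attribute
#'   when available.
#' @param smooth_cycles width of the smoothing window (oscillation cycles).
#' @return List with `n_switches`, `mean_waiting_periods` (mean inter-switch
#'   interval; when fewer than 2 switches are observed this is a lower bound
#'   and `lower_bound` is `TRUE`), `switch_times_ms`, `total_periods`.
#' @export
spontaneous_switching_stats <- function(dphi, f_s = 1000, f_peak = NULL,
                                        smooth_cycles = 50) {
  if (inherits(dphi, "phase_difference")) {
    if (is.null(f_peak)) f_peak <- attr(dphi, "f_peak")
    dphi <- dphi$dphi
  }
  if (is.null(f_peak)) stop("f_peak required when dphi is a bare vector")
  s <- .circ_dist(dphi, 0)          # signed difference, modes at +/- dphi_locked
  w <- max(3, round(smooth_cycles * f_s / f_peak))
  sm <- stats::filter(s, rep(1 / w, w), sides = 2)
  ok <- !is.na(sm)
  sgn <- sign(sm[ok])
  idx <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  t_ms <- (which(ok)[idx]) * 1000 / f_s
  total_periods <- length(dphi) / f_s * f_peak
  n_sw <- length(t_ms)
  if (n_sw >= 2) {
    mwt <- mean(diff(t_ms)) / 1000 * f_peak
    lb <- FALSE
  } else {
    mwt <- total_periods     # no (or one) switch observed: lower bound
    lb <- TRUE
  }
  list(n_switches = n_sw, mean_waiting_periods = mwt,
       switch_times_ms = t_ms, total_periods = total_periods,
       lower_bound = lb)
}

#' Pulse-perturbation experiments on the two-area motif
#'
#' Runs the single-pulse perturbation protocol against a phase-locked
#' two-area network: a long unperturbed run is simulated once (with state
#' checkpoints at the pulse onset times), and each pulse experiment restarts
#' from its checkpoint with a single rectangular light pulse applied to the
#' transduced (leader) area. For each experiment the pre-pulse lock is
#' verified (20 cycles before onset, circular std below `lock_tol`, leader =
#' transduced area); unlocked experiments are discarded with a log entry.
#'
#' @param config a two-area [network_config()] with `P_ChR2 > 0` on area 1.
#' @param n_onsets number of pulse onset times, uniform over
#'   `onset_window_cycles` cycles.
#' @param W_light,T_light pulse intensity and duration (protocol defaults
#'   0.20 and 3 ms).
#' @param settle_cycles unperturbed cycles before the onset window (attractor
#'   convergence; protocol 100).
#' @param post_cycles simulated cycles after each onset (>= 65 for the
#'   switching analysis).
#' @param onset_window_cycles width of the onset window.
#' @param lock_tol circular-std threshold for the pre-pulse lock check.
#' @param progress print progress.
#' @return Object of class `locking_experiments`: list with `experiments`
#'   (data frame: onset time, onset phase, pre/post phase differences,
#'   short-term mean over cycles 1-5, long-term mean over cycles 11-60,
#'   locked flag), `unperturbed` (the long run's phase-difference series),
#'   `dphi_locked`, `f_peak`, `config`, and the discarded-experiment log.
#' @export
locking_experiments <- function(config, n_onsets = 100, W_light = 0.20,
                                T_light = 3, settle_cycles = 100,
                                post_cycles = 65, onset_window_cycles = 50,
                                lock_tol = 0.05, progress = FALSE) {
  stopifnot(config$n_areas == 2, config$P_ChR2 > 0)
  graph <- build_connectivity(config)
  pilot <- simulate_network(config, 1000, graph = graph)
  f_peak <- as.numeric(spectral_peak(pilot$lfp[pilot$lfp_t > 300, 1],
                                     pilot$sample_rate))
  Tbar <- 1000 / f_peak
  settle_ms <- settle_cycles * Tbar
  win_ms <- onset_window_cycles * Tbar
  post_ms <- (post_cycles + 5) * Tbar

  set.seed(config$seeds$noise + 2000)
  t_on <- sort(settle_ms + stats::runif(n_onsets) * win_ms)
  t_on <- round(t_on / config$dt) * config$dt
  total_ms <- settle_ms + win_ms + post_ms
  unpert <- simulate_network(config, total_ms, graph = graph,
                             checkpoint_times = t_on)
  fs <- unpert$sample_rate
  pd_u <- phase_difference_series(unpert$lfp[, 1], unpert$lfp[, 2], fs)
  md <- locking_modes(pd_u$dphi[pd_u$time > settle_ms / 2])
  dphi_locked <- md$dphi_locked
  pa_u <- hilbert_phase(unpert$lfp[, 1], fs, f_peak = f_peak)

  log <- character(0)
  rows <- vector("list", n_onsets)
  for (i in seq_len(n_onsets)) {
    cp <- unpert$checkpoints[[i]]
    # pre-pulse lock verification on the unperturbed trace
    pre <- pd_u$time > t_on[i] - 20 * Tbar & pd_u$time <= t_on[i]
    pre_d <- pd_u$dphi[pre]
    pre_mean <- .circ_mean(pre_d) %% 1
    locked <- .circ_sd(pre_d) < lock_tol &&
      abs(.circ_dist(pre_mean, dphi_locked)) <
        abs(.circ_dist(pre_mean, 1 - dphi_locked))
    if (!locked) {
      log <- c(log, sprintf(
        "onset %d at %.1f ms discarded: pre-pulse state not locked with the transduced area leading",
        i, t_on[i]))
    }
    pert <- simulate_network(config, post_ms,
                             light = light_stimulus(t_on[i], T_light, W_light),
                             graph = graph, state = cp)
    pd_p <- phase_difference_series(pert$lfp[, 1], pert$lfp[, 2], fs,
                                    f_peak = f_peak)
    tl <- cp$t + pd_p$time + 1000 / fs  # absolute times of the perturbed samples
    short <- tl > t_on[i] & tl <= t_on[i] + 5 * Tbar
    long <- tl > t_on[i] + 10 * Tbar & tl <= t_on[i] + 60 * Tbar
    rows[[i]] <- data.frame(
      t_on = t_on[i],
      onset_phase = pa_u$phase[which.min(abs(pa_u$time - t_on[i]))],
      pre_dphi = pre_mean,
      short_dphi = .circ_mean(pd_p$dphi[short]) %% 1,
      long_dphi = .circ_mean(pd_p$dphi[long]) %% 1,
      locked = locked)
    if (progress && i %% 20 == 0) message("onset ", i, "/", n_onsets)
  }
  structure(list(experiments = do.call(rbind, rows),
                 unperturbed = pd_u, dphi_locked = dphi_locked,
                 f_peak = f_peak, Tbar = Tbar, config = config,
                 discarded = log),
            class = "locking_experiments")
}

#' @export
print.locking_experiments <- function(x, ...) {
  e <- x$experiments
  cat(sprintf(paste0("locking_experiments: %d pulses (%d locked pre-state), ",
                     "dphi_locked = %.3f, f_peak = %.1f Hz\n"),
              nrow(e), sum(e$locked), x$dphi_locked, x$f_peak))
  invisible(x)
}

.polar_hist <- function(phase, hit, n_bins, baseline) {
  bins <- floor(phase * n_bins) + 1
  bc <- (seq_len(n_bins) - 0.5) / n_bins
  p <- vapply(seq_len(n_bins), function(b) {
    h <- hit[bins == b]
    if (length(h)) mean(h) else NA_real_
  }, numeric(1))
  n <- vapply(seq_len(n_bins), function(b) sum(bins == b), numeric(1))
  structure(data.frame(bin_centre = bc, probability = p, n = n),
            baseline = baseline, class = c("polar_histogram", "data.frame"))
}

#' @export
print.polar_histogram <- function(x, ...) {
  cat(sprintf("polar_histogram: %d bins, baseline = %.3f, peak = %.3f at %.2f\n",
              nrow(x), attr(x, "baseline"),
              max(x$probability, na.rm = TRUE),
              x$bin_centre[which.max(x$probability)]))
  invisible(x)
}

#' Short-term shifting probability by onset phase
#'
#' Probability, per onset-phase bin, that a light pulse changes the
#' inter-areal phase difference (averaged over the first 5 post-pulse cycles)
#' by more than 10 percent relative to the pre-pulse difference, compared
#' with the probability of equally large spontaneous fluctuations in matched
#' unperturbed windows.
#'
#' @param exps a [locking_experiments()] result.
#' @param n_bins onset-phase bins (polar histogram convention, default 10).
#' @param threshold relative-change threshold (default 0.10).
#' @param mode `"relative"` (default): `|d_post - d_pre| / d_pre >
#'   threshold` with differences measured as circular distance from 0;
#'   `"absolute"`: `|d_post - d_pre| > threshold` in cycle fractions.
#' @return A `polar_histogram` with the spontaneous baseline as attribute.
#' @export
shifting_probability <- function(exps, n_bins = 10, threshold = 0.10,
                                 mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  e <- exps$experiments[exps$experiments$locked, ]
  if (nrow(e) == 0) stop("no locked experiments")
  chg <- function(pre, post) {
    a <- abs(.circ_dist(pre, 0)); b <- abs(.circ_dist(post, 0))
    if (mode == "relative") abs(b - a) / a else abs(b - a)
  }
  hit <- mapply(chg, e$pre_dphi, e$short_dphi) > threshold
  # baseline: same statistic on unperturbed windows
  pd <- exps$unperturbed
  Tb <- exps$Tbar
  t0s <- seq(min(e$t_on), max(e$t_on), by = 5 * Tb)
  base_hits <- vapply(t0s, function(t0) {
    pre <- pd$dphi[pd$time > t0 - 20 * Tb & pd$time <= t0]
    post <- pd$dphi[pd$time > t0 & pd$time <= t0 + 5 * Tb]
    if (!length(pre) || !length(post)) return(NA)
    chg(.circ_mean(pre) %% 1, .circ_mean(post) %% 1) > threshold
  }, logical(1))
  .polar_hist(e$onset_phase, hit, n_bins, mean(base_hits, na.rm = TRUE))
}

#' Long-term switching probability by onset phase
#'
#' Probability, per onset-phase bin, that after a light pulse the phase
#' difference averaged over post-pulse cycles 11-60 lies within
#' `1 - dphi_locked +/- delta`, i.e. that the motif has switched steadily to
#' the opposite locking mode (transduced area now laggard). The baseline is
#' the probability of spontaneous switching over an equivalent 50-cycle span
#' of the unperturbed run.
#'
#' @param exps a [locking_experiments()] result.
#' @param n_bins onset-phase bins (default 10).
#' @param delta tolerance around the switched mode (cycle fraction).
#' @return A `polar_histogram` with the spontaneous baseline as attribute.
#' @export
switching_probability <- function(exps, n_bins = 10, delta = 0.05) {
  e <- exps$experiments[exps$experiments$locked, ]
  if (nrow(e) == 0) stop("no locked experiments")
  target <- 1 - exps$dphi_locked
  hit <- abs(.circ_dist(e$long_dphi, target)) <= delta
  pd <- exps$unperturbed
  Tb <- exps$Tbar
  t0s <- seq(min(e$t_on), max(e$t_on), by = 5 * Tb)
  base_hits <- vapply(t0s, function(t0) {
    pre <- pd$dphi[pd$time > t0 - 20 * Tb & pd$time <= t0]
    post <- pd$dphi[pd$time > t0 + 10 * Tb & pd$time <= t0 + 60 * Tb]
    if (!length(pre) || !length(post)) return(NA)
    pre_m <- .circ_mean(pre) %% 1
    # started in the reference mode and ended in the opposite one
    ok_pre <- abs(.circ_dist(pre_m, exps$dphi_locked)) <
      abs(.circ_dist(pre_m, target))
    ok_pre && abs(.circ_dist(.circ_mean(post) %% 1, target)) <= delta
  }, logical(1))
  .polar_hist(e$onset_phase, hit, n_bins, mean(base_hits, na.rm = TRUE))
}
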