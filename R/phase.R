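#' Hilbert phase of an oscillating LFP
#'
#' Extracts the instantaneous phase of the dominant narrowband component of a
#' signal via the analytic signal, mapped to the cyclic unit interval
#' `[0, 1)`. The signal is demeaned, band-passed with a zero-phase Butterworth
#' filter centred on its spectral peak (bandwidth +/- `half_bw` Hz), and the
#' analytic-signal angle is shifted so that phase 0 falls at the upward zero
#' crossings of the band-passed signal (where the angle of the analytic
#' signal of a cosine-convention oscillation is \eqn{-\pi/2}).
#'
#' @param x signal vector (an LFP trace).
#' @param f_s sampling rate (Hz).
#' @param f_peak optional centre frequency (Hz); estimated from the spectrum
#'   when `NULL`.
#' @param half_bw half bandwidth of the band-pass (Hz).
#' @param bandpass set `FALSE` to skip filtering (signal already narrowband).
#' @return Object of class `phase_series`: data frame with columns `time`
#'   (ms, starting at 0 at the first sample) and `phase` in `[0, 1)`;
#'   attributes `f_peak`, `method`.
#' @export
hilbert_phase <- function(x, f_s = 1000, f_peak = NULL, half_bw = 20,
                          bandpass = TRUE) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("flat signal: no phase defined")
  x <- x - mean(x)
  if (bandpass) {
    if (is.null(f_peak)) f_peak <- as.numeric(spectral_peak(x, f_s))
    lo <- max(f_peak - half_bw, 1) / (f_s / 2)
    hi <- min(f_peak + half_bw, f_s / 2 - 1) / (f_s / 2)
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    x <- signal::filtfilt(bf, x)
  } else if (is.null(f_peak)) {
    f_peak <- as.numeric(spectral_peak(x, f_s))
  }
  a <- .analytic_signal(x)
  theta <- Arg(a) / (2 * pi)       # cycles, 0 at signal maximum
  phase <- (theta + 0.25) %% 1     # 0 at upward zero crossing
  structure(data.frame(time = (seq_along(x) - 1) * 1000 / f_s, phase = phase),
            f_peak = f_peak, method = "hilbert",
            class = c("phase_series", "data.frame"))
}

# analytic signal via FFT (positive frequencies doubled)
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Linear (interpolated) phase from zero-crossing times
#'
#' Piecewise-linear phase growing from 0 to 1 between consecutive upward zero
#' crossings; the cheap online approximation to the Hilbert phase.
#'
#' @param crossings strictly increasing upward zero-crossing times (ms).
#' @param t query times (ms), all within `[crossings[1],
#'   crossings[length(crossings)])`.
#' @return Object of class `phase_series` (method `"linear"`).
#' @export
linear_phase <- function(crossings, t) {
  if (length(crossings) < 2) stop("need at least 2 zero crossings")
  if (any(t < crossings[1] | t >= crossings[length(crossings)])) {
    stop("query times outside the span covered by the crossings")
  }
  i <- findInterval(t, crossings)
  ph <- (t - crossings[i]) / (crossings[i + 1] - crossings[i])
  structure(data.frame(time = t, phase = ph),
            f_peak = 1000 / mean(diff(crossings)), method = "linear",
            class = c("phase_series", "data.frame"))
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("phase_series (%s): %d samples, f_peak = %.1f Hz\n",
              attr(x, "method"), nrow(x), attr(x, "f_peak")))
  invisible(x)
}

# circular mean of unit-interval phases, result in (-0.5, 0.5]
.circ_mean <- function(ph) {
  z <- mean(exp(2i * pi * ph))
  m <- Arg(z) / (2 * pi)
  if (m <= -0.5) m <- m + 1
  m
}

# circular standard deviation (cycle fraction)
.circ_sd <- function(ph) {
  R <- Mod(mean(exp(2i * pi * ph)))
  sqrt(-2 * log(max(R, 1e-12))) / (2 * pi)
}

#' Induced phase shift between a perturbed and an unperturbed run
#'
#' Circular mean of the instantaneous Hilbert-phase difference (perturbed
#' minus unperturbed) over oscillation cycles 11 to 60 after the perturbation
#' onset: the first 10 post-onset cycles are discarded as transient and the
#' following 50 averaged. Positive values are phase advances, in cycle
#' fractions.
#'
#' @param lfp_pert,lfp_unpert LFP vectors from a frozen-noise run pair
#'   (identical topology, noise and initial state).
#' @param t_on perturbation onset time (ms) relative to the first sample.
#' @param f_s sampling rate (Hz).
#' @param f_peak optional common centre frequency (estimated from the
#'   unperturbed trace when `NULL`).
#' @param skip_cycles,avg_cycles discarded transient and averaging window
#'   lengths (cycles).
#' @return Phase shift in `(-0.5, 0.5]` cycle fractions.
#' @export
measure_phase_shift <- function(lfp_pert, lfp_unpert, t_on, f_s = 1000,
                                f_peak = NULL,
                                skip_cycles = 10, avg_cycles = 50) {
  if (is.null(f_peak)) f_peak <- as.numeric(spectral_peak(lfp_unpert, f_s))
  Tbar <- 1000 / f_peak
  need <- t_on + (skip_cycles + avg_cycles) * Tbar
  n_ms <- (length(lfp_unpert) - 1) * 1000 / f_s
  if (n_ms < need) {
    stop(sprintf("insufficient post-onset duration: have %.0f ms, need %.0f ms",
                 n_ms, need))
  }
  pp <- hilbert_phase(lfp_pert, f_s, f_peak = f_peak)
  pu <- hilbert_phase(lfp_unpert, f_s, f_peak = f_peak)
  win <- pu$time >= t_on + skip_cycles * Tbar &
    pu$time < t_on + (skip_cycles + avg_cycles) * Tbar
  .circ_mean(pp$phase[win] - pu$phase[win])
}

#' Empirical phase response curve of the population oscillation
#'
#' Runs frozen-noise pulse/no-pulse simulation pairs for many light onset
#' times distributed uniformly over a window of ongoing oscillation, assigns
#' each onset the Hilbert phase of the unperturbed twin run at the onset
#' time, and bins the induced phase shifts by onset phase.
#'
#' The unperturbed run is simulated once with state checkpoints at the onset
#' times; each perturbed run restarts from its checkpoint with the light
#' pulse applied, so the pair shares noise, topology and initial state
#' exactly and only needs to cover the post-onset analysis window.
#'
#' @param config a [network_config()] with `P_ChR2 > 0`.
#' @param W_light pulse intensity (default 0.18, the photocurrent optimum).
#' @param T_light pulse duration (ms).
#' @param n_onsets number of onset times (protocol default here 150; the full
#'   protocol uses 1500).
#' @param n_bins number of onset-phase bins (default 30).
#' @param settle_ms settle time before the onset window.
#' @param onset_window_cycles width of the onset window (cycles).
#' @param skip_cycles,avg_cycles see [measure_phase_shift()].
#' @param chi_warn warn and flag results if the synchronisation index of the
#'   unperturbed run falls below this threshold.
#' @param progress print progress.
#' @return Object of class `prc_estimate`: data frame with one row per bin
#'   (`bin_centre`, `mean_shift`, `sd_shift`, `n`) and metadata attributes.
#' @export
estimate_prc <- function(config, W_light = 0.18, T_light = 3,
                         n_onsets = 150, n_bins = 30, settle_ms = 1000,
                         onset_window_cycles = 50, skip_cycles = 10,
                         avg_cycles = 50, chi_warn = 0.05, progress = FALSE) {
  stopifnot(config$P_ChR2 > 0)
  graph <- build_connectivity(config)

  # pilot to locate the oscillation frequency
  pilot <- simulate_network(config, settle_ms, graph = graph)
  f_peak <- as.numeric(spectral_peak(pilot$lfp[pilot$lfp_t > settle_ms / 2, 1],
                                     pilot$sample_rate))
  Tbar <- 1000 / f_peak
  win_ms <- onset_window_cycles * Tbar
  post_ms <- (skip_cycles + avg_cycles + 5) * Tbar

  set.seed(config$seeds$noise + 1000)
  t_on <- sort(settle_ms + stats::runif(n_onsets) * win_ms)
  t_on <- round(t_on / config$dt) * config$dt

  total_ms <- settle_ms + win_ms + post_ms
  unpert <- simulate_network(config, total_ms, graph = graph,
                             record_v = TRUE, checkpoint_times = t_on)
  keep <- unpert$lfp_t > settle_ms
  chi <- synchronization_index(unpert$v[keep, , drop = FALSE])
  flagged <- chi < chi_warn
  if (flagged) {
    warning(sprintf("weak synchrony (chi = %.3f): PRC results flagged", chi))
  }
  pu <- hilbert_phase(unpert$lfp[, 1], unpert$sample_rate, f_peak = f_peak)

  pulse_of <- function(t0) light_stimulus(t0, T_light, W_light)
  shifts <- numeric(n_onsets)
  onset_phase <- numeric(n_onsets)
  for (i in seq_len(n_onsets)) {
    cp <- unpert$checkpoints[[i]]
    pert <- simulate_network(config, post_ms, light = pulse_of(t_on[i]),
                             graph = graph, state = cp)
    # align the perturbed segment with the unperturbed trace
    i0 <- which(unpert$lfp_t > cp$t)[1]
    n_seg <- min(length(pert$lfp_t), nrow(unpert$lfp) - i0 + 1)
    seg_u <- unpert$lfp[i0:(i0 + n_seg - 1), 1]
    shifts[i] <- measure_phase_shift(pert$lfp[seq_len(n_seg), 1], seg_u,
                                     t_on[i] - unpert$lfp_t[i0],
                                     f_s = unpert$sample_rate, f_peak = f_peak,
                                     skip_cycles = skip_cycles,
                                     avg_cycles = avg_cycles)
    onset_phase[i] <- pu$phase[which.min(abs(pu$time - t_on[i]))]
    if (progress && i %% 25 == 0) message("onset ", i, "/", n_onsets)
  }

  bins <- floor(onset_phase * n_bins) + 1
  bin_centre <- (seq_len(n_bins) - 0.5) / n_bins
  agg <- lapply(seq_len(n_bins), function(b) {
    s <- shifts[bins == b]
    data.frame(bin_centre = bin_centre[b],
               mean_shift = if (length(s)) .circ_mean(s) else NA_real_,
               sd_shift = if (length(s) > 1) .circ_sd(s) else NA_real_,
               n = length(s))
  })
  structure(do.call(rbind, agg),
            W_light = W_light, T_light = T_light, P_ChR2 = config$P_ChR2,
            n_onsets = n_onsets, f_peak = f_peak, chi = chi,
            flagged = flagged,
            onsets = data.frame(t_on = t_on, phase = onset_phase,
                                shift = shifts),
            class = c("prc_estimate", "data.frame"))
}

#' @export
print.prc_estimate <- function(x, ...) {
  cat(sprintf(paste0("prc_estimate: W = %.2g, T = %g ms, P_ChR2 = %.2g, ",
                     "%d onsets, f_peak = %.1f Hz, chi = %.2f%s\n"),
              attr(x, "W_light"), attr(x, "T_light"), attr(x, "P_ChR2"),
              attr(x, "n_onsets"), attr(x, "f_peak"), attr(x, "chi"),
              if (attr(x, "flagged")) " [weak synchrony]" else ""))
  pk <- prc_peak(x)
  cat(sprintf("  peak advance %.3f cycles at onset phase %.3f\n",
              pk$peak_shift, pk$peak_phase))
  invisible(x)
}

#' Location and height of the PRC positive peak
#'
#' @param prc a `prc_estimate`.
#' @return List with `peak_phase` (bin centre of the maximal mean advance)
#'   and `peak_shift` (cycle fraction).
#' @export
prc_peak <- function(prc) {
  ok <- !is.na(prc$mean_shift)
  i <- which.max(ifelse(ok, prc$mean_shift, -Inf))
  list(peak_phase = prc$bin_centre[i], peak_shift = prc$mean_shift[i])
}

#' Phase-binned average waveform of an oscillation
#'
#' Bins a signal by its instantaneous Hilbert phase and averages, yielding
#' the mean waveform over the cycle; reports the phases of the waveform
#' maximum and minimum.
#'
#' @param x signal vector.
#' @param f_s sampling rate (Hz).
#' @param n_bins phase bins.
#' @param ... passed to [hilbert_phase()].
#' @return List with `bin_centre`, `mean_wave`, `phase_max`, `phase_min`,
#'   `separation` (`(phase_min - phase_max) mod 1`, a phase-origin-free
#'   quantity).
#' @export
waveform_by_phase <- function(x, f_s = 1000, n_bins = 30, ...) {
  x <- as.numeric(x)
  ph <- hilbert_phase(x, f_s, ...)$phase
  bins <- floor(ph * n_bins) + 1
  xm <- x - mean(x)
  mw <- vapply(seq_len(n_bins), function(b) mean(xm[bins == b]), numeric(1))
  bc <- (seq_len(n_bins) - 0.5) / n_bins
  pmax_ <- bc[which.max(mw)]
  pmin_ <- bc[which.min(mw)]
  list(bin_centre = bc, mean_wave = mw, phase_max = pmax_, phase_min = pmin_,
       separation = (pmin_ - pmax_) %% 1)
}
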