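#' Parameters of the ChR2 conductance model
#'
#' Bundles the global (light-independent) constants of the phenomenological
#' channelrhodopsin-2 conductance model together with the fit constants of the
#' intensity-dependence laws for latency, activation and inactivation. All
#' defaults are the calibrated values obtained from voltage-clamp recordings of
#' ChR2-transfected cells over two decades of light intensity.
#'
#' The evoked conductance waveform while light of relative intensity
#' \eqn{W \in (0, 1]} is on is
#' \deqn{F(t) = A_{act}\,(1 - e^{-(t - t_{ON} - d)/\tau_{act}})\,
#'   (A_{persist} + A^{(1)}_{inact} e^{-(t - t_{ON} - d)/\tau^{(1)}_{inact}}
#'              + A^{(2)}_{inact} e^{-(t - t_{ON} - d)/\tau^{(2)}_{inact}})}
#' with \eqn{A_{persist} = 1 - A^{(1)}_{inact} - A^{(2)}_{inact}}; after
#' light-off the conductance relaxes to zero with time constant
#' \code{tau_off}.
#'
#' @param d_A,d_B,d_C latency law constants (ms, ms per unit intensity,
#'   ms times unit intensity): \eqn{d = d_A + d_B W + d_C / W}, clipped at 0.
#' @param tau_act_0,c_act,k_act activation time-constant law (ms, ms, 1/W):
#'   \eqn{\tau_{act} = \tau^{(0)}_{act} + c_{act} e^{-k_{act} W}}.
#' @param a_0,a_min,W_half activation amplitude law:
#'   \eqn{A_{act} = a_0 + (a_{min} - 1) / (1 + (W_{0.5}/W)^2)}.
#' @param tau_inact_1 global fast inactivation time constant (ms).
#' @param b_0,b_1,b_2,W_inact fast inactivation amplitude law:
#'   \eqn{A^{(1)}_{inact} = b_0 + b_1 / (b_2 + (W - W_{inact})^2)}.
#' @param tau_inact_2 global slow inactivation time constant (ms).
#' @param c_inact,k_inact slow inactivation amplitude law:
#'   \eqn{A^{(2)}_{inact} = c_{inact} e^{-k_{inact} W}}.
#' @param tau_off single-exponential off-decay time constant (ms).
#' @param g_chr2 printed coupling prefactor, in nS (0.007 uS = 7 nS).
#' @param V_chr2 reversal potential of the photocurrent (mV).
#' @param g_mode `"calibrated"` (default) rescales the prefactor so that a
#'   3 ms pulse at the optimal intensity evokes a 2 nA peak photocurrent in a
#'   model neuron at rest; `"printed"` uses `g_chr2` literally.
#' @return An object of class `chr2_params`.
#' @export
chr2_params <- function(d_A = 0.27, d_B = -0.05, d_C = 0.0126,
                        tau_act_0 = 0.74, c_act = 12.0, k_act = 25,
                        a_0 = 1.00, a_min = 0.4, W_half = 0.38,
                        tau_inact_1 = 9.06,
                        b_0 = 0.16, b_1 = 0.013, b_2 = 0.027, W_inact = 0.11,
                        tau_inact_2 = 59.6, c_inact = 0.29, k_inact = 2.4,
                        tau_off = 10, g_chr2 = 7, V_chr2 = 0,
                        g_mode = c("calibrated", "printed")) {
  g_mode <- match.arg(g_mode)
  p <- list(d_A = d_A, d_B = d_B, d_C = d_C,
            tau_act_0 = tau_act_0, c_act = c_act, k_act = k_act,
            a_0 = a_0, a_min = a_min, W_half = W_half,
            tau_inact_1 = tau_inact_1, b_0 = b_0, b_1 = b_1, b_2 = b_2,
            W_inact = W_inact, tau_inact_2 = tau_inact_2,
            c_inact = c_inact, k_inact = k_inact,
            tau_off = tau_off, g_chr2 = g_chr2, V_chr2 = V_chr2,
            g_mode = g_mode)
  taus <- c(tau_act_0 = tau_act_0, tau_inact_1 = tau_inact_1,
            tau_inact_2 = tau_inact_2, tau_off = tau_off)
  if (any(taus <= 0)) {
    stop("all ChR2 time constants must be > 0")
  }
  structure(p, class = "chr2_params")
}

#' @export
print.chr2_params <- function(x, ...) {
  cat("ChR2 conductance model parameters\n")
  cat(sprintf("  latency:      d = %.3g %+.3g*W %+.3g/W (ms)\n",
              x$d_A, x$d_B, x$d_C))
  cat(sprintf("  activation:   tau_act = %.3g + %.3g*exp(-%.3g*W) (ms)\n",
              x$tau_act_0, x$c_act, x$k_act))
  cat(sprintf("  inactivation: tau1 = %.3g ms, tau2 = %.3g ms, tau_off = %.3g ms\n",
              x$tau_inact_1, x$tau_inact_2, x$tau_off))
  cat(sprintf("  coupling:     g_chr2 = %.3g nS (%s), V_chr2 = %g mV\n",
              x$g_chr2, x$g_mode, x$V_chr2))
  invisible(x)
}

#' Piecewise-constant light stimulus
#'
#' A light waveform is a time-ordered set of non-overlapping constant-intensity
#' segments; ramps are represented as many short constant segments (see
#' [light_ramp()]).
#'
#' @param t_on onset times (ms).
#' @param duration segment durations (ms).
#' @param intensity relative intensities in `[0, 1]` (fraction of the maximal
#'   deliverable intensity).
#' @return An object of class `light_stimulus`: a data frame with columns
#'   `t_on`, `duration`, `intensity`.
#' @export
light_stimulus <- function(t_on = numeric(), duration = numeric(),
                           intensity = numeric()) {
  stopifnot(length(t_on) == length(duration),
            length(t_on) == length(intensity))
  o <- order(t_on)
  t_on <- t_on[o]; duration <- duration[o]; intensity <- intensity[o]
  if (any(duration < 0)) stop("segment durations must be >= 0")
  if (any(intensity < 0 | intensity > 1)) {
    stop("relative intensities must lie in [0, 1]")
  }
  if (length(t_on) > 1 &&
      any(t_on[-1] < (t_on + duration)[-length(t_on)] - 1e-9)) {
    stop("light segments must not overlap")
  }
  structure(data.frame(t_on = t_on, duration = duration,
                       intensity = intensity),
            class = c("light_stimulus", "data.frame"))
}

#' @rdname light_stimulus
#' @param t_end ramp end time (ms).
#' @param from,to intensity at ramp start/end.
#' @param resolution width of the constant segments used to sample the ramp
#'   (ms, default 1).
#' @export
light_ramp <- function(t_on, t_end, from = 0, to = 1, resolution = 1) {
  stopifnot(t_end > t_on, resolution > 0)
  starts <- seq(t_on, t_end, by = resolution)
  if (starts[length(starts)] >= t_end) starts <- starts[-length(starts)]
  durs <- c(diff(starts), t_end - starts[length(starts)])
  mid <- starts + durs / 2
  w <- from + (to - from) * (mid - t_on) / (t_end - t_on)
  light_stimulus(starts, durs, pmin(pmax(w, 0), 1))
}

#' Intensity dependence of the ChR2 kinetic parameters
#'
#' Evaluates the empirical laws giving latency, activation time constant and
#' the activation/inactivation amplitudes as functions of the relative light
#' intensity, and completes them with
#' \eqn{A_{persist} = 1 - A^{(1)}_{inact} - A^{(2)}_{inact}}.
#'
#' @param W relative light intensity (vectorised), must be in `(0, 1]`.
#' @param params a [chr2_params()] object.
#' @return A data frame of class `chr2_kinetics` with one row per intensity and
#'   columns `W`, `d`, `tau_act`, `A_act`, `A_inact_1`, `A_inact_2`,
#'   `A_persist`.
#' @export
chr2_kinetics <- function(W, params = chr2_params()) {
  if (any(W <= 0)) {
    stop("W must be > 0: the latency law diverges at zero intensity (no light)")
  }
  if (any(W > 1)) stop("W must be <= 1 (relative intensity)")
  p <- params
  d <- pmax(p$d_A + p$d_B * W + p$d_C / W, 0)
  tau_act <- p$tau_act_0 + p$c_act * exp(-p$k_act * W)
  A_act <- p$a_0 + (p$a_min - 1) / (1 + (p$W_half / W)^2)
  A1 <- p$b_0 + p$b_1 / (p$b_2 + (W - p$W_inact)^2)
  A2 <- p$c_inact * exp(-p$k_inact * W)
  structure(data.frame(W = W, d = d, tau_act = tau_act, A_act = A_act,
                       A_inact_1 = A1, A_inact_2 = A2,
                       A_persist = 1 - A1 - A2),
            class = c("chr2_kinetics", "data.frame"))
}

#' Evoked ChR2 conductance time course
#'
#' Evaluates the dimensionless conductance factor \eqn{F(t)} of the ChR2 model
#' for an arbitrary piecewise-constant light waveform. Within each light
#' segment the product-of-exponentials waveform is integrated exactly on the
#' sample grid; after light-off the conductance decays single-exponentially
#' with `tau_off`, and the decay state carries causally into gaps between
#' segments. Activation state is continuous across contiguous segment
#' boundaries (ramps); the inactivation envelope restarts fresh when a segment
#' begins from darkness, i.e. cumulative desensitisation across well-separated
#' pulses is not modelled.
#'
#' @param stim a [light_stimulus()].
#' @param t strictly increasing time grid (ms); resolution of 0.1 ms or finer
#'   recommended.
#' @param params a [chr2_params()] object.
#' @return An object of class `conductance_trace`: data frame with columns
#'   `time` (ms) and `F` (dimensionless, `>= 0`).
#' @export
chr2_conductance <- function(stim, t, params = chr2_params()) {
  stopifnot(inherits(stim, "light_stimulus"))
  if (is.unsorted(t, strictly = TRUE)) stop("time grid must be strictly increasing")
  p <- params
  F <- numeric(length(t))
  if (nrow(stim) == 0) {
    return(structure(data.frame(time = t, F = F),
                     class = c("conductance_trace", "data.frame")))
  }
  # state: x (activation), y1/y2 (inactivation components), ap (persistent level)
  x <- 0; y1 <- 0; y2 <- 0; ap <- 0
  prev_end <- -Inf   # end time of previous light segment
  for (s in seq_len(nrow(stim))) {
    t0 <- stim$t_on[s]; dur <- stim$duration[s]; Wl <- stim$intensity[s]
    # dark interval [prev_end, t0): off-decay of x, inactivation frozen
    if (is.finite(prev_end) && t0 > prev_end) {
      idx <- which(t >= prev_end & t < t0)
      if (length(idx)) {
        F[idx] <- x * (ap + y1 + y2) * exp(-(t[idx] - prev_end) / p$tau_off)
      }
      x <- x * exp(-(t0 - prev_end) / p$tau_off)
    }
    if (Wl <= 0) { # dark segment: continue decay
      prev_end <- max(prev_end, t0 + dur)
      next
    }
    k <- chr2_kinetics(Wl, p)
    contiguous <- is.finite(prev_end) && (t0 - prev_end) < 1e-9 && x > 1e-12
    if (!contiguous) {
      # fresh onset from dark: latency, fresh inactivation envelope
      y1 <- k$A_inact_1; y2 <- k$A_inact_2
      t_start <- t0 + k$d
    } else {
      t_start <- t0
    }
    ap <- k$A_persist
    t1 <- t0 + dur
    if (t_start < t1) {
      idx <- which(t >= t_start & t < t1)
      if (length(idx)) {
        s_rel <- t[idx] - t_start
        xa <- k$A_act + (x - k$A_act) * exp(-s_rel / k$tau_act)
        F[idx] <- xa * (ap + y1 * exp(-s_rel / p$tau_inact_1) +
                             y2 * exp(-s_rel / p$tau_inact_2))
      }
      el <- t1 - t_start
      x <- k$A_act + (x - k$A_act) * exp(-el / k$tau_act)
      y1 <- y1 * exp(-el / p$tau_inact_1)
      y2 <- y2 * exp(-el / p$tau_inact_2)
    }
    prev_end <- t1
  }
  # trailing off-decay
  idx <- which(t >= prev_end)
  if (length(idx)) {
    F[idx] <- x * (ap + y1 + y2) * exp(-(t[idx] - prev_end) / p$tau_off)
  }
  structure(data.frame(time = t, F = pmax(F, 0)),
            class = c("conductance_trace", "data.frame"))
}

#' ChR2 photocurrent from a conductance trace
#'
#' \eqn{I(t) = -g\,F(t)\,(V - V_{ChR2})}: inward (depolarising, positive in
#' the membrane-equation sign convention) for membrane potentials below the
#' reversal potential.
#'
#' @param trace a `conductance_trace` (or a bare numeric vector of `F` values).
#' @param V membrane potential (mV), scalar or vector matching the trace.
#' @param params a [chr2_params()] object (supplies `V_chr2`).
#' @param g coupling conductance in nS; defaults to [chr2_gain()] of `params`.
#' @return Numeric vector of currents in pA (positive = depolarising).
#' @export
chr2_photocurrent <- function(trace, V, params = chr2_params(), g = NULL) {
  if (is.null(g)) g <- chr2_gain(params)
  if (g < 0) stop("negative coupling conductance g")
  F <- if (inherits(trace, "conductance_trace")) trace$F else as.numeric(trace)
  if (any(F < -1e-12)) stop("conductance factor F must be non-negative")
  -g * F * (V - params$V_chr2)
}

#' Optimal relative light intensity
#'
#' Finds the relative intensity maximising the peak photocurrent evoked by a
#' rectangular pulse of given duration at a fixed clamp voltage, by a dense
#' scan over `(0, 1]` followed by quadratic interpolation around the grid
#' maximum. The non-monotonic intensity dependence of the peak current (faster
#' activation but stronger fast inactivation at high intensity) gives a unique
#' interior optimum.
#'
#' @param duration_ms pulse duration (ms), `> 0`.
#' @param params a [chr2_params()] object.
#' @param V_clamp clamp voltage (mV); the experimental clamp of -60 mV by
#'   default. The argmax is independent of the (fixed) driving force.
#' @param n_grid number of scan intensities.
#' @param dt trace resolution (ms).
#' @return The optimal intensity (scalar in `(0, 1]`), with attributes
#'   `peak_current_pA` (at unit prefactor scale times driving force) and
#'   `scan` (data frame of the scanned peaks).
#' @export
chr2_optimal_intensity <- function(duration_ms, params = chr2_params(),
                                   V_clamp = -60, n_grid = 200, dt = 0.02) {
  stopifnot(duration_ms > 0)
  Ws <- seq(1 / n_grid, 1, length.out = n_grid)
  tt <- seq(0, duration_ms + 5 * params$tau_off, by = dt)
  peaks <- vapply(Ws, function(w) {
    F <- chr2_conductance(light_stimulus(0, duration_ms, w), tt, params)$F
    max(-1 * F * (V_clamp - params$V_chr2)) # unit g
  }, numeric(1))
  i <- which.max(peaks)
  W_opt <- Ws[i]
  if (i > 1 && i < length(Ws)) {
    # quadratic interpolation through the three points around the maximum
    y1 <- peaks[i - 1]; y2 <- peaks[i]; y3 <- peaks[i + 1]
    h <- Ws[2] - Ws[1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 0) W_opt <- Ws[i] + h * 0.5 * (y1 - y3) / denom
  }
  structure(W_opt, peak_current_pA = peaks[i],
            scan = data.frame(W = Ws, peak = peaks))
}

#' Resolved ChR2 coupling conductance
#'
#' In `"printed"` mode returns the tabulated prefactor. In `"calibrated"` mode
#' (the default) the prefactor is re-derived from the calibration rule used to
#' couple the channel model to the network model: a 3 ms pulse at the optimal
#' intensity must evoke a 2 nA peak photocurrent in a model neuron at its
#' resting potential.
#'
#' @param params a [chr2_params()] object.
#' @param V_rest resting potential of the model neuron (mV).
#' @param target_peak_pA calibration target (pA).
#' @return Coupling conductance in nS.
#' @export
chr2_gain <- function(params = chr2_params(), V_rest = wb_resting_potential(),
                      target_peak_pA = 2000) {
  if (params$g_mode == "printed") return(params$g_chr2)
  W_opt <- chr2_optimal_intensity(3, params, V_clamp = V_rest)
  tt <- seq(0, 60, by = 0.02)
  F <- chr2_conductance(light_stimulus(0, 3, as.numeric(W_opt)), tt, params)$F
  peakF <- max(F)
  target_peak_pA / (peakF * abs(V_rest - params$V_chr2))
}
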