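#' Specification of a surrogate oscillation
#'
#' Ground-truth oscillatory test signals whose cycle-to-cycle period lengths
#' follow a first-order autoregressive process
#' \eqn{T_i = \bar T + a (T_{i-1} - \bar T) + \epsilon_i} with i.i.d.
#' Gaussian residuals. They emulate band-limited LFP-like rhythms with known
#' phase, so the phase, locking and prediction machinery can be validated in
#' seconds without network simulation. Not a generative model of real LFPs.
#'
#' @param T_bar mean period (ms).
#' @param a AR(1) coefficient, `|a| < 1`.
#' @param sigma residual standard deviation (ms).
#' @param waveform `"sine"` or `"gamma"` (asymmetric template with a slow
#'   depolarising rise and fast fall, mimicking inhibition-dominated gamma).
#' @param skew warp strength of the asymmetric template (0 = sinusoid;
#'   positive values sharpen the fall and delay the waveform maximum).
#' @param noise_sd additive white measurement noise (signal units; the
#'   waveform has unit amplitude).
#' @param f_s sampling rate (Hz).
#' @param seed RNG seed.
#' @return Object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(T_bar = 18, a = 0.3, sigma = 1,
                           waveform = c("sine", "gamma"), skew = 0.25,
                           noise_sd = 0, f_s = 1000, seed = 1L) {
  waveform <- match.arg(waveform)
  if (abs(a) >= 1) stop("|a| must be < 1 for a stationary AR(1) process")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(T_bar = T_bar, a = a, sigma = sigma, waveform = waveform,
                 skew = skew, noise_sd = noise_sd, f_s = f_s,
                 seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' @export
print.surrogate_spec <- function(x, ...) {
  cat(sprintf("surrogate_spec: T_bar = %g ms, a = %g, sigma = %g ms, %s%s\n",
              x$T_bar, x$a, x$sigma, x$waveform,
              if (x$noise_sd > 0) sprintf(", noise %g", x$noise_sd) else ""))
  invisible(x)
}

#' Draw AR(1)-correlated cycle periods
#'
#' Stationary-initialised draw of `n` periods; the cumulative sums give the
#' ground-truth cycle boundary times.
#'
#' @param spec a [surrogate_spec()].
#' @param n number of cycles.
#' @return List with `periods` (ms), `crossings` (n+1 boundary times starting
#'   at 0).
#' @export
generate_periods <- function(spec, n) {
  stopifnot(inherits(spec, "surrogate_spec"), n >= 1)
  set.seed(spec$seed)
  Tb <- spec$T_bar; a <- spec$a; s <- spec$sigma
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, if (s > 0) s / sqrt(1 - a^2) else 0)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, s)
    for (i in 2:n) x[i] <- a * x[i - 1] + eps[i - 1]
  }
  periods <- pmax(Tb + x, 0.1 * Tb)  # clip positive
  list(periods = periods, crossings = c(0, cumsum(periods)))
}

#' Render a surrogate oscillation from a period series
#'
#' Each cycle renders one waveform template time-warped to its period, plus
#' optional additive white noise. The ground-truth phase grows linearly from
#' 0 to 1 within each cycle, with phase 0 at the cycle boundary (the upward
#' zero crossing of the template).
#'
#' @param periods result of [generate_periods()] (or a bare numeric vector of
#'   periods in ms).
#' @param spec a [surrogate_spec()].
#' @return List with `time` (ms), `signal`, `phase` (ground truth, `[0,1)`),
#'   `crossings` (cycle boundaries, ms).
#' @export
render_signal <- function(periods, spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (is.list(periods)) periods <- periods$periods
  cross <- c(0, cumsum(periods))
  t_end <- cross[length(cross)]
  t <- seq(0, t_end - 1000 / spec$f_s, by = 1000 / spec$f_s)
  i <- findInterval(t, cross)
  u <- (t - cross[i]) / periods[i]
  w <- if (spec$waveform == "sine") {
    sin(2 * pi * u)
  } else {
    # warped sinusoid: phase runs faster late in the cycle -> slow rise,
    # sharp fall, waveform maximum displaced past a quarter cycle
    g <- u - spec$skew * sin(2 * pi * u) / (2 * pi)
    sin(2 * pi * g)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 1L)
    w <- w + stats::rnorm(length(w), 0, spec$noise_sd)
  }
  list(time = t, signal = w, phase = u, crossings = cross)
}
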