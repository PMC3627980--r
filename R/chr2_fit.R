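#' Synthetic voltage-clamp conductance traces
#'
#' Generates noisy conductance-factor traces of the ChR2 model at a set of
#' light intensities, emulating the voltage-clamp recordings from which the
#' model constants were originally calibrated. Used to validate the fitting
#' machinery by parameter recovery.
#'
#' @param W intensities in `(0, 1]` (at least one).
#' @param duration_ms light-pulse duration (ms); traces cover the light-on
#'   phase (activation plus biphasic inactivation).
#' @param dt sample interval (ms).
#' @param noise_sd standard deviation of additive Gaussian noise, as a
#'   fraction of the per-trace peak (e.g. 0.01 for 1\% noise).
#' @param params generating [chr2_params()].
#' @param seed RNG seed.
#' @return List of per-intensity records `list(W, time, F)`.
#' @export
chr2_synthetic_traces <- function(W, duration_ms = 200, dt = 0.1,
                                  noise_sd = 0, params = chr2_params(),
                                  seed = 1L) {
  set.seed(seed)
  tt <- seq(0, duration_ms, by = dt)
  lapply(W, function(w) {
    F <- chr2_conductance(light_stimulus(0, duration_ms + dt, w), tt, params)$F
    if (noise_sd > 0) F <- F + rnorm(length(F), 0, noise_sd * max(F))
    list(W = w, time = tt, F = F)
  })
}

# model trace for the light-on phase, t relative to onset
.chr2_trace_model <- function(t, d, tau_act, A_act, A1, A2, tau1, tau2) {
  s <- t - d
  out <- numeric(length(t))
  on <- s > 0
  s <- s[on]
  out[on] <- A_act * (1 - exp(-s / tau_act)) *
    ((1 - A1 - A2) + A1 * exp(-s / tau1) + A2 * exp(-s / tau2))
  out
}

#' Fit the ChR2 conductance model to voltage-clamp traces
#'
#' Two-stage least-squares calibration. Stage A fits all traces
#' simultaneously with the two inactivation time constants shared (global)
#' across intensities and latency, activation time constant and the three
#' amplitudes free per intensity, using bounded Levenberg-Marquardt with a
#' small multi-start over jittered initial values. Stage B then fits the
#' intensity-dependence laws (latency, activation time constant, activation
#' amplitude, two inactivation amplitudes) to the per-intensity estimates;
#' this stage requires at least four intensities spanning at least one decade.
#'
#' @param traces list of records `list(W, time, F)` as produced by
#'   [chr2_synthetic_traces()] (`F` is the dimensionless conductance factor;
#'   photocurrents recorded at a known clamp voltage can be converted by
#'   dividing by \eqn{g (V_{clamp} - V_{ChR2})}).
#' @param fix_k_inact optional fixed value for the slow-inactivation decay
#'   rate in stage B (the original calibration fixed it manually to aid
#'   convergence); `NULL` (default) estimates it.
#' @param n_starts number of multi-start initialisations for stage A.
#' @param seed seed for the multi-start jitter.
#' @return An object of class `chr2_fit`: list with elements
#'   `per_intensity` (data frame of stage-A estimates with standard errors),
#'   `tau_inact_1`, `tau_inact_2` (shared estimates), `rss`, `stage_b`
#'   (fitted law constants, or a note when intensities are insufficient) and
#'   `converged`.
#' @export
chr2_fit <- function(traces, fix_k_inact = NULL, n_starts = 3, seed = 42L) {
  nW <- length(traces)
  if (nW < 1) stop("need at least one trace")
  Ws <- vapply(traces, `[[`, numeric(1), "W")
  if (anyDuplicated(Ws)) stop("duplicate intensities in traces")

  # stage A ------------------------------------------------------------
  # theta = c(log tau1, log tau2, then per intensity: d, log tau_act, A_act, A1, A2)
  unpack <- function(theta) {
    list(tau1 = exp(theta[1]), tau2 = exp(theta[2]),
         per = matrix(theta[-(1:2)], nrow = nW, byrow = TRUE,
                      dimnames = list(NULL, c("d", "ltau_act", "A_act",
                                              "A1", "A2"))))
  }
  resid_fn <- function(theta) {
    u <- unpack(theta)
    unlist(lapply(seq_len(nW), function(i) {
      p <- u$per[i, ]
      traces[[i]]$F - .chr2_trace_model(traces[[i]]$time, p["d"],
                                        exp(p["ltau_act"]), p["A_act"],
                                        p["A1"], p["A2"], u$tau1, u$tau2)
    }))
  }
  init_one <- function(jitter = 0) {
    per <- t(vapply(seq_len(nW), function(i) {
      F <- traces[[i]]$F; tt <- traces[[i]]$time
      pk <- max(F)
      d0 <- tt[which(F > 0.02 * pk)[1]]
      if (is.na(d0)) d0 <- 0.3
      plateau <- mean(F[tt > max(tt) * 0.9])
      c(d = max(d0, 0.01), ltau_act = log(1), A_act = pk * 1.05,
        A1 = max(min(1 - plateau / max(pk, 1e-12), 0.9), 0.05) * 0.7,
        A2 = max(min(1 - plateau / max(pk, 1e-12), 0.9), 0.05) * 0.3)
    }, numeric(5)))
    theta <- c(log(9), log(60), as.vector(t(per)))
    if (jitter > 0) theta <- theta + rnorm(length(theta), 0, jitter)
    theta
  }
  lower <- c(log(0.5), log(5),
             rep(c(0, log(0.05), 1e-4, 0, 0), nW))
  upper <- c(log(50), log(500),
             rep(c(5, log(20), 3, 0.95, 0.95), nW))
  set.seed(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    th0 <- pmin(pmax(init_one(jitter = if (k == 1) 0 else 0.05), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("stage A (joint trace fit) failed to converge")
  u <- unpack(best$par)
  # standard errors from the LM Jacobian
  se <- rep(NA_real_, length(best$par))
  cov <- tryCatch({
    dof <- length(resid_fn(best$par)) - length(best$par)
    s2 <- best$deviance / max(dof, 1)
    s2 * solve(best$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  per <- data.frame(W = Ws, d = u$per[, "d"], tau_act = exp(u$per[, "ltau_act"]),
                    A_act = u$per[, "A_act"], A_inact_1 = u$per[, "A1"],
                    A_inact_2 = u$per[, "A2"])
  per$A_persist <- 1 - per$A_inact_1 - per$A_inact_2

  out <- list(per_intensity = per,
              tau_inact_1 = u$tau1, tau_inact_2 = u$tau2,
              se = se, rss = best$deviance,
              converged = best$info %in% 1:4)

  # stage B ------------------------------------------------------------
  decades <- log10(max(Ws) / min(Ws))
  if (nW < 4 || decades < 1) {
    out$stage_b <- paste0("insufficient intensities for the intensity-",
                          "dependence laws (need >= 4 spanning >= 1 decade)")
  } else {
    df <- per
    nls_law <- function(formula, start, lower = NULL, upper = NULL) {
      tryCatch(minpack.lm::nlsLM(formula, data = df, start = start,
                                 lower = lower, upper = upper,
                                 control = stats::nls.control(maxiter = 200,
                                                              warnOnly = TRUE)),
               error = function(e) NULL)
    }
    f_d <- nls_law(d ~ d_A + d_B * W + d_C / W,
                   start = list(d_A = 0.3, d_B = 0, d_C = 0.01))
    f_tau <- nls_law(tau_act ~ t0 + c_act * exp(-k_act * W),
                     start = list(t0 = 1, c_act = 10, k_act = 20),
                     lower = c(0, 0, 0.1), upper = c(10, 100, 200))
    f_aact <- nls_law(A_act ~ a_0 + (a_min - 1) / (1 + (W_half / W)^2),
                      start = list(a_0 = 1, a_min = 0.5, W_half = 0.4),
                      lower = c(0, 0, 0.01), upper = c(3, 1, 1))
    f_a1 <- nls_law(A_inact_1 ~ b_0 + b_1 / (b_2 + (W - W_inact)^2),
                    start = list(b_0 = 0.15, b_1 = 0.01, b_2 = 0.03,
                                 W_inact = 0.1),
                    lower = c(0, 1e-5, 1e-4, 0), upper = c(1, 1, 1, 1))
    f_a2 <- if (is.null(fix_k_inact)) {
      nls_law(A_inact_2 ~ c_inact * exp(-k_inact * W),
              start = list(c_inact = 0.3, k_inact = 2),
              lower = c(0, 0.01), upper = c(2, 50))
    } else {
      k_i <- fix_k_inact
      nls_law(A_inact_2 ~ c_inact * exp(-k_i * W),
              start = list(c_inact = 0.3), lower = 0, upper = 2)
    }
    fits <- list(latency = f_d, tau_act = f_tau, A_act = f_aact,
                 A_inact_1 = f_a1, A_inact_2 = f_a2)
    if (any(vapply(fits, is.null, logical(1)))) {
      failed <- names(fits)[vapply(fits, is.null, logical(1))]
      stop("stage B (intensity laws) failed to converge for: ",
           paste(failed, collapse = ", "))
    }
    co <- function(f) as.list(stats::coef(f))
    out$stage_b <- list(
      latency = co(f_d), tau_act = co(f_tau), A_act = co(f_aact),
      A_inact_1 = co(f_a1),
      A_inact_2 = c(co(f_a2),
                    if (!is.null(fix_k_inact)) list(k_inact = fix_k_inact)))
  }
  structure(out, class = "chr2_fit")
}

#' @export
print.chr2_fit <- function(x, ...) {
  cat("ChR2 model fit\n")
  cat(sprintf("  shared: tau_inact_1 = %.3f ms, tau_inact_2 = %.2f ms\n",
              x$tau_inact_1, x$tau_inact_2))
  cat(sprintf("  rss = %.4g over %d intensities; converged: %s\n",
              x$rss, nrow(x$per_intensity), x$converged))
  print(x$per_intensity, digits = 4)
  if (is.character(x$stage_b)) cat("  stage B:", x$stage_b, "\n")
  invisible(x)
}
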