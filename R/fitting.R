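# Decay-phase and full-profile fitting of PSC traces.
#
# All decay fits operate on the magnitude of the baseline-subtracted
# current (inward currents are sign-flipped first) so amplitudes are
# positive during optimization; the orientation is recorded and restored
# on output. Nonlinear least squares uses minpack.lm's Levenberg-Marquardt
# with box constraints.

#' Root-mean-square error between two equal-length sequences
#'
#' @param model_values,data_values numeric vectors of equal length.
#' @return `sqrt(mean((model - data)^2))`, in trace units.
#' @export
rmse <- function(model_values, data_values) {
  if (length(model_values) != length(data_values))
    stop("length mismatch in rmse", call. = FALSE)
  if (length(model_values) < 1) stop("empty sequences in rmse", call. = FALSE)
  sqrt(mean((model_values - data_values)^2))
}

#' Fit window
#'
#' Time window (ms) restricting a decay fit; both ends must lie within the
#' trace passed to the fitting function.
#'
#' @param start,end window bounds (ms), `start < end`.
#' @return a `fit_window` object.
#' @export
fit_window <- function(start, end) {
  stopifnot(is.finite(start), is.finite(end))
  if (start >= end) stop("window start must precede end", call. = FALSE)
  structure(list(start = start, end = end), class = "fit_window")
}

#' Default decay window for a trace: detected peak to last sample
#'
#' @param trace a [sampled_trace()] with `stim_time` set.
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @return a [fit_window()].
#' @export
default_decay_window <- function(trace, baseline_ms = 10) {
  pk <- detect_peak(trace, baseline_ms)
  fit_window(pk$time, trace$times[length(trace$times)])
}

# window selection + orientation for the decay fits; returns times relative
# to window start, positive magnitudes and metadata
.decay_data <- function(trace, w, baseline_ms = 10) {
  stopifnot(inherits(trace, "sampled_trace"), inherits(w, "fit_window"))
  if (w$start < trace$times[1] || w$end > trace$times[length(trace$times)])
    stop("window outside trace span", call. = FALSE)
  b <- if (is.null(trace$stim_time)) 0 else trace_baseline(trace, baseline_ms)
  sel <- trace$times >= w$start & trace$times <= w$end
  if (sum(sel) < 4) stop("too few samples in fit window", call. = FALSE)
  y <- trace$values[sel] - b
  orient <- if (sum(y) < 0) -1 else 1
  list(t = trace$times[sel] - w$start, y = orient * y,
       times = trace$times[sel], baseline = b, orientation = orient)
}

.nls_fit <- function(residual_fn, start, lower, upper,
                     maxiter = 200, ptol = 1e-12, ftol = 1e-12) {
  minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                     fn = residual_fn,
                     control = minpack.lm::nls.lm.control(
                       maxiter = maxiter, ptol = ptol, ftol = ftol))
}

#' Mono-exponential decay fit
#'
#' Least-squares fit of \eqn{A e^{-(t - t_w)/\tau}} to the trace on the
#' window (times measured from the window start), on the magnitude of the
#' baseline-subtracted current.
#'
#' @param trace a [sampled_trace()].
#' @param w a [fit_window()] starting at or after the trace peak; defaults
#'   to [default_decay_window()].
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @return a `decay_fit_mono` list: `amplitude`, `tau_decay` (ms),
#'   `baseline`, `rmse`, `orientation`, `window`, `fitted` (reconstructed
#'   model values in original orientation, baseline excluded).
#' @export
fit_mono_decay <- function(trace, w = NULL, baseline_ms = 10) {
  if (is.null(w)) w <- default_decay_window(trace, baseline_ms)
  d <- .decay_data(trace, w, baseline_ms)
  a0 <- max(d$y[1], max(d$y) / 2, 1e-12)
  # crude 1/e crossing for the initial time constant
  below <- which(d$y <= a0 / exp(1))
  tau0 <- if (length(below)) max(d$t[below[1]], d$t[2]) else max(d$t) / 2
  fit <- .nls_fit(function(p) p[1] * exp(-d$t / p[2]) - d$y,
                  start = c(A = a0, tau = tau0),
                  lower = c(1e-12, 1e-6), upper = c(Inf, Inf))
  if (fit$info == 0 || fit$info == 9)
    stop("mono-exponential fit did not converge: ", fit$message,
         call. = FALSE)
  p <- fit$par
  model <- p[[1]] * exp(-d$t / p[[2]])
  structure(list(amplitude = p[[1]], tau_decay = p[[2]],
                 baseline = d$baseline, rmse = rmse(model, d$y),
                 orientation = d$orientation, window = w,
                 times = d$times, fitted = d$orientation * model),
            class = "decay_fit_mono")
}

#' Double-exponential decay fit
#'
#' Least-squares fit of
#' \eqn{I_f e^{-(t-t_w)/\tau_f} + I_s e^{-(t-t_w)/\tau_s}} on the window,
#' with three seeded starts (fast-dominant, slow-dominant, balanced) to
#' mitigate local minima. Components are relabeled after fitting so
#' `tau_f <= tau_s` (ties broken by labeling the larger amplitude fast);
#' the weighted mean time constant `tau_w` is derived via
#' [weighted_tau()]. Fits with `tau_f` within 1\% of `tau_s` are flagged
#' `degenerate`.
#'
#' @inheritParams fit_mono_decay
#' @return a `decay_fit_double` list: `i_f`, `i_s`, `tau_f`, `tau_s`,
#'   `tau_w`, `baseline`, `rmse`, `degenerate`, `orientation`, `window`,
#'   `fitted`.
#' @export
fit_double_decay <- function(trace, w = NULL, baseline_ms = 10) {
  if (is.null(w)) w <- default_decay_window(trace, baseline_ms)
  d <- .decay_data(trace, w, baseline_ms)
  a0 <- max(d$y[1], max(d$y), 1e-12)
  span <- max(d$t)
  mono_tau <- tryCatch(fit_mono_decay(trace, w, baseline_ms)$tau_decay,
                       error = function(e) span / 3)
  starts <- list(
    c(If = 0.8 * a0, Is = 0.2 * a0, tf = mono_tau / 3, ts = mono_tau * 2),
    c(If = 0.2 * a0, Is = 0.8 * a0, tf = mono_tau / 5, ts = mono_tau * 4),
    c(If = 0.5 * a0, Is = 0.5 * a0, tf = mono_tau / 2, ts = mono_tau * 1.5))
  resid <- function(p) p[1] * exp(-d$t / p[3]) + p[2] * exp(-d$t / p[4]) - d$y
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      .nls_fit(resid, start = s, lower = c(0, 0, 1e-6, 1e-6),
               upper = rep(Inf, 4)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info == 0 || fit$info == 9) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("double-exponential fit did not converge from any start",
         call. = FALSE)
  p <- best$par
  if (p[[3]] <= p[[4]]) {
    i_f <- p[[1]]; i_s <- p[[2]]; tau_f <- p[[3]]; tau_s <- p[[4]]
  } else {
    i_f <- p[[2]]; i_s <- p[[1]]; tau_f <- p[[4]]; tau_s <- p[[3]]
  }
  if (tau_f == tau_s && i_f < i_s) {  # tie: larger amplitude labeled fast
    tmp <- i_f; i_f <- i_s; i_s <- tmp
  }
  model <- i_f * exp(-d$t / tau_f) + i_s * exp(-d$t / tau_s)
  structure(list(
    i_f = i_f, i_s = i_s, tau_f = tau_f, tau_s = tau_s,
    tau_w = if (i_f + i_s > 0) weighted_tau(i_f, i_s, tau_f, tau_s) else NA,
    baseline = d$baseline, rmse = rmse(model, d$y),
    degenerate = abs(tau_s - tau_f) / tau_s < 0.01,
    orientation = d$orientation, window = w,
    times = d$times, fitted = d$orientation * model),
    class = "decay_fit_double")
}

#' Full tri-exponential model fit (rise plus fast and slow decay)
#'
#' Fits the complete normalized conductance profile to the post-stimulus
#' trace: free parameters are the rise constant `tau_r`, the two decay
#' constants, the slow amplitude fraction (fractions constrained to sum to
#' one, since the profile is invariant under common rescaling of the
#' amplitude pair) and the peak amplitude. The decay constants are
#' parameterized as offsets (`tau_f = tau_r + d1`, `tau_s = tau_f + d2`)
#' so the ordering `tau_r < tau_f <= tau_s` holds throughout the search.
#' Every residual evaluation solves the peak time by Newton's method.
#'
#' @param trace a [sampled_trace()] with `stim_time` set.
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @param settings [newton_settings()] used for the peak solves.
#' @return a `full_fit` list: `kinetics` (a [triexp_kinetics()] with
#'   unit-sum fractions and `gbar` = fitted peak amplitude in trace
#'   units), `peak` (the `newton_result` at the solution), `rmse` over the
#'   full post-stimulus window, `baseline`, `orientation`, `fitted`.
#' @export
fit_full_model <- function(trace, baseline_ms = 10,
                           settings = newton_settings()) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (is.null(trace$stim_time)) stop("stim_time not set", call. = FALSE)
  b <- trace_baseline(trace, baseline_ms)
  sel <- trace$times >= trace$stim_time
  tt <- trace$times[sel]
  y <- trace$values[sel] - b
  orient <- if (sum(y) < 0) -1 else 1
  y <- orient * y
  pk <- detect_peak(trace, baseline_ms)
  amp0 <- abs(pk$amplitude)
  # seed decay constants and fractions from a double fit on the decay limb
  dw <- fit_window(pk$time, tt[length(tt)])
  dd <- tryCatch(fit_double_decay(trace, dw, baseline_ms),
                 error = function(e) NULL)
  tau_r0 <- max((pk$time - trace$stim_time) / 3, trace$dt)
  if (!is.null(dd) && dd$i_f + dd$i_s > 0) {
    tau_f0 <- dd$tau_f; tau_s0 <- dd$tau_s
    fs0 <- min(max(dd$i_s / (dd$i_f + dd$i_s), 0.05), 0.95)
  } else {
    tau_f0 <- tau_r0 * 4; tau_s0 <- tau_f0 * 5; fs0 <- 0.5
  }
  tau_r0 <- min(tau_r0, tau_f0 * 0.8)
  start <- c(tr = tau_r0, d1 = max(tau_f0 - tau_r0, 1e-3),
             d2 = max(tau_s0 - tau_f0, 1e-3), fs = fs0, amp = amp0)
  profile <- function(p) {
    tr <- p[[1]]; tf <- tr + p[[2]]; ts <- tf + p[[3]]
    fs <- p[[4]]
    k <- triexp_kinetics(tr, tf, ts, i_f = 1 - fs, i_s = fs, gbar = 1,
                         t0 = trace$stim_time)
    tp <- newton_peak_time(k, settings)
    p[[5]] * triexp_conductance(k, tt, tp$t_peak, check = FALSE)
  }
  fit <- .nls_fit(function(p) {
    m <- tryCatch(profile(p), error = function(e) NULL)
    if (is.null(m) || any(!is.finite(m))) return(rep(1e6, length(y)))
    m - y
  },
  start = start,
  lower = c(trace$dt / 100, 1e-4, 0, 1e-6, 0),
  upper = c(Inf, Inf, Inf, 1 - 1e-6, Inf),
  maxiter = 400)
  if (fit$info == 0 || fit$info == 9)
    stop("full-model fit did not converge: ", fit$message, call. = FALSE)
  p <- fit$par
  k <- triexp_kinetics(p[[1]], p[[1]] + p[[2]], p[[1]] + p[[2]] + p[[3]],
                       i_f = 1 - p[[4]], i_s = p[[4]], gbar = p[[5]],
                       t0 = trace$stim_time)
  peak <- newton_peak_time(k, settings)
  model <- triexp_conductance(k, tt, peak$t_peak, check = FALSE)
  structure(list(kinetics = k, peak = peak, rmse = rmse(model, y),
                 baseline = b, orientation = orient,
                 times = tt, fitted = orient * model),
            class = "full_fit")
}

#' Compare mono, weighted and double decay fitting on one trace
#'
#' Runs the mono- and double-exponential decay fits on the window, then
#' derives the "weighted" method from the double fit: its fast and slow
#' components are collapsed to a single exponential with the weighted mean
#' time constant [weighted_tau()] and total amplitude `i_f + i_s`, and the
#' RMSE of that reconstructed profile is computed on the same window. A
#' method that fails to fit is reported with `NA` entries rather than
#' aborting the comparison.
#'
#' @inheritParams fit_mono_decay
#' @return a data.frame with one row per method (`mono`, `weighted`,
#'   `double`) and columns `method`, `rmse`, `tau_f`, `tau_s`, `tau_w`,
#'   `amplitude`, `error` (failure message or NA). The individual fit
#'   objects are attached as attribute `fits`.
#' @export
compare_methods <- function(trace, w = NULL, baseline_ms = 10) {
  if (is.null(w)) w <- default_decay_window(trace, baseline_ms)
  rows <- list()
  fits <- list()
  mono <- tryCatch(fit_mono_decay(trace, w, baseline_ms),
                   error = function(e) e)
  if (inherits(mono, "error")) {
    rows$mono <- data.frame(method = "mono", rmse = NA, tau_f = NA,
                            tau_s = NA, tau_w = NA, amplitude = NA,
                            error = conditionMessage(mono))
  } else {
    fits$mono <- mono
    rows$mono <- data.frame(method = "mono", rmse = mono$rmse,
                            tau_f = mono$tau_decay, tau_s = NA, tau_w = NA,
                            amplitude = mono$amplitude, error = NA)
  }
  dbl <- tryCatch(fit_double_decay(trace, w, baseline_ms),
                  error = function(e) e)
  if (inherits(dbl, "error")) {
    msg <- conditionMessage(dbl)
    rows$weighted <- data.frame(method = "weighted", rmse = NA, tau_f = NA,
                                tau_s = NA, tau_w = NA, amplitude = NA,
                                error = msg)
    rows$double <- data.frame(method = "double", rmse = NA, tau_f = NA,
                              tau_s = NA, tau_w = NA, amplitude = NA,
                              error = msg)
  } else {
    fits$double <- dbl
    d <- .decay_data(trace, w, baseline_ms)
    wmodel <- (dbl$i_f + dbl$i_s) * exp(-d$t / dbl$tau_w)
    fits$weighted <- list(amplitude = dbl$i_f + dbl$i_s, tau_w = dbl$tau_w,
                          rmse = rmse(wmodel, d$y),
                          fitted = d$orientation * wmodel, times = d$times)
    rows$weighted <- data.frame(method = "weighted",
                                rmse = fits$weighted$rmse, tau_f = NA,
                                tau_s = NA, tau_w = dbl$tau_w,
                                amplitude = dbl$i_f + dbl$i_s, error = NA)
    rows$double <- data.frame(method = "double", rmse = dbl$rmse,
                              tau_f = dbl$tau_f, tau_s = dbl$tau_s,
                              tau_w = dbl$tau_w,
                              amplitude = dbl$i_f + dbl$i_s, error = NA)
  }
  out <- do.call(rbind, rows[c("mono", "weighted", "double")])
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
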