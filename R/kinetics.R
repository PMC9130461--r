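#' Bi-exponential synaptic conductance kinetics
#'
#' Classical two-exponential conductance profile
#' \deqn{g(t) = \bar g K (e^{-(t-t_0)/\tau_{decay}} - e^{-(t-t_0)/\tau_{rise}})}
#' with one rising and one decaying exponential. The peak time and the
#' normalization factor \eqn{K} have closed forms (see
#' [biexp_peak_time()], [biexp_norm_factor()]).
#'
#' Units follow NEURON mechanism conventions: time in ms, conductance in
#' microsiemens (uS).
#'
#' @param tau_rise rise time constant (ms), > 0.
#' @param tau_decay decay time constant (ms), must exceed `tau_rise` unless
#'   `equal_tau = "limit"`.
#' @param gbar peak conductance (uS), >= 0.
#' @param t0 presynaptic spike time (ms).
#' @param equal_tau how to treat `tau_rise == tau_decay`: `"error"` (default)
#'   rejects it; `"limit"` switches to the analytic alpha-function limit
#'   \eqn{g \propto (t-t_0) e^{-(t-t_0)/\tau}}.
#' @return an object of class `biexp_kinetics`.
#' @export
biexp_kinetics <- function(tau_rise, tau_decay, gbar = 1, t0 = 0,
                           equal_tau = c("error", "limit")) {
  equal_tau <- match.arg(equal_tau)
  stopifnot(is.finite(tau_rise), is.finite(tau_decay), is.finite(gbar),
            is.finite(t0))
  if (tau_rise <= 0 || tau_decay <= 0)
    stop("time constants must be positive", call. = FALSE)
  if (gbar < 0) stop("gbar must be nonnegative", call. = FALSE)
  if (tau_decay < tau_rise)
    stop("tau_decay must be >= tau_rise", call. = FALSE)
  if (tau_decay == tau_rise && equal_tau == "error")
    stop("degenerate kinetics: tau_decay == tau_rise (set equal_tau = \"limit\" ",
         "to use the alpha-function limit)", call. = FALSE)
  structure(
    list(tau_rise = tau_rise, tau_decay = tau_decay, gbar = gbar, t0 = t0,
         equal_tau = equal_tau),
    class = "biexp_kinetics")
}

#' Tri-exponential synaptic conductance kinetics
#'
#' The conductance profile with one rising exponential and a fast plus a
#' slow decay component:
#' \deqn{g(t) = \bar g K (I_f e^{-(t-t_0)/\tau_f} + I_s e^{-(t-t_0)/\tau_s}
#'   - \tilde K e^{-(t-t_0)/\tau_r})}
#' where \eqn{\tilde K = I_f + I_s} makes the profile start at zero at
#' \eqn{t_0}. The peak time has no closed form; it is computed numerically
#' by [newton_peak_time()].
#'
#' Amplitude fractions are stored un-normalized; \eqn{\tilde K} is always
#' recomputed as `i_f + i_s`, never stored.
#'
#' @param tau_r rise time constant (ms); must satisfy `0 < tau_r < tau_f`.
#' @param tau_f fast decay time constant (ms).
#' @param tau_s slow decay time constant (ms); `tau_f <= tau_s`.
#' @param i_f,i_s nonnegative amplitude fractions of the fast and slow decay
#'   components; `i_f + i_s` must be positive.
#' @param gbar peak conductance (uS).
#' @param t0 presynaptic spike time (ms).
#' @return an object of class `triexp_kinetics`.
#' @export
triexp_kinetics <- function(tau_r, tau_f, tau_s, i_f, i_s, gbar = 1, t0 = 0) {
  stopifnot(is.finite(tau_r), is.finite(tau_f), is.finite(tau_s),
            is.finite(i_f), is.finite(i_s), is.finite(gbar), is.finite(t0))
  if (tau_r <= 0) stop("tau_r must be positive", call. = FALSE)
  if (!(tau_r < tau_f)) stop("need tau_r < tau_f", call. = FALSE)
  if (!(tau_f <= tau_s)) stop("need tau_f <= tau_s", call. = FALSE)
  if (i_f < 0 || i_s < 0) stop("amplitude fractions must be >= 0", call. = FALSE)
  if (i_f + i_s <= 0) stop("i_f + i_s must be positive", call. = FALSE)
  if (gbar < 0) stop("gbar must be nonnegative", call. = FALSE)
  structure(
    list(tau_r = tau_r, tau_f = tau_f, tau_s = tau_s,
         i_f = i_f, i_s = i_s, gbar = gbar, t0 = t0),
    class = "triexp_kinetics")
}

#' Magnesium block parameters
#'
#' Voltage-dependent Mg2+ block of the NMDA receptor,
#' \deqn{Mg(V) = 1 / (1 + e^{-aV} [Mg^{2+}]/b).}
#' Defaults are the classical Jahr--Stevens constants (a = 0.062/mV,
#' b = 3.57 mM at 1 mM extracellular Mg2+). These are assumptions the user
#' should override when a corrected parameterization is preferred.
#'
#' @param a voltage-sensitivity constant (1/mV), > 0.
#' @param b concentration constant (mM), > 0.
#' @param mg_conc extracellular Mg2+ concentration (mM), >= 0.
#' @return an object of class `mg_block_params`.
#' @export
mg_block_params <- function(a = 0.062, b = 3.57, mg_conc = 1) {
  stopifnot(is.finite(a), is.finite(b), is.finite(mg_conc))
  if (a <= 0 || b <= 0) stop("a and b must be positive", call. = FALSE)
  if (mg_conc < 0) stop("mg_conc must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, mg_conc = mg_conc), class = "mg_block_params")
}

#' Synapse model: kinetics plus reversal potential, optionally Mg block
#'
#' Couples a conductance kinetics object with a reversal potential and, for
#' NMDA-type synapses, a magnesium block. A model without `mg` is
#' AMPA-type: \eqn{I = g (V - E_{syn})}. With `mg` it is NMDA-type:
#' \eqn{I = g\, Mg(V) (V - E_{syn})}.
#'
#' @param kinetics a `biexp_kinetics` or `triexp_kinetics` object.
#' @param e_rev reversal potential (mV).
#' @param mg optional `mg_block_params`; presence marks the synapse NMDA-type.
#' @return an object of class `synapse_model`.
#' @export
synapse_model <- function(kinetics, e_rev = 0, mg = NULL) {
  if (!inherits(kinetics, c("biexp_kinetics", "triexp_kinetics")))
    stop("kinetics must be biexp_kinetics or triexp_kinetics", call. = FALSE)
  if (!is.null(mg) && !inherits(mg, "mg_block_params"))
    stop("mg must be NULL or mg_block_params", call. = FALSE)
  stopifnot(is.finite(e_rev))
  structure(list(kinetics = kinetics, e_rev = e_rev, mg = mg),
            class = "synapse_model")
}

#' Peak time of the bi-exponential conductance (closed form)
#'
#' \deqn{t_{peak} = t_0 + \frac{\tau_{decay}\tau_{rise}}
#'   {\tau_{decay}-\tau_{rise}} \ln(\tau_{decay}/\tau_{rise})}
#' In the alpha-function limit (`equal_tau = "limit"`,
#' `tau_rise == tau_decay == tau`) the peak is at `t0 + tau`.
#'
#' @param k a `biexp_kinetics` object.
#' @return peak time (ms), strictly greater than `t0`.
#' @export
biexp_peak_time <- function(k) {
  stopifnot(inherits(k, "biexp_kinetics"))
  if (k$tau_decay == k$tau_rise) return(k$t0 + k$tau_rise)
  k$t0 + (k$tau_decay * k$tau_rise / (k$tau_decay - k$tau_rise)) *
    log(k$tau_decay / k$tau_rise)
}

#' Normalization factor of the bi-exponential conductance (closed form)
#'
#' The constant \eqn{K} such that the profile evaluated at its peak equals
#' `gbar`:
#' \deqn{K = 1 / (e^{-(t_{peak}-t_0)/\tau_{decay}} -
#'   e^{-(t_{peak}-t_0)/\tau_{rise}})}
#'
#' @param k a `biexp_kinetics` object.
#' @return dimensionless scalar, always > 1 for valid kinetics.
#' @export
biexp_norm_factor <- function(k) {
  stopifnot(inherits(k, "biexp_kinetics"))
  x <- biexp_peak_time(k) - k$t0
  if (k$tau_decay == k$tau_rise) {
    # alpha-function profile (x/tau) e^{-x/tau} peaks at tau with value 1/e
    return(exp(1))
  }
  1 / (exp(-x / k$tau_decay) - exp(-x / k$tau_rise))
}

#' Evaluate the bi-exponential conductance profile
#'
#' Returns zero for `t < t0` (causality); from `t0` onward evaluates the
#' normalized double-exponential profile, which reaches exactly `gbar` at
#' the closed-form peak time.
#'
#' @param k a `biexp_kinetics` object.
#' @param t time or vector of times (ms).
#' @return conductance (uS), same length as `t`.
#' @export
biexp_conductance <- function(k, t) {
  stopifnot(inherits(k, "biexp_kinetics"))
  x <- t - k$t0
  g <- numeric(length(x))
  on <- x > 0
  if (any(on)) {
    if (k$tau_decay == k$tau_rise) {
      tau <- k$tau_rise
      g[on] <- k$gbar * (x[on] / tau) * exp(1 - x[on] / tau)
    } else {
      K <- biexp_norm_factor(k)
      g[on] <- k$gbar * K *
        (exp(-x[on] / k$tau_decay) - exp(-x[on] / k$tau_rise))
    }
  }
  g
}

#' Normalization factor of the tri-exponential conductance
#'
#' The constant \eqn{K} such that the tri-exponential profile evaluated at
#' the numerically computed peak time equals `gbar`:
#' \deqn{K = 1 / (I_f e^{-(t_{peak}-t_0)/\tau_f} +
#'   I_s e^{-(t_{peak}-t_0)/\tau_s} - \tilde K e^{-(t_{peak}-t_0)/\tau_r})}
#'
#' @param k a `triexp_kinetics` object.
#' @param t_peak peak time (ms) as returned by [newton_peak_time()] for the
#'   same kinetics.
#' @return dimensionless scalar.
#' @export
triexp_norm_factor <- function(k, t_peak) {
  stopifnot(inherits(k, "triexp_kinetics"))
  x <- t_peak - k$t0
  ktilde <- k$i_f + k$i_s
  den <- k$i_f * exp(-x / k$tau_f) + k$i_s * exp(-x / k$tau_s) -
    ktilde * exp(-x / k$tau_r)
  if (!is.finite(den) || den <= 0)
    stop("invalid t_peak: normalization denominator is not positive",
         call. = FALSE)
  1 / den
}

#' Evaluate the tri-exponential conductance profile
#'
#' Requires the peak time solved by [newton_peak_time()] (or
#' [fallback_peak_time()]) for the same kinetics; the profile is normalized
#' so that it equals `gbar` there. The supplied `t_peak` is checked against
#' the stationarity condition of the profile's derivative and rejected if
#' it is not a stationary point.
#'
#' @param k a `triexp_kinetics` object.
#' @param t time or vector of times (ms).
#' @param t_peak solved peak time (ms). If missing it is computed.
#' @param check verify the stationarity residual of `t_peak` (default TRUE).
#' @return conductance (uS), zero before `t0`.
#' @export
triexp_conductance <- function(k, t, t_peak = NULL, check = TRUE) {
  stopifnot(inherits(k, "triexp_kinetics"))
  if (is.null(t_peak)) {
    t_peak <- newton_peak_time(k)$t_peak
  } else if (check) {
    r <- stationarity_residual(k, t_peak)
    if (!is.finite(r) || r > 1e-6)
      stop("supplied t_peak is not a stationary point of the conductance ",
           "profile (relative residual ", signif(r, 3), ")", call. = FALSE)
  }
  K <- triexp_norm_factor(k, t_peak)
  x <- t - k$t0
  ktilde <- k$i_f + k$i_s
  g <- numeric(length(x))
  on <- x > 0
  g[on] <- k$gbar * K *
    (k$i_f * exp(-x[on] / k$tau_f) + k$i_s * exp(-x[on] / k$tau_s) -
       ktilde * exp(-x[on] / k$tau_r))
  g
}

#' Amplitude-weighted mean decay time constant
#'
#' \deqn{\tau_w = \frac{I_f}{I_f+I_s}\tau_f + \frac{I_s}{I_f+I_s}\tau_s}
#' The conventional collapse of a double-exponential decay to a single
#' time constant; always lies between `tau_f` and `tau_s`.
#'
#' @param i_f,i_s nonnegative amplitudes; their sum must be positive.
#' @param tau_f,tau_s decay time constants (ms).
#' @return weighted time constant (ms).
#' @export
weighted_tau <- function(i_f, i_s, tau_f, tau_s) {
  if (i_f + i_s <= 0) stop("i_f + i_s must be positive", call. = FALSE)
  (i_f * tau_f + i_s * tau_s) / (i_f + i_s)
}

#' Voltage-dependent magnesium block fraction
#'
#' \deqn{Mg(V) = \frac{1}{1 + e^{-aV}\,[Mg^{2+}]/b}}
#' Bounded in (0, 1], monotone nondecreasing in `v`, identically 1 when
#' `mg_conc = 0`.
#'
#' @param p an `mg_block_params` object.
#' @param v membrane potential (mV), scalar or vector.
#' @return unblocked fraction in (0, 1].
#' @export
mg_block <- function(p, v) {
  stopifnot(inherits(p, "mg_block_params"))
  1 / (1 + exp(-p$a * v) * (p$mg_conc / p$b))
}

#' Synaptic current from conductance and membrane potential
#'
#' AMPA-type: \eqn{I = g (V - E_{syn})}; NMDA-type additionally scales by
#' the magnesium block, \eqn{I = g\,Mg(V) (V - E_{syn})}. With conductance
#' in uS and potentials in mV the current is in nA; holding at -70 mV with
#' `e_rev = 0` gives negative (inward) current.
#'
#' @param m a `synapse_model` object.
#' @param g conductance (uS), scalar or vector, >= 0.
#' @param v membrane potential (mV), scalar or vector.
#' @return current (nA).
#' @export
synaptic_current <- function(m, g, v) {
  stopifnot(inherits(m, "synapse_model"))
  i <- g * (v - m$e_rev)
  if (!is.null(m$mg)) i <- i * mg_block(m$mg, v)
  i
}

#' Evaluate a synapse model's current time course
#'
#' Convenience wrapper: evaluates the model's conductance profile at times
#' `t` and converts to current at holding potential `v`.
#'
#' @param m a `synapse_model` object.
#' @param t times (ms).
#' @param v holding potential (mV).
#' @return current (nA) at each time.
#' @export
model_current <- function(m, t, v) {
  g <- if (inherits(m$kinetics, "triexp_kinetics")) {
    triexp_conductance(m$kinetics, t)
  } else {
    biexp_conductance(m$kinetics, t)
  }
  synaptic_current(m, g, v)
}

#' Read/write flat key-value kinetics configuration
#'
#' Parameter sets serialize to a flat `key = value` text format with keys
#' `tau_r, tau_f, tau_s, i_f, i_s, gbar, t0, e_rev, mg_a, mg_b, mg_conc`
#' (bi-exponential sets use `tau_rise, tau_decay, gbar, t0` instead of the
#' tri-exponential keys). Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_kinetics_config`: a named numeric vector of the keys found.
#' @export
read_kinetics_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric config value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  stats::setNames(vals, keys)
}

#' @rdname read_kinetics_config
#' @param params named numeric vector or list of parameter values.
#' @export
write_kinetics_config <- function(params, path) {
  params <- unlist(params)
  writeLines(sprintf("%s = %.17g", names(params), as.numeric(params)), path)
  invisible(path)
}

#' Build a kinetics object from a flat config vector
#'
#' Recognizes tri-exponential sets by the presence of `tau_f`/`tau_s` keys
#' and bi-exponential sets by `tau_rise`/`tau_decay`.
#'
#' @param cfg named numeric vector as returned by [read_kinetics_config()].
#' @return a `biexp_kinetics` or `triexp_kinetics` object.
#' @export
kinetics_from_config <- function(cfg) {
  get0 <- function(key, default = NULL) {
    if (key %in% names(cfg)) unname(cfg[[key]]) else default
  }
  if (all(c("tau_f", "tau_s") %in% names(cfg))) {
    triexp_kinetics(tau_r = get0("tau_r"), tau_f = get0("tau_f"),
                    tau_s = get0("tau_s"), i_f = get0("i_f", 1),
                    i_s = get0("i_s", 0), gbar = get0("gbar", 1),
                    t0 = get0("t0", 0))
  } else if (all(c("tau_rise", "tau_decay") %in% names(cfg))) {
    biexp_kinetics(tau_rise = get0("tau_rise"), tau_decay = get0("tau_decay"),
                   gbar = get0("gbar", 1), t0 = get0("t0", 0))
  } else {
    stop("config does not define a recognizable kinetics set ",
         "(need tau_f+tau_s or tau_rise+tau_decay)", call. = FALSE)
  }
}
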