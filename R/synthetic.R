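# Seeded synthetic PSC generator emulating voltage-clamp acquisition:
# model current on a uniform 10-20 kHz grid, optional first-order low-pass
# (acquisition anti-alias filtering), additive Gaussian noise. Every
# random draw flows through the explicit seed.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-trace generator specification
#'
#' Describes one simulated voltage-clamp recording: the synapse model,
#' holding potential, sampling rate (10--20 kHz typical of PSC
#' acquisition), duration, additive Gaussian noise level and an optional
#' first-order low-pass corner emulating acquisition filtering (2 kHz
#' typical).
#'
#' @param model a [synapse_model()]; its kinetics `t0` is the stimulation
#'   time and is carried into the generated trace.
#' @param holding_mV holding potential (mV).
#' @param sampling_khz sampling rate (kHz), > 0.
#' @param duration total trace duration (ms), > 0.
#' @param noise_sd additive Gaussian noise sd in trace units, >= 0.
#' @param seed integer seed controlling all randomness.
#' @param filter_khz optional low-pass corner frequency (kHz), or `NULL`
#'   for no filtering.
#' @param units `"pA"` (default; model nA scaled by 1000) or `"nA"`.
#' @return a `generator_spec` object.
#' @export
generator_spec <- function(model, holding_mV, sampling_khz = 10,
                           duration = 500, noise_sd = 0, seed = 1L,
                           filter_khz = NULL, units = c("pA", "nA")) {
  stopifnot(inherits(model, "synapse_model"))
  units <- match.arg(units)
  if (sampling_khz <= 0) stop("sampling_khz must be > 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(model = model, holding_mV = holding_mV,
                 sampling_khz = sampling_khz, duration = duration,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 filter_khz = filter_khz, units = units),
            class = "generator_spec")
}

.analytic_values <- function(spec) {
  dt <- 1 / spec$sampling_khz
  times <- seq(0, spec$duration, by = dt)
  i_na <- model_current(spec$model, times, spec$holding_mV)
  scale <- if (spec$units == "pA") 1000 else 1
  list(times = times, values = i_na * scale, dt = dt)
}

.lowpass1 <- function(x, dt_ms, corner_khz) {
  rc <- 1 / (2 * pi * corner_khz)          # ms, since corner in kHz
  alpha <- dt_ms / (rc + dt_ms)
  stats::filter(alpha * x, filter = 1 - alpha, method = "recursive",
                init = x[1] * 0)[seq_along(x)]
}

#' Generate one synthetic PSC trace
#'
#' Evaluates the model current at the holding potential on the uniform
#' sampling grid, optionally applies the first-order low-pass, and adds
#' seeded Gaussian noise. With `noise_sd = 0` and no filter the samples
#' equal the analytic model current exactly.
#'
#' @param spec a [generator_spec()].
#' @return list with `trace` (a [sampled_trace()]; `stim_time` is the
#'   model kinetics `t0`) and `truth` (the exact generating parameters).
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  a <- .analytic_values(spec)
  v <- a$values
  if (!is.null(spec$filter_khz))
    v <- as.numeric(.lowpass1(v, a$dt, spec$filter_khz))
  if (spec$noise_sd > 0)
    v <- v + .with_seed(spec$seed, stats::rnorm(length(v), 0, spec$noise_sd))
  tr <- sampled_trace(a$times, v, units_label = spec$units,
                      stim_time = spec$model$kinetics$t0)
  attr(tr, "holding_mV") <- spec$holding_mV
  list(trace = tr, truth = list(kinetics = spec$model$kinetics,
                                e_rev = spec$model$e_rev,
                                mg = spec$model$mg,
                                holding_mV = spec$holding_mV,
                                noise_sd = spec$noise_sd,
                                filter_khz = spec$filter_khz,
                                seed = spec$seed, units = spec$units))
}

#' Generate a paired -70/+40 mV recording with a known NMDA/AMPA ratio
#'
#' Emulates the paired-holding-potential protocol: the -70 mV trace is
#' the AMPA current plus the (heavily Mg-blocked) NMDA current, the
#' +40 mV trace is the sum of both components with the Mg block applied.
#' The NMDA peak conductance is rescaled so that the NMDA/AMPA ratio
#' computed by [nmda_ampa_ratio()] on the noiseless sampled traces equals
#' `target_ratio` exactly; noise per `spec_ampa$noise_sd` /
#' `spec_nmda$noise_sd` is then added on top.
#'
#' @param spec_ampa [generator_spec()] for the AMPA component; its
#'   `holding_mV` is the -70 mV-side potential.
#' @param spec_nmda [generator_spec()] for the NMDA component (model must
#'   include Mg-block parameters); its `holding_mV` is the +40 mV-side
#'   potential. Sampling, duration and units must match `spec_ampa`.
#' @param target_ratio desired NMDA/AMPA ratio, > 0.
#' @return list with `minus70` and `plus40` traces and `truth` (both
#'   kinetics, the NMDA scale applied, and `target_ratio`).
#' @export
generate_paired_cell <- function(spec_ampa, spec_nmda, target_ratio) {
  stopifnot(inherits(spec_ampa, "generator_spec"),
            inherits(spec_nmda, "generator_spec"))
  if (target_ratio <= 0) stop("target_ratio must be > 0", call. = FALSE)
  if (spec_ampa$sampling_khz != spec_nmda$sampling_khz ||
      spec_ampa$duration != spec_nmda$duration ||
      spec_ampa$units != spec_nmda$units)
    stop("paired specs must share sampling, duration and units",
         call. = FALSE)
  t0a <- spec_ampa$model$kinetics$t0
  t0n <- spec_nmda$model$kinetics$t0
  if (t0a != t0n) stop("paired specs must share the stimulation time",
                       call. = FALSE)
  v_minus <- spec_ampa$holding_mV
  v_plus <- spec_nmda$holding_mV
  scale_units <- if (spec_ampa$units == "pA") 1000 else 1
  dt <- 1 / spec_ampa$sampling_khz
  times <- seq(0, spec_ampa$duration, by = dt)
  ia_minus <- model_current(spec_ampa$model, times, v_minus) * scale_units
  ia_plus <- model_current(spec_ampa$model, times, v_plus) * scale_units
  in_minus <- model_current(spec_nmda$model, times, v_minus) * scale_units
  in_plus <- model_current(spec_nmda$model, times, v_plus) * scale_units
  mk <- function(values) sampled_trace(times, values, spec_ampa$units,
                                       stim_time = t0a)
  ratio_at <- function(s) {
    nmda_ampa_ratio(mk(ia_minus + s * in_minus),
                    mk(ia_plus + s * in_plus))$ratio
  }
  # ratio is monotone increasing in the NMDA scale; bracket then root-find
  hi <- 1
  while (ratio_at(hi) < target_ratio && hi < 1e8) hi <- hi * 4
  if (ratio_at(hi) < target_ratio)
    stop("cannot reach target_ratio with these kinetics", call. = FALSE)
  if (ratio_at(0) > target_ratio)
    stop("AMPA residual in the late window already exceeds the target ratio",
         call. = FALSE)
  s <- stats::uniroot(function(x) ratio_at(x) - target_ratio,
                      lower = 0, upper = hi, tol = 1e-12)$root
  noisy <- function(values, spec, seed_offset) {
    if (spec$noise_sd > 0)
      values <- values + .with_seed(spec$seed + seed_offset,
                                    stats::rnorm(length(values), 0,
                                                 spec$noise_sd))
    mk(values)
  }
  minus70 <- noisy(ia_minus + s * in_minus, spec_ampa, 0L)
  plus40 <- noisy(ia_plus + s * in_plus, spec_nmda, 1L)
  attr(minus70, "holding_mV") <- v_minus
  attr(plus40, "holding_mV") <- v_plus
  list(minus70 = minus70, plus40 = plus40,
       truth = list(ampa_kinetics = spec_ampa$model$kinetics,
                    nmda_kinetics = spec_nmda$model$kinetics,
                    nmda_scale = s, target_ratio = target_ratio))
}

#' Sample random physiological tri-exponential kinetics sets
#'
#' Draws kinetics spanning AMPA-like through NMDA-like ranges:
#' `tau_r` uniform on \[0.2, 5\] ms, `tau_f` on \[2, 60\] ms, `tau_s` on
#' \[60, 600\] ms, slow amplitude fraction on \[0.1, 0.9\] (fractions sum
#' to one). Draws violating `tau_r < tau_f` are rejected and redrawn, so
#' every returned set is valid.
#'
#' @param n number of sets.
#' @param seed integer seed.
#' @param t0 stimulation time (ms) given to every set.
#' @return list of [triexp_kinetics()] objects of length `n`.
#' @export
sample_physiological_kinetics <- function(n, seed = 1L, t0 = 0) {
  .with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        tau_r <- stats::runif(1, 0.2, 5)
        tau_f <- stats::runif(1, 2, 60)
        if (tau_r < tau_f) break
      }
      tau_s <- stats::runif(1, 60, 600)
      fs <- stats::runif(1, 0.1, 0.9)
      out[[i]] <- triexp_kinetics(tau_r, tau_f, tau_s,
                                  i_f = 1 - fs, i_s = fs,
                                  gbar = 1, t0 = t0)
    }
    out
  })
}

#' Parameter-recovery study over seeded synthetic traces
#'
#' Samples `n` kinetics sets from the physiological ranges of
#' [sample_physiological_kinetics()], generates one AMPA-type trace per
#' set and per noise level (noise sd expressed as a fraction of the
#' trace's peak magnitude), runs [fit_full_model()] on each, and
#' summarizes per-parameter recovery and Newton solver behavior.
#'
#' @param n kinetics sets per noise level.
#' @param seed integer seed for sampling, trace noise and fits.
#' @param noise_sd_grid numeric vector of noise levels as fractions of
#'   the peak (e.g. `c(0, 0.02)`).
#' @param sampling_khz,duration acquisition grid for the generated traces.
#' @param holding_mV,e_rev recording and reversal potentials (mV).
#' @return list with `summary` (data.frame: one row per noise level with
#'   median absolute relative errors of each parameter, fit failure
#'   count, and Newton iteration statistics) and `details` (per-fit
#'   data.frame of relative errors and iteration counts).
#' @export
recovery_suite <- function(n, seed = 1L, noise_sd_grid = c(0, 0.02),
                           sampling_khz = 10, duration = 500,
                           holding_mV = -70, e_rev = 0) {
  stopifnot(n >= 1)
  kin <- sample_physiological_kinetics(n, seed, t0 = 20)
  details <- list()
  for (nl in seq_along(noise_sd_grid)) {
    frac <- noise_sd_grid[nl]
    for (i in seq_len(n)) {
      k <- kin[[i]]
      k$gbar <- 5e-4                      # ~35 pA peak at -70 mV
      m <- synapse_model(k, e_rev = e_rev)
      spec0 <- generator_spec(m, holding_mV, sampling_khz, duration,
                              noise_sd = 0, seed = 1L)
      peak_abs <- max(abs(.analytic_values(spec0)$values))
      spec <- generator_spec(m, holding_mV, sampling_khz, duration,
                             noise_sd = frac * peak_abs,
                             seed = seed + 1000L * nl + i)
      tr <- generate_trace(spec)$trace
      fit <- tryCatch(fit_full_model(tr), error = function(e) NULL)
      rel <- function(est, true) abs(est - true) / abs(true)
      if (is.null(fit)) {
        details[[length(details) + 1]] <- data.frame(
          noise_frac = frac, set = i, failed = TRUE,
          tau_r = NA, tau_f = NA, tau_s = NA, i_f = NA, i_s = NA,
          newton_iterations = NA)
      } else {
        fk <- fit$kinetics
        details[[length(details) + 1]] <- data.frame(
          noise_frac = frac, set = i, failed = FALSE,
          tau_r = rel(fk$tau_r, k$tau_r),
          tau_f = rel(fk$tau_f, k$tau_f),
          tau_s = rel(fk$tau_s, k$tau_s),
          i_f = rel(fk$i_f, k$i_f),
          i_s = rel(fk$i_s, k$i_s),
          newton_iterations = fit$peak$iterations)
      }
    }
  }
  det <- do.call(rbind, details)
  summ <- do.call(rbind, lapply(split(det, det$noise_frac), function(d) {
    ok <- d[!d$failed, , drop = FALSE]
    data.frame(
      noise_frac = d$noise_frac[1],
      n = nrow(d), failures = sum(d$failed),
      med_rel_tau_r = stats::median(ok$tau_r),
      med_rel_tau_f = stats::median(ok$tau_f),
      med_rel_tau_s = stats::median(ok$tau_s),
      med_rel_i_f = stats::median(ok$i_f),
      med_rel_i_s = stats::median(ok$i_s),
      max_newton_iterations = max(ok$newton_iterations),
      frac_newton_le_5 = mean(ok$newton_iterations <= 5))
  }))
  rownames(summ) <- NULL
  list(summary = summ, details = det)
}
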