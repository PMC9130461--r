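# Independent oracles used across the suite. These evaluate the raw
# (un-normalized) conductance profiles directly so they share no code
# path with the solvers they check.

# un-normalized tri-exponential profile as a plain function of x = t - t0
raw_triexp_profile <- function(k) {
  ktilde <- k$i_f + k$i_s
  function(x) k$i_f * exp(-x / k$tau_f) + k$i_s * exp(-x / k$tau_s) -
    ktilde * exp(-x / k$tau_r)
}

# dense-grid argmax of the profile. Two-stage: a 20001-point coarse grid
# over (0, 20 tau_s] brackets the peak (the profile is unimodal, so the
# coarse argmax is within one coarse step of the true peak), then a dense
# grid at `step` inside that bracket, with one intermediate refinement if
# the bracket is too wide for a direct dense sweep.
grid_argmax_peak <- function(k, step = 1e-4) {
  prof <- raw_triexp_profile(k)
  lo <- 0
  hi <- 20 * k$tau_s
  repeat {
    xs <- seq(lo, hi, length.out = 20001)
    i <- which.max(prof(xs))
    lo <- xs[max(i - 1L, 1L)]
    hi <- xs[min(i + 1L, length(xs))]
    if ((hi - lo) / step <= 2e5) break
  }
  xs <- seq(lo, hi, by = step)
  k$t0 + xs[which.max(prof(xs))]
}

# brute-force argmax of the bi-exponential profile on a fine grid
grid_argmax_biexp <- function(tau_rise, tau_decay, step = 1e-5,
                              span = 10 * tau_decay) {
  xs <- seq(step, span, by = step)
  xs[which.max(exp(-xs / tau_decay) - exp(-xs / tau_rise))]
}

# synthetic trace directly from the analytic tri-exponential current,
# bypassing the generator (for tests of the generator itself)
analytic_current_trace <- function(k, holding_mV = -70, e_rev = 0,
                                   sampling_khz = 10, duration = 500,
                                   mg = NULL, units_scale = 1000) {
  times <- seq(0, duration, by = 1 / sampling_khz)
  g <- pscfit::triexp_conductance(k, times)
  i <- g * (holding_mV - e_rev)
  if (!is.null(mg)) i <- i * pscfit::mg_block(mg, holding_mV)
  pscfit::sampled_trace(times, i * units_scale, stim_time = k$t0)
}

representative_kinetics <- function(gbar = 1, t0 = 0) {
  pscfit::triexp_kinetics(2, 30, 200, 0.7, 0.3, gbar = gbar, t0 = t0)
}
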