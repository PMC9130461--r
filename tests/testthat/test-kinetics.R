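test_that("bi-exponential peak time matches the closed form and a grid search", {
  k <- biexp_kinetics(tau_rise = 1, tau_decay = 2)
  # 2*1/(2-1)*log(2) = 1.3862944
  expect_equal(biexp_peak_time(k), 2 * log(2), tolerance = 1e-12)
  expect_equal(biexp_peak_time(k), grid_argmax_biexp(1, 2), tolerance = 1e-4)
  # peak is always after the spike, including with a shifted onset
  k2 <- biexp_kinetics(0.5, 12, gbar = 2, t0 = 15)
  expect_gt(biexp_peak_time(k2), 15)
  expect_equal(biexp_peak_time(k2) - 15, grid_argmax_biexp(0.5, 12),
               tolerance = 1e-4)
})

test_that("bi-exponential normalization makes the profile reach gbar at the peak", {
  k <- biexp_kinetics(1, 2, gbar = 3.5)
  expect_equal(biexp_norm_factor(k), 4, tolerance = 1e-12)
  expect_equal(biexp_conductance(k, biexp_peak_time(k)), 3.5,
               tolerance = 1e-12)
  # K > 1 and normalization holds across random valid kinetics
  set.seed(11)
  for (i in 1:50) {
    tr <- runif(1, 0.1, 5)
    td <- tr + runif(1, 0.5, 100)
    gb <- runif(1, 0.1, 10)
    ki <- biexp_kinetics(tr, td, gbar = gb, t0 = runif(1, -5, 5))
    expect_gt(biexp_norm_factor(ki), 1)
    expect_equal(biexp_conductance(ki, biexp_peak_time(ki)), gb,
                 tolerance = 1e-12)
  }
})

test_that("bi-exponential conductance is causal, zero at onset, and vanishes late", {
  k <- biexp_kinetics(1, 8, gbar = 2, t0 = 10)
  expect_identical(biexp_conductance(k, c(0, 5, 9.999)), c(0, 0, 0))
  expect_identical(biexp_conductance(k, 10), 0)
  expect_lt(biexp_conductance(k, 10 + 2000), 1e-12)
  expect_true(all(biexp_conductance(k, seq(10, 100, by = 0.1)) >= 0))
})

test_that("equal rise and decay constants use the alpha-function limit only on opt-in", {
  expect_error(biexp_kinetics(2, 2), "degenerate")
  k <- biexp_kinetics(2, 2, gbar = 1.5, equal_tau = "limit")
  expect_equal(biexp_peak_time(k), 2)
  expect_equal(biexp_conductance(k, 2), 1.5, tolerance = 1e-12)
  # limit agrees with a nearly-degenerate regular profile
  k_near <- biexp_kinetics(2, 2 + 1e-8)
  expect_equal(biexp_peak_time(k_near), 2, tolerance = 1e-6)
})

test_that("tri-exponential profile is zero at onset, normalized at the peak, nonnegative", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample_physiological_kinetics(1, seed = i, t0 = runif(1, 0, 10))[[1]]
    k$gbar <- runif(1, 0.1, 10)
    nr <- newton_peak_time(k)
    g_on <- triexp_conductance(k, k$t0, nr$t_peak)
    expect_identical(g_on, 0)
    expect_equal(triexp_conductance(k, nr$t_peak, nr$t_peak), k$gbar,
                 tolerance = 1e-12)
    tgrid <- k$t0 + seq(0, 20 * k$tau_s, length.out = 500)
    expect_true(all(triexp_conductance(k, tgrid, nr$t_peak) >= -1e-15))
  }
})

test_that("tri-exponential model reduces exactly to the bi-exponential one", {
  k3 <- triexp_kinetics(1, 2, 2, i_f = 1, i_s = 0)
  k2 <- biexp_kinetics(1, 2)
  tp3 <- newton_peak_time(k3)$t_peak
  expect_equal(tp3, biexp_peak_time(k2), tolerance = 1e-10)
  expect_equal(triexp_norm_factor(k3, tp3), biexp_norm_factor(k2),
               tolerance = 1e-10)
  tt <- seq(0, 30, by = 0.01)
  expect_equal(triexp_conductance(k3, tt, tp3), biexp_conductance(k2, tt),
               tolerance = 1e-12)
  # tau_f = tau_s with both fractions positive also collapses to Eq-1 form
  k3b <- triexp_kinetics(1.5, 7, 7, i_f = 0.4, i_s = 0.6)
  k2b <- biexp_kinetics(1.5, 7)
  tpb <- newton_peak_time(k3b)$t_peak
  expect_equal(tpb, biexp_peak_time(k2b), tolerance = 1e-10)
  expect_equal(triexp_conductance(k3b, tt, tpb), biexp_conductance(k2b, tt),
               tolerance = 1e-12)
})

test_that("tri-exponential norm factor matches the grid-maximization oracle", {
  k <- representative_kinetics()
  tp <- newton_peak_time(k)$t_peak
  prof <- raw_triexp_profile(k)
  xs <- seq(1e-4, 20 * k$tau_s, by = 1e-3)
  expect_equal(triexp_norm_factor(k, tp), 1 / max(prof(xs)),
               tolerance = 1e-6)
  expect_error(triexp_norm_factor(k, k$t0), "not positive")
})

test_that("supplied non-stationary peak times are rejected", {
  k <- representative_kinetics()
  tp <- newton_peak_time(k)$t_peak
  expect_error(triexp_conductance(k, 5, tp * 2), "stationary")
  expect_silent(triexp_conductance(k, 5, tp))
})

test_that("weighted tau is the amplitude-weighted mean of the decay constants", {
  expect_equal(weighted_tau(1, 1, 10, 50), 30)
  expect_equal(weighted_tau(3, 1, 10, 50), 20)
  expect_equal(weighted_tau(1, 0, 10, 50), 10)
  expect_error(weighted_tau(0, 0, 10, 50), "positive")
  set.seed(4)
  for (i in 1:20) {
    i_f <- runif(1); i_s <- runif(1)
    tf <- runif(1, 1, 50); ts <- tf + runif(1, 0, 400)
    tw <- weighted_tau(i_f, i_s, tf, ts)
    expect_true(tw >= tf && tw <= ts)
  }
})

test_that("magnesium block is bounded, monotone, and trivial without magnesium", {
  p0 <- mg_block_params(mg_conc = 0)
  expect_identical(mg_block(p0, c(-120, -70, 0, 40)), rep(1, 4))
  p <- mg_block_params(a = 0.062, b = 3.57, mg_conc = 1)
  expect_equal(mg_block(p, 0), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  v <- seq(-150, 80, by = 1)
  mb <- mg_block(p, v)
  expect_true(all(mb > 0 & mb <= 1))
  expect_true(all(diff(mb) > 0))
  expect_lt(mg_block(p, -1e4), 1e-200)
})

test_that("synaptic current follows the driving force and the Mg block", {
  ka <- biexp_kinetics(1, 5, gbar = 1)
  ampa <- synapse_model(ka, e_rev = 0)
  expect_equal(synaptic_current(ampa, 1, -70), -70)
  expect_equal(synaptic_current(ampa, 0.5, 0), 0)
  nmda <- synapse_model(ka, e_rev = 0, mg = mg_block_params())
  for (v in c(-90, -70, -30, 0.5, 40))
    expect_lte(abs(synaptic_current(nmda, 1, v)),
               abs(synaptic_current(ampa, 1, v)))
})

test_that("kinetics configs round-trip through the flat key-value format", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_kinetics_config(
    c(tau_r = 2, tau_f = 30, tau_s = 200, i_f = 0.7, i_s = 0.3,
      gbar = 5e-4, t0 = 20), path)
  k <- kinetics_from_config(read_kinetics_config(path))
  expect_s3_class(k, "triexp_kinetics")
  expect_equal(k$tau_s, 200)
  expect_equal(k$gbar, 5e-4)
  # bi-exponential variant
  write_kinetics_config(c(tau_rise = 1, tau_decay = 6, gbar = 2), path)
  kb <- kinetics_from_config(read_kinetics_config(path))
  expect_s3_class(kb, "biexp_kinetics")
  expect_equal(kb$tau_decay, 6)
  writeLines("tau_r = fast", path)
  expect_error(read_kinetics_config(path), "non-numeric")
})

test_that("invalid kinetics parameters are rejected", {
  expect_error(triexp_kinetics(5, 3, 200, 0.7, 0.3), "tau_r < tau_f")
  expect_error(triexp_kinetics(1, 30, 20, 0.7, 0.3), "tau_f <= tau_s")
  expect_error(triexp_kinetics(1, 30, 200, 0, 0), "positive")
  expect_error(triexp_kinetics(1, 30, 200, -0.1, 0.5), ">= 0")
  expect_error(biexp_kinetics(-1, 2), "positive")
  expect_error(biexp_kinetics(3, 2), "tau_decay")
  expect_error(mg_block_params(a = -1), "positive")
})
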