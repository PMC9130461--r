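# pscfit

Conductance-based modeling and fitting of AMPA/NMDA postsynaptic
currents (PSCs) in which the decay phase keeps **both** exponential
components instead of collapsing them to a weighted mean time constant.

## The problem

Synaptic conductances are conventionally modeled with a double
exponential,

    g(t) = ḡ · K · ( e^{-(t-t0)/τ_decay} - e^{-(t-t0)/τ_rise} ),

whose peak time and normalization factor K have closed forms. Real PSC
decays — NMDA currents especially — are often better described by two
decay exponentials (fast τ_f, slow τ_s with amplitudes I_f, I_s). The
common workaround fits both but then collapses them to a single weighted
time constant τ_w = (I_f τ_f + I_s τ_s)/(I_f + I_s), which discards most
of the gained accuracy. `pscfit` instead keeps both components in the
conductance model,

    g(t) = ḡ · K · ( I_f e^{-(t-t0)/τ_f} + I_s e^{-(t-t0)/τ_s} - K̃ e^{-(t-t0)/τ_r} ),

with K̃ = I_f + I_s so the profile starts at zero. The price is that the
peak time t_peak (needed for the normalization K) no longer has a closed
form: it is the root of a transcendental equation, which the package
solves by a safeguarded Newton iteration with an analytic derivative and
a closed-form initial guess — quadratically convergent, machine
precision in fewer than six iterations.

The package is for electrophysiologists and modelers who fit
voltage-clamp PSC traces and export synapse mechanisms to NEURON: it
provides the kinetics models and the Newton solver, mono/weighted/double
decay fitting with RMSE comparison, full rise+decay model fitting,
NMDA/AMPA ratio analysis of paired −70/+40 mV recordings with QC rules,
a seeded synthetic-trace generator, and an NMODL mechanism-text emitter
with the solver outputs embedded as constants.

## Worked example

```r
library(pscfit)

# NMDA-like kinetics: 2 ms rise, 30/200 ms fast/slow decay, 70/30 split
k  <- triexp_kinetics(tau_r = 2, tau_f = 30, tau_s = 200,
                      i_f = 0.7, i_s = 0.3, gbar = 5e-4, t0 = 20)
pk <- newton_peak_time(k)
pk
#> Peak time: 26.408144303 ms (newton, 3 iterations, |last step| = 3.71e-13 ms,
#>   stationarity residual = 6.84e-16, converged: TRUE)
triexp_norm_factor(k, pk$t_peak)
#> [1] 1.226526
```

The peak occurs 6.41 ms after the spike; three Newton steps reach a
step size of 4e-13 ms. K = 1.2265 scales the profile so that its
maximum is exactly ḡ.

```r
# simulate a +40 mV recording at 10 kHz and compare decay-fitting methods
m   <- synapse_model(k, e_rev = 0)
tr  <- generate_trace(generator_spec(m, holding_mV = 40, sampling_khz = 10,
                                     duration = 600, noise_sd = 0, seed = 1))$trace
compare_methods(tr)
#>     method    rmse tau_f tau_s tau_w amplitude
#> 1     mono 0.87597 94.96    NA    NA     16.29
#> 2 weighted 1.40053    NA    NA 88.85     20.73
#> 3   double 0.03148 30.90 201.9 88.85     20.73
```

RMSE is in pA over the decay window. The double fit is ~28× more
accurate than the mono fit here, while the weighted collapse is *worse*
than mono — the motivation for keeping both decay components. Fitting
the full rise+decay model recovers the generating parameters to
machine precision on this noiseless trace:

```r
fit_full_model(tr)$kinetics[c("tau_r", "tau_f", "tau_s", "i_f", "i_s")]
#> $tau_r  2      $tau_f  30     $tau_s  200    $i_f  0.7    $i_s  0.3
```

A command-line front-end covering simulation, fitting, ratio/QC
analysis, peak-time computation and NMODL emission is in
`inst/cli/pscfit.R`:

```sh
Rscript inst/cli/pscfit.R peaktime --config kinetics.cfg
Rscript inst/cli/pscfit.R compare --trace psc.csv --out rmse.csv
```

See `vignettes/psc-double-decay.Rmd` for the model derivation, solver
details and the validation studies.

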