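---
title: "Modeling postsynaptic currents with a double-exponential decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling postsynaptic currents with a double-exponential decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscfit)
```

## The model

A postsynaptic conductance is classically written as the difference of
two exponentials,

$$g(t) = \bar g\,K\left(e^{-(t-t_0)/\tau_{decay}} -
  e^{-(t-t_0)/\tau_{rise}}\right), \qquad t \ge t_0,$$

with peak time
$t_{peak} = t_0 + \frac{\tau_{decay}\tau_{rise}}{\tau_{decay}-\tau_{rise}}
\ln(\tau_{decay}/\tau_{rise})$ and normalization
$K = 1/(e^{-(t_{peak}-t_0)/\tau_{decay}} - e^{-(t_{peak}-t_0)/\tau_{rise}})$
so the maximum equals $\bar g$ exactly. Measured PSC decays, however, are
frequently bi-exponential; NMDA currents in particular carry a
substantial slow component. The common compromise — fit
$I_f e^{-t/\tau_f} + I_s e^{-t/\tau_s}$, then collapse it to the
amplitude-weighted mean $\tau_w$ and use a single decay exponential — is
demonstrably not an improvement over a plain mono-exponential fit (the
package's method-comparison tests reproduce this as a statistical
tendency). `pscfit` therefore models the conductance with all fitted
decay parameters:

$$g(t) = \bar g\,K\left(I_f e^{-(t-t_0)/\tau_f} +
  I_s e^{-(t-t_0)/\tau_s} - \tilde K e^{-(t-t_0)/\tau_r}\right),
  \qquad \tilde K = I_f + I_s,$$

where the $\tilde K$ term guarantees $g(t_0)=0$. Currents follow from the
driving force, $I = g\,(V-E_{syn})$ for AMPA receptors, with NMDA
receptors additionally scaled by the sigmoidal magnesium block
$Mg(V) = 1/(1 + e^{-aV}[\mathrm{Mg}^{2+}]/b)$.

**Assumptions.** The kinetics are deterministic and history-free: no
receptor desensitization, no Markov gating schemes, no short-term
plasticity, no stochastic release. Fractions are stored un-normalized
and $\tilde K$ is always recomputed, never stored. Conductance is
nonnegative by construction and zero before $t_0$ (causality). Units
follow NEURON conventions — ms, mV, µS, nA — so emitted mechanisms and
computed currents agree; trace files carry pA, the generator converts.

## The peak-time problem

Setting $g'(t)=0$ gives the stationarity condition

$$\frac{I_f}{\tau_f}e^{-x/\tau_f} + \frac{I_s}{\tau_s}e^{-x/\tau_s}
  = \frac{\tilde K}{\tau_r}e^{-x/\tau_r}, \qquad x = t - t_0,$$

which has no closed-form solution. Taking logarithms reduces it to the
scalar root problem $F(t)=0$ with

$$F(t) = x - \frac{\tau_r\tau_f}{\tau_r-\tau_f}
  \log\!\left(\frac{I_f}{\tilde K}\frac{\tau_r}{\tau_f} +
  \frac{I_s}{\tilde K}\frac{\tau_r}{\tau_s}
  e^{x(\tau_s-\tau_f)/(\tau_f\tau_s)}\right).$$

`newton_peak_time()` solves this by Newton iteration
$t \leftarrow t - F(t)/F'(t)$. Three numerical choices matter:

* **Derivative.** Writing $F(t) = x - M\log(A + Be^{cx})$, the analytic
  derivative is $F'(t) = 1 - McBe^{cx}/(A + Be^{cx})$, evaluated as
  $1 - Mc/(1 + (A/B)e^{-cx})$ so large $x$ cannot overflow. The log term
  itself uses a log-sum-exp form for the same reason. The derivative is
  validated against a central finite-difference oracle in the test
  suite (agreement to 1e-6 relative across 1000 random kinetics sets).
  With $I_s = 0$ the log argument is constant, $F$ is affine with unit
  slope, and one Newton step lands on the bi-exponential closed form.
* **Initial guess.** Newton's convergence is local, so the guess
  matters. The default is the bi-exponential closed-form peak time
  evaluated with $\tau_{decay} = \tau_w$: always defined (since
  $\tau_w \ge \tau_f > \tau_r$), costs one logarithm, and lands close
  enough that the iteration is quadratic from the first step. Measured
  over 1000 random physiological sets, the 99th-percentile iteration
  count to a 1e-12 ms step tolerance is 5.
* **Safeguard.** Convergence is declared on the Newton step magnitude
  ($|d| \le$ `tol`, default 1e-12 ms, cap 50 iterations), and a
  converged root must additionally satisfy the stationarity condition
  to a relative residual below 1e-8 — guarding against convergence to a
  point outside the log-domain. Any failure falls back to bracketed
  bisection on the sign change of $g'$ over $(t_0, t_0 + 20\tau_s]$,
  refined to 1e-9 ms; the fallback agrees with Newton to below 1e-8 ms
  whenever both succeed, and results are flagged with the method that
  produced them.

Degenerate kinetics ($\tau_{rise}=\tau_{decay}$, or $\tau_f=\tau_s$ with
$I_s>0$) have removable singularities. For the bi-exponential model the
alpha-function limit $g \propto x e^{-x/\tau}$ (peak at $t_0+\tau$) is
available behind an explicit `equal_tau = "limit"` opt-in; the default
is a validation error, because silent limiting can mask a pathological
fit. The tri-exponential model accepts $\tau_f = \tau_s$ (the profile
merely collapses to the bi-exponential form, which the solver handles
without special-casing).

## Trace fitting

`fit_mono_decay()` and `fit_double_decay()` fit the decay limb;
`fit_full_model()` fits the complete rise+decay profile with the peak
solved by Newton inside every residual evaluation. Choices made where
the procedure was genuinely open:

* **Window.** Decay fits run from the detected peak to the last sample
  by default (configurable). The baseline is the mean of the 10 ms of
  samples preceding the stimulus, subtracted before fitting; no offset
  term is fitted on top (a free offset trades against the slow
  component over finite windows).
* **Orientation.** Fits operate on the magnitude (inward currents are
  sign-flipped) so amplitude bounds are simple positivity constraints;
  orientation is restored on output.
* **Optimizer.** Levenberg–Marquardt least squares (`minpack.lm`) with
  positivity bounds. The double fit uses three seeded starts
  (fast-dominant, slow-dominant, balanced) to mitigate local minima;
  components are relabeled afterwards so $\tau_f \le \tau_s$, ties
  broken by labeling the larger amplitude fast, and fits with the two
  constants within 1% are flagged degenerate.
* **Identifiability.** The full model is invariant under common
  rescaling of $(I_f, I_s)$ — the normalization absorbs it — so the fit
  parameterizes fractions with $I_f + I_s = 1$ plus a free peak
  amplitude, and the decay constants as ordered offsets
  ($\tau_f = \tau_r + d_1$, $\tau_s = \tau_f + d_2$, $d_i \ge 0$) so
  the ordering constraint holds throughout the search.
* **Comparison.** `compare_methods()` reports RMSE for mono, weighted
  and double on the same window. "Weighted" reconstructs a single
  exponential with $\tau_w$ and amplitude $I_f+I_s$ from the double
  fit, mirroring how the collapse is used in practice.

## NMDA/AMPA ratio pipeline

The AMPA component of a paired recording is the baseline-subtracted
current peak at −70 mV; the NMDA component is the magnitude of the mean
+40 mV current 50–60 ms after stimulation, by which time the fast AMPA
component has decayed. Ratios are computed per cell and averaged within
a group — never as a ratio of group means. Pairs whose NMDA current
peaks at or before the AMPA current are excluded (NMDA kinetics are
slower; an early NMDA peak indicates absent NMDA receptors or
contamination, as reported for some fast-spiking interneurons). AMPA
subtraction from a raw +40 mV trace uses a pointwise scaled template;
the default scale is the linear driving-force ratio
$(+40 - E_{rev})/(-70 - E_{rev})$, exposed as a parameter.

The magnesium-block defaults ($a = 0.062\,\mathrm{mV}^{-1}$,
$b = 3.57$ mM, 1 mM Mg²⁺) are the classical Jahr–Stevens constants.
They are deliberately exposed as parameters: corrected values exist in
the literature, and any downstream use should treat these defaults as
overridable assumptions rather than measurements.

## The synthetic-trace generator

`generate_trace()` emulates voltage-clamp acquisition: the analytic
model current sampled on a uniform 10–20 kHz grid, an optional
first-order low-pass (2 kHz corner typical of acquisition filtering)
applied to the signal, and additive i.i.d. Gaussian noise on top. All
randomness flows through the explicit seed; identical specifications
give bit-identical traces, and the generator restores the caller's RNG
state. `generate_paired_cell()` constructs −70/+40 mV pairs whose
NMDA/AMPA ratio — computed by the same pipeline that will analyze them
— equals a requested target exactly at zero noise, by root-finding the
NMDA conductance scale; the −70 mV trace includes the Mg-blocked NMDA
contribution, as a real recording would.

Random kinetics for validation studies span
$\tau_r \in [0.2, 5]$, $\tau_f \in [2, 60]$, $\tau_s \in [60, 600]$ ms
with slow fractions in $[0.1, 0.9]$ — AMPA-like through NMDA-like
striatal kinetics. What the generator does **not** emulate: trial
amplitude variability, stochastic release, stimulus artifacts, access
resistance errors, or correlated recording noise. Passing recovery
tests therefore demonstrate correctness of the fitting machinery under
the stated noise model, not robustness to every artifact of real
recordings — inputs are assumed to be pre-processed averaged traces.

## Validation studies and problem sizes

The test suite runs, among others:

* solver–oracle equivalence on 1000 seeded random kinetics sets against
  a dense-grid argmax of the raw profile (1e-4 ms resolution; the grid
  oracle brackets coarsely first, which is exact for a unimodal
  profile, then sweeps densely inside the bracket);
* reduction identities ($I_s = 0$, and $\tau_f = \tau_s$) against the
  bi-exponential closed forms at 1e-10 ms / 1e-12 relative;
* normalization ($|g(t_{peak}) - \bar g| \le 10^{-12}\bar g$) and exact
  zero onset across the random suite, for both models;
* full-model parameter recovery on 100 synthetic traces at 10 kHz and
  500 ms: every parameter within 0.1% at zero noise; median relative
  error of $\tau_f$, $\tau_s$ about 1% at noise of 2% of peak (well
  under the 5% acceptance bound);
* RMSE ordering — double never worse than mono (nested models), and at
  least 3× better on NMDA-like traces ($\tau_s/\tau_f \ge 5$, slow
  fraction $\ge 0.3$) at zero noise, typically 20–30×;
* exact NMDA/AMPA ratio round trips at zero noise and QC behavior on
  constructed early/equal/late-peak pairs.

These sizes keep the whole suite around a minute on one core while
leaving every statistical margin wide; all are parameters of the test
code, not of the package.

## NMODL emission

`emit_nmodl()` writes a NEURON point-process mechanism with both
receptors: tri-exponential kinetics become one rise state plus two decay
states per receptor (`A_*`, `B_*`, `C_*`), and the peak times
(`tp_ampa`, `tp_nmda`) and normalization factors (`factor_ampa`,
`factor_nmda`) are embedded as precomputed constants — they depend only
on the kinetics, so computing them once at emission time (Newton's
method for tri-exponential kinetics) avoids any per-timestep cost. The
emitter produces deterministic text; compiling and running it under a
simulator is outside the package's test surface.

## Known limitations

* Decay fits assume the baseline is stationary; drifting baselines bias
  the slow component.
* Near-degenerate decay constants ($\tau_f \approx \tau_s$) make the
  amplitude split ill-conditioned; the double fit flags these rather
  than failing, and downstream users should treat the individual
  fractions of a flagged fit as unidentified.
* The supplementary simulation-based estimation of NMDA components when
  pharmacological separation is unavailable is not implemented; only
  the template-subtraction pathway is.
* The Mg-block constants are literature defaults, not fitted values.
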