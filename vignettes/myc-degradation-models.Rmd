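---
title: "Modelling ubiquitin-mediated c-Myc degradation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ubiquitin-mediated c-Myc degradation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycdeg)
```

## The biological problem

c-Myc is a short-lived transcription factor whose abundance decides between
proliferation and differentiation; failure to clear it is a hallmark of many
cancers. Clearance runs through the ubiquitin-proteasome system, and two
F-box substrate adaptors of the SCF E3 ligase can tag c-Myc:

* **FBXW7** recognizes the phosphodegron in Myc Box I and requires prior
  sequential phosphorylation at S62 (by Erk) and T58 (by GSK3beta) —
  a *phosphorylation-dependent* route;
* **Skp2** binds Myc Box II / bHLH-LZip and ubiquitinates c-Myc without any
  phosphorylation — a *phosphorylation-independent* route.

`mycdeg` implements deterministic kinetic models of both routes, compares
their parameter sensitivity and robustness, and asks when a cell should use
which route by optimizing an exclusive on-off switch between them.

## The models

### Model 1 — FBXW7 (phosphorylation-dependent)

Five states: `x1` (newly synthesized, growth-factor-stimulated c-Myc), `x2`
(phospho-S62), `x3` (phospho-T58), `x4` (ubiquitinated), and `Fstar`
(active FBXW7, bounded by the total pool `F_T`):

$$
\begin{aligned}
\dot x_1 &= k_1\,GF - k_2 x_1 - k_3 E(t)\, x_1\\
\dot x_2 &= k_3 E(t)\,x_1 - k_4 x_2 - k_5 G(t)\, x_2\\
\dot x_3 &= k_5 G(t)\,x_2 - k_6 x_3 - k_7 F^{*} x_3 + k_{10} x_4\\
\dot x_4 &= k_7 F^{*} x_3 - (k_{10}+k_{11})\,x_4\\
\dot F^{*} &= k_8 x_3 (F_T - F^{*}) - k_9 F^{*}
\end{aligned}
$$

The only nonlinearities are the bilinear ubiquitination term and the
saturating FBXW7 activation; there are no phosphatases or deubiquitinases
other than the single `k10` recycling step, and no reverse reactions
elsewhere.

The model output is the ubiquitinated fraction
$\gamma = x_4/(x_1+x_2+x_3+x_4)$.

### Model 2 — Skp2 (phosphorylation-independent)

Three states, with Skp2 (`S`) activated by c-Myc itself in positive
feedback:

$$
\begin{aligned}
\dot x_1 &= k_1\,GF - k_2 x_1 - k_{12} x_1 S\\
\dot x_4 &= k_{12} x_1 S - k_{11} x_4\\
\dot S   &= k_{13} x_1 - k_{14} S
\end{aligned}
$$

with output $\gamma' = x_4/(x_1+x_4)$.

### The combined, switched model

The union of the two systems shares the `x1` and `x4` balances and gates
the two *activation* steps through a binary switch $\alpha(t)$:

$$
\dot F^{*} = \alpha\,k_8 x_3 (F_T-F^{*}) - k_9 F^{*},\qquad
\dot S = (1-\alpha)\,k_{13} x_1 - k_{14} S .
$$

$\alpha = 1$ activates FBXW7 (Model 1 behaviour), $\alpha = 0$ activates
Skp2. Note that $\alpha$ gates activation, not catalysis: an already-active
pool keeps working while it decays. `simulate_combined(sw = NULL)` runs the
no-switch variant with both activation terms permanently on.

## Input signals

All inputs are piecewise-constant pulses built from Heaviside steps with
the half-open convention $\theta(0) = 0$ (a pulse is on over
$[\mathrm{on}, \mathrm{off})$):

* **Erk** $E(t) = E_R + E_{Max}\,\theta(Dur_E - t)$: on at level 1.0 until
  `Dur_E` = 1 h, baseline 0.1 afterwards.
* **GSK3beta**
  $G(t) = G_R + G_{Max}\,(\pi[Width_G\,(Dur_{G1}-t)] + \theta(t-Dur_{G2}))$
  with $\pi[u]$ the unit rectangle ($1$ for $|u| < 1/2$): a boxcar centred
  on `Dur_G1` = 2 h with full width $1/Width_G$ = 2 h — i.e. on over
  $[1, 3)$ h, turning on exactly as the Erk pulse ends — plus a sustained
  step from `Dur_G2` = 7 h to the end of the course.
* **Growth factor** is constant at `GF` = 1; the total FBXW7 pool is
  `F_T` = 5.

A note on the boxcar. The prose description of this signal says it
switches off at 2 h, which conflicts with the formula above (under the
standard rectangle convention the window is $[1, 3)$, and 2 h is its
*centre*). This package follows the formula, for a structural reason
uncovered during development: the optimal exclusivity switch of the
combined model (next sections) locks onto the time at which the first
GSK3beta pulse has finished loading the phospho-T58 pool, so the reported
~3 h switch-on time is reachable only if the first pulse extends past
2 h — exactly what the formula's $[1, 3)$ window produces. The formula
reading also makes `Width_G` a real shape parameter, which the robustness
analysis (which perturbs the signal durations *and width*) presupposes.

The half-open convention makes Erk off exactly when GSK3beta turns on at
t = 1 h, with no double-on instant. Signals are evaluated lazily as
functions of t, and `signal_breakpoints()` enumerates every discontinuity
so the integrator can restart there.

```{r signals}
prog <- signal_program()
t <- c(0.5, 1, 1.5, 4, 10)
rbind(time = t, E = erk_signal(t, prog), G = gsk_signal(t, prog))
```

## Numerical integration

Adaptive, stiff-capable integration (`deSolve::lsoda`, compiled
right-hand sides) with relative tolerance `1e-8` and absolute tolerance
`1e-10` by default. Because the inputs jump, the time axis is split at
every signal and switch discontinuity and the solver is restarted segment
by segment with the segment-constant signal levels; within a segment the
system is smooth, so the stepper's error control is valid. The test suite
cross-checks all three systems against an independent fixed-step RK4
integrator (step $10^{-3}$ h) written in plain R.

Initial conditions are not part of the published description; the package
defaults all states to zero at t = 0, consistent with growth-factor-driven
synthesis being the system's only source term, and accepts any nonnegative
initial state. The ubiquitinated fraction at zero total c-Myc (which
occurs only at t = 0 under the defaults) is defined as 0.

Trajectory grids default to 0.05 h for plotting and to the segment
boundaries only when just the final state is needed (ensemble runs), which
keeps 5000-sample ensembles inside a few tens of seconds without touching
solver accuracy.

## Rate constants: the calibrated default set

The original reaction tables with the numeric values of k1-k14 live in a
supplement that is not distributed with this package, and the main text
gives only the signal constants. The packaged defaults are therefore a
**calibrated, non-authoritative set**, chosen once so that the model
reproduces the documented qualitative behaviour:

* steep growth of `x1 + x2` while Erk is on, with `x3` and `x4` appearing
  only after the Erk pulse hands over to GSK3beta at 1 h;
* a mid-range ubiquitinated fraction at 30 h for both models, with the
  published sign pattern and approximate magnitudes of the sensitivity
  coefficients (strong positive k5/gsk, strong negative k6/k11 for
  Model 1; positive k12/k13, negative k14 for Model 2);
* an interior optimum of the exclusivity switch: off for the first few
  hours, then on through the horizon.

Every configuration records a `provenance` field
(`"packaged_default"` vs `"table_s1"`/`"table_s2"`), so results computed
with the calibrated set are never mistaken for results computed with the
original tables. Users who have the original supplement can supply its
values through `rate_parameters()` or a configuration file and set the
provenance accordingly.

```{r rates}
rate_parameters()
```

## Sensitivity analysis

`run_sensitivity()` perturbs each parameter independently with a Gaussian
whose standard deviation is `intensity x nominal` (the intensity is a
coefficient of variation, matching the percentage sweep 5-25% of the
study design); non-positive draws are rejected and redrawn rather than
clipped, which preserves the shape of the distribution near its mode.
Model 1 perturbs k1-k11 plus the signal amplitudes (`erk` = E_Max,
`gsk` = G_Max, `gf` = GF); Model 2 perturbs its six rate constants. The
output is measured "at steady state", operationalized as the value at the
30 h horizon — the inputs are time-varying pulses, so a fixed-point search
would be ill-posed.

Three coefficients are computed per parameter: Pearson (CC), Spearman rank
(RCC), and the partial rank correlation coefficient (PRCC) via
rank-residual regression with intercept: rank-transform everything,
regress the parameter's ranks and the output's ranks on all other
parameters' ranks, and correlate the residuals. Agreement of CC and RCC
diagnoses an approximately monotone-linear input-output map; PRCC then
sharpens each parameter's effect by removing the others' influence.
Two-sided t-tests (`t = r sqrt((n-2)/(1-r^2))`, df = n-2) accompany every
coefficient; no multiple-testing correction is applied, mirroring the
original analysis, and degenerate (zero-variance) columns raise errors
rather than silently producing NaN. The exact ensemble size behind the
published coefficient tables is unstated; the package defaults to
n = 5000 at 10% intensity.

## Robustness

`run_robustness()` repeats Gaussian ensembles over an ascending intensity
grid (default 5-25%), for Model 1 additionally perturbing the pulse
durations and width. Each sample is summarized by its *total parameter
variation* $\sum_i |p_i - p_i^0|/p_i^0$, and the output scatter is smoothed
by a moving average over the variation-sorted samples. The window defaults
to n/50 samples (100 at the published ensemble size n = 5000), giving at
least 50 effective bins — granular enough to see structure, wide enough to
suppress sampling noise; the original description fixes no window. The
*fluctuation score* — the standard deviation of the moving-average curve —
operationalizes "low variation in the moving average" as a single number,
and `compare_robustness()` orders two models by it. A flat curve means the
output depends only weakly on how far the parameter set strayed, i.e. a
robust model.

## The decision process

With both routes permanently active the combined model cannot reach low
ubiquitinated-Myc levels, which motivates an exclusive switch. The switch
search is a pure random search, exactly as in the study design: `n_iter`
(default 10,000) structures with on-time and duration drawn uniformly over
the horizon, each scored by $J = \int_0^{30} x_4\,dt$ (trapezoid on the
trajectory grid), argmin returned, ties broken by sample order. Two
boundary probes — always-on and always-off — are appended deterministically
so the optimum provably dominates both pure strategies. No gradient or
annealing refinement is added: the reported optimum is the best sampled
structure, keeping its provenance identical to the published procedure.
A single on-window parameterization is used (one off-to-on transition,
with the window allowed to end before the horizon); the reported optimum
keeps alpha on through the horizon, and the sampler does not forbid
earlier shut-off.

The search keeps the switched trajectory's x4 integral; `summarize_switch()`
re-simulates the winner and the no-switch variant to report the final
ubiquitinated levels side by side.

## What the generators emulate — and what they do not

The Gaussian ensembles and uniform switch samples reproduce the stated
statistical structure of the study design: independent per-parameter
Gaussian perturbation with CV equal to the named intensity, strictly
positive rates via rejection, uniform switch times, fixed seeds end to
end. They do not emulate anything about real biological variability —
no correlated parameter changes, no extrinsic/intrinsic noise, no cell-to-
cell heterogeneity; a passing suite shows that the deterministic models
respond to parameter displacement as described, not that real c-Myc
turnover does.

Open modelling choices resolved here, for the record:

* the combined model keeps `k10` recycling from the shared `x4` pool even
  for Skp2-produced x4, as the printed combined equations imply;
* rates and concentrations are treated as dimensionless with time in
  hours; nothing in the analysis depends on absolute units;
* duration perturbations in robustness ensembles can invert the two
  GSK3beta windows in extreme draws; the program then merges the windows
  (amplitudes never stack) and nudges `Dur_G2` above `Dur_G1` to keep the
  timetable well-defined.

## Problem sizes

Defaults follow the study design: 5000-sample ensembles for sensitivity
and robustness, 10,000-iteration switch searches, 30 h horizon. The test
suite exercises the same code paths at reduced sizes (hundreds of samples)
where the property under test does not require the full ensemble; the
acceptance script recomputes the headline quantities at full sensitivity
size, a 2000-sample robustness sweep per intensity, and the full 10,000
switch iterations.

## Known limitations

* The calibrated rate set is not the original one; quantitative
  coefficients computed from it are expected to approximate, not equal,
  the published tables. Two structural observations bound how close any
  calibration can get. First, for independent sampled inputs the squared
  Pearson coefficients of one output cannot sum past 1 (Bessel's
  inequality), while the published Model 2 CC column sums to about 1.5;
  those six printed values are therefore not jointly attainable under the
  stated independent-Gaussian sampling, and the calibrated set matches
  their *pattern* (three strong positive-feedback coefficients against
  three negative ones, near-equal k12/k13) at a proportionally smaller
  common magnitude. Second, a strong Pearson coefficient for the T58
  phosphorylation step requires that step to be rate-limiting (slow k5
  relative to the competing x2 decay), whereas an interior optimum of the
  exclusivity switch requires the first GSK3beta pulse to load the
  phospho-T58 pool briskly; the defaults sit deliberately between the two
  regimes. The partial rank coefficients, which are insensitive to the
  variance-share effects behind both observations, reproduce the
  published PRCC values much more closely than the CC column does.
* "Steady state" is a horizon convention; systems with very slow modes
  would report pre-asymptotic values.
* The robustness fluctuation score depends (weakly) on the moving-average
  window; the window is recorded in every result object.
* No stochastic (SSA/Langevin) simulation, no phosphatases or DUBs, no
  additional E3 ligases, and no upstream mechanistic model of Erk/GSK3beta
  activation — the pulses are the interface.
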