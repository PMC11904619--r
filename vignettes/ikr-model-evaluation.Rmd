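---
title: "Evaluating Markov models of IKr across voltage-clamp protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating Markov models of IKr across voltage-clamp protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The rapid delayed rectifier potassium current, IKr, carried by hERG (KV11.1)
channels, shapes cardiac repolarisation, and its pharmacological block is a
central concern of drug-safety assessment. Competing Markov models of IKr —
differing in state count, connectivity, and rate symmetries — all fit single
voltage-clamp recordings well, so discriminating between them requires
*cross-protocol* validation: fit each candidate model to each of a battery of
voltage-clamp designs, then score how well every fitted parameter set
predicts the current under every *other* design. `ikrfit` implements that
whole workflow — model library, protocol engine, simulator, synthetic-data
generator, trace postprocessing, repeated stochastic fitting,
cross-validation metrics, and a linear effects analysis of the resulting
parameter estimates — so the statistical machinery can be validated end to
end on synthetic data with a known data-generating process.

## Models

Each model is a continuous-time Markov chain over channel conformations with
governing equation $\dot x = Q(V_m)^\top x$, where $Q_{i,j}$ is the $i \to j$
transition rate. Only one open conformation conducts; the observed current is

$$I_{Kr}(t) = g\, x_O(t)\, (V_m(t) - E_{Kr}),$$

with maximal conductance $g$ (nS) and reversal potential $E_{Kr}$ (mV), so
that with voltages in mV the current is in pA. Voltage-dependent rates have
the form $k = A e^{\pm b V}$ ($A$ in ms$^{-1}$, $b$ in mV$^{-1}$, both fitted);
the five-state Wang structure additionally carries two voltage-independent
rates. The four structures are:

* **C-O-I** — three states in a chain, 9 parameters in total;
* **Beattie** — four states (C, O, I, IC) in a square with shared
  activation/inactivation rates, 9 parameters, including an inactivated-to-
  closed pathway that avoids the open state;
* **Kemp** — five states: the Beattie square plus a second closed state with
  its own rate pair (13 parameters). The published structure is available
  only as a diagram, so this connectivity is a documented transcription
  stand-in rather than a verbatim copy;
* **Wang** — five states in a chain (C1-C2-C3-O-I), 15 parameters, with the
  constant kf/kb pair on the C2-C3 transition and no inactivated-closed
  shortcut.

`E_Kr` is normally fixed at the Nernst potential
$E = (RT/F)\ln([K]_{out}/[K]_{in})$; with the study solutions (4 mM external,
132 mM internal potassium, 25 °C) this is about −90 mV. Simulations start
from the steady state at the −80 mV holding potential, computed directly from
the linear system $\{Q^\top x = 0,\ \mathbf 1^\top x = 1\}$ (long-time
integration is used only as an independent oracle in the tests).

The literature does not print parameter values alongside the structures, so
the package's `default_params` are implementer-chosen: the widely reproduced
room-temperature Beattie values for the C-O-I/Beattie/Kemp square, the
original Wang rate constants for the Wang chain, and a 100 nS conductance
scale. They serve as synthetic ground truth, not as fitted results.

## Protocols and the experiment design

A protocol is a table of steps and ramps. Every protocol shares a scaffold:
hold at −80 mV, step to −120 mV, a slow *leak ramp* back to −80 mV (IKr is
negligible in [−120, −80] mV, so this window identifies the linear leak), a
+40 mV leak-validation step; then the protocol-specific main section; then a
+40 mV preconditioning step, a fast *reversal ramp* from −70 to −110 mV
(crossing the reversal potential, so the corrected current's zero crossing
reads off $E_{obs}$), and a final hold. Scaffold durations are not published
in the main text; the defaults here (250/50/400/200/500/100/500 ms) are
package choices, configurable per call, as is the 1 ms default sampling
interval. The staircase stand-in spans [−120, +40] mV in deterministic
treads; the optimised designs d2–d12 of the original battery are deposited
with the raw data rather than printed, so the package ships seeded random
step protocols with the same scaffold plus a CSV loader for user-supplied
waveforms.

One well's experiment is: staircase twice, each other protocol once,
staircase twice more — then the identical block again after a simulated
specific IKr blocker. That yields 15 sweeps per drug state and, excluding
the validation-only protocol (d6), 14 fitting sweeps per well.

## Simulation

$\dot x = Q(V)^\top x$ is linear, so on constant-voltage segments the exact
solution is a matrix exponential, evaluated via the eigendecomposition of
$Q^\top$ (with a scaling-and-squaring fallback for near-defective cases). On
ramps the system is integrated with LSODA at `rtol = atol = 1e-8`. The
hybrid split (analytic steps, numeric ramps) is this package's choice; its
contract is agreement with the all-numeric path to 1e-6 sup-norm on the
state occupancies, which the test suite checks for all four structures.

**Voltage-offset convention.** Patch-clamp recordings carry a small
systematic voltage error. The package models it as $V_m = V_{cmd} + V_{off}$
and estimates it as $V_{off} = E_{Nernst} - E_{obs}$. These two signs are
chosen *together*: under this pairing the estimator applied to the
reversal-ramp zero crossing returns exactly the offset the simulator
consumes, so postprocessed offsets can be fed straight back into fitting.
(The opposite simulator sign, which one also meets in the literature, makes
that estimator return the negated offset and would mis-correct the voltage
by twice the offset if combined naively.)

## Synthetic data

The generator realises the assumed data-generating process:
$I_{out} = I_{Kr} + g_L (V_{cmd} - E_L) + \varepsilon$ with IID Gaussian
noise, per-well leak and voltage offset, and post-drug sweeps in which the
IKr term is removed entirely (complete specific block). Well- and
protocol-level kinetic heterogeneity is applied on the $a = \ln A$ and $b$
scales — the same scales the downstream linear model analyses — with
sum-to-zero Gaussian effects, and the conductance is log-normal per well.

Default magnitudes (noise 20 pA; leak 0.1–2 nS uniform; leak reversal
N(0, 5 mV); offset N(0, 2 mV); conductance log-normal around 100 nS with 30%
CV) are implementer-chosen to be realistic for automated patch clamp at room
temperature; none are printed in the source literature. What the generator
deliberately omits — capacitance transients, series-resistance artefacts,
endogenous background currents, time-varying leak — bounds what passing
tests show: they validate the statistical machinery under the stated
assumptions, not robustness to artefacts the model family excludes.

A `qc_filter()` pass emulates the heavy attrition of real screens with four
criteria (noise level, staircase stability between the first and last d1
sweeps, $|E_{obs} - E_{Nernst}|$, post/pre-drug RMS ratio). The real study's
thresholds live in its supplement; the defaults here (50 pA, 0.4 NRMSE,
15 mV, 0.5) are package choices. The drift threshold deserves a note: the
NRMSE between two *noisy* repeats has a noise floor of roughly
$\sqrt 2\,\sigma\sqrt n / \lVert z\rVert \approx 0.1{-}0.25$ at the default
noise, so a 0.2 threshold would reject genuinely stable wells; 0.4 sits
above that floor and far below genuine rundown (`inject_qc_failure()`
produces drifts of ~0.6).

## Postprocessing

Per sweep: ordinary least squares of current on command voltage over the
leak ramp gives $(g_L, E_L)$; the fitted line is subtracted; the post-drug
leak-corrected sweep is subtracted from the pre-drug one; a degree-4
polynomial in time is fitted to the corrected current over the reversal ramp
and its sign-appropriate real root gives $t^*$ and
$E_{obs} = V_{cmd}(t^*)$; the noise SD is estimated from the initial hold.
Two numerical conventions: a degenerate all-zero leak fit reports
$g_L = 0, E_L = 0$ with a flag (keeping downstream arithmetic finite), and
among multiple real roots in the ramp window the one where the fitted
polynomial decreases through zero is taken (the physiological direction on a
descending ramp).

One inherent limitation is worth stating precisely: the pre-drug leak fit
absorbs whatever small IKr flows in the [−120, −80] mV window, so even
noiseless postprocessing returns IKr only up to that projection (relative
sup-norm error ~1e-3 at the defaults). This is a property of linear-leak
estimation itself, not of the implementation; the tests bound it rather
than pretend it away.

## Fitting

Under IID Gaussian noise the MLE is nonlinear least squares. Each sweep is
fitted by `n_repeats` independent CMA-ES runs (population
$\lfloor 4 + 3\ln n_p\rfloor$, raised to 50 for the 15-parameter Wang
model), each started from a log-uniform guess ($\log_{10} p \sim U(-7, 1)$,
rejection-resampled until all constraints hold). Transition rates are
constrained so their maximum over [−120, +60] mV lies in
$[1.67\times10^{-5}, 10^5]$ ms$^{-1}$; the conductance is loosely bounded
from the current during the −120 mV scaffold step, scaled by leniency
constants $(10^{-2}, 10^4)$ — the upper constant must be large because the
step current estimates $g\,x_O$ with open probabilities down to ~$10^{-4}$.

Package-level numerical choices, in the absence of published ones: the
search runs in transformed coordinates ($\log_{10}$ for $A$-type parameters
and $g$, linear for $b$-type, scaled so one CMA-ES step size of 0.3 suits
all axes); bounds are enforced by repair-plus-quadratic-penalty; repeats
stop on a 1e-7 relative function tolerance or the evaluation budget; and the
best repeat is refined by a deterministic L-BFGS-B polish in the same
coordinates. The polish never replaces the repeat structure — per-repeat
diagnostics report the raw CMA-ES results, and the repeat-clustering check
(estimates within a 1% RMSE increase of the best should occupy a small
region of parameter space) is computed on those.

## Validation metrics

Accuracy is scored by
$\mathrm{NRMSE}(y, z) = \sqrt{\sum_i (z_i - y_i)^2} / \lVert z \rVert$ with
both numerator and denominator in root-sum-of-squares form, so the sample
count cancels and protocols of different lengths and cells of different
conductance are comparable. The cross-validation table has one row per
fitting sweep (staircase repeats are separate rows) and one column per
validation sweep; `e_fit()` averages the diagonal and `e_predict()` the
off-diagonal under the $1/(N_d - 1)^2$ normalisation. Time-resolved
discrepancy uses noise-weighted residuals $(y_i - z_i)/\hat\sigma$ averaged
across wells, and the ensemble statistic

$$T_i = \frac{\bar y_i - z_i}{\hat\sigma + \mathrm{std}(y_i)/\sqrt{N}},$$

both clipped to [−100, 100]. The spread term is read as a standard error
($\sqrt N$); a `se = FALSE` switch gives the $/N$ reading, since the printed
form is typographically ambiguous. Fits to the sweep under evaluation are
excluded from the ensemble by the caller, so $T$ measures genuine
predictions only.

## Variability analysis

Kinetic estimates (transformed to $a = \ln A$ and $b$; the conductance is
excluded because cell-to-cell conductance variability is expected and
uninformative about kinetics) are stacked into a table $Y$ and fitted with

$$M_{w,d}: \quad Y = \mu + X_d\beta_d + X_w\beta_w + E,$$

sum-to-zero effects coding for both factors, independent Gaussian errors per
column with maximum-likelihood variances ($\mathrm{RSS}/N$, matching the
reported ML log-likelihoods; a REML-style divisor would not). Repeated
staircase sweeps share one protocol level — the model has no replicate term.
Nested variants fix $\beta_w$ and/or $\beta_d$ at zero, and
$\mathrm{LLD}(-w) = \ell(M_{w,d}) - \ell(M_d)$,
$\mathrm{LLD}(-d) = \ell(M_{w,d}) - \ell(M_w)$ quantify well- and
protocol-dependence. On synthetic tables the analysis separates strong well
effects from none by an order of magnitude in LLD(-w), reproducing the
qualitative signature — large LLDs of both kinds — that real multi-well,
multi-protocol estimates show.

## Problem sizes used in the checks

The shipped test battery runs at deliberately modest scale, chosen once as
the package's desk-scale study conditions: simulator agreement on the full
staircase at a 10 ms grid; postprocessing recovery over 50 noise seeds at
20 pA; parameter recovery with the 3-state C-O-I model, 5 CMA-ES repeats and
a 2500-evaluation budget per repeat on the 10 ms staircase; cross-validation
behaviour on a 3-protocol battery (staircase, one random design, one
validation-only design) at noise 0/5/20 pA with one staircase fit per noise
level (4 repeats, 2000 evaluations each); and the effects analysis on
8-well × 14-sweep tables, the same shape as the real estimate ensembles.
The full 12-protocol, 30-repeat configuration is the package default for
real use.

## Known limitations

* The Kemp connectivity is a transcription stand-in (see above); its
  parameter count (13) is internally consistent but not a published number.
* Protocols d2–d12 are seeded stand-ins, not the deposited waveforms; all
  protocol-specific conclusions on synthetic data are therefore qualitative.
* No artefact model (series resistance, capacitance, endogenous currents) —
  fitted offsets and leaks absorb what they can, as in the ideal-patch
  assumption the analysis is built on.
* The leak-window IKr projection bounds noiseless postprocessing accuracy at
  ~1e-3 relative; see Postprocessing.
* MCMC identifiability analysis is out of scope; the repeat-clustering
  diagnostic is the only optimiser-convergence evidence reported.
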