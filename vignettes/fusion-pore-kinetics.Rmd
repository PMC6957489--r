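---
title: "Resolving fusion-pore kinetic intermediates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving fusion-pore kinetic intermediates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusepore)
```

## The measurement problem

Exocytotic fusion pores are nanometer-scale, millisecond-lived conduits
between a vesicle lumen and the extracellular space. In the nanodisc /
planar-bilayer (ND-BLM) configuration a single trans-SNARE-driven pore is
trapped between a nanodisc and a black lipid membrane and read out as a
unitary ionic current at a fixed holding potential, with microsecond time
resolution; single-molecule FRET on labelled SNARE pairs reports the
zippering state of the same complexes. `fusepore` implements the complete
quantitative chain for both readouts:

1. **Simulation** — continuous-time Markov pore gating rendered as a
   realistic recording (Gaussian noise, 4-pole Bessel filtering,
   decimation), and two-colour smFRET traces with crosstalk, noise and
   single-step photobleaching.
2. **Idealization** — threshold-crossing event detection with hysteresis
   and a dead time, producing state segments and dwell-time tables.
3. **Kinetics** — fraction of time open; dwell-time CDFs fitted with
   constrained exponential mixtures; component count chosen by AIC.
4. **Conductance** — Gaussian-mixture current-histogram fits, conversion to
   conductance and an approximate pore diameter.
5. **Dose–response** — Hill fits (EC50, cooperativity) and Pearson
   chi-squared occurrence statistics.
6. **smFRET** — ratio computation, photobleach-based single-molecule
   selection, FRET-state Gaussian mixtures.

Because the raw recordings behind the published analyses are not deposited,
the synthetic generators double as the reference data source: every
downstream stage is validated against simulations whose ground truth is
known, at the parameter values the study reports (open conductances of
170–902 pS depending on nanodisc composition and Ca²⁺, Hill parameters
EC50 ≈ 164–210 µM with coefficients 3.4–4.3, FRET states at ratios
0.2 / 0.5 / 0.7).

## Gating model and trace rendering

A `gating_model` is a small continuous-time Markov chain over `closed`,
optionally `partial`, and `open` states. Each state has a conductance
$\gamma$ (pS, closed $\equiv 0$); off-diagonal entries of the rate matrix
are transition rates (s⁻¹). The rendered current is

$$I = \gamma\,\Delta\psi / 1000 \quad \text{(pA, with } \gamma \text{ in pS
and } \Delta\psi \text{ in mV)},$$

so openings are downward (negative) at the standard holding potential
$\Delta\psi = -60$ mV; all conductances are reported as positive
magnitudes. Ca²⁺ sensitivity enters by scaling a designated rate with a
Hill term $H(c) = c^h/(\mathrm{EC}_{50}^h + c^h)$ (direction "up") or
$1 - H(c)$ ("down") — the simplest mechanism that produces sigmoidal
dose–response curves with adjustable midpoint and cooperativity.

Rendering emulates the acquisition chain: simulation at 8× the output rate
(80 kHz for the default 10 kHz output), additive Gaussian noise at the
oversampled rate, a digital 4-pole Bessel low-pass at 5 kHz applied
forward-only (matching the causal analog filter of a bilayer-clamp rig),
then decimation. The filter is designed from the standard analog
fourth-order Bessel prototype poles (−3 dB normalized) by bilinear
transform with frequency prewarping, and its DC group delay is compensated
by an integer-sample shift so the rendered trace stays aligned with the
retained true state path. Oversampling before filtering reproduces the
rounding of fast events that a real dead time must absorb.

Two fields are retained on every simulated trace for oracle testing: the
hidden state label and the ideal noise-free unfiltered current per output
sample. With the filter disabled and zero noise the rendered samples equal
the ideal current exactly; with the filter enabled, transitions acquire the
filter's finite rise time, which is the realistic case the idealizer must
handle. The recording noise level is not calibrated to any instrument —
the study does not report one — so `noise_sd_pA` is always an explicit
argument.

Seeds are mandatory everywhere; no function consumes or mutates the global
random state (`withr::with_seed` wraps every stochastic block), and
sub-seeds for replicate loops are derived deterministically below $2^{31}$.

## Idealization

Event detection is deliberately simple, mirroring threshold-based event
detectors in acquisition software rather than hidden-Markov inference:
samples are assigned to the nearest supplied current level through
half-amplitude thresholds with a hysteresis of 10 % of the inter-level gap
(a sample switches state only after crossing 10 % beyond the midpoint
toward the new level, suppressing noise chatter at the boundary). Runs
shorter than the dead time are merged into the flanking segment with the
longer duration, ties toward the earlier segment, so output is
deterministic; segment mean currents are recomputed from raw samples.

The default dead time is 0.2 ms — two samples at 10 kHz and comfortably
above the ≈ 66 µs rise time of a 5 kHz 4-pole Bessel filter — chosen to
suppress filter-ringing artifacts without hiding the millisecond flickers
of interest. The first and last segments of every record are censored from
dwell statistics (their true onset/offset is unobserved) but retained for
fraction-open bookkeeping, which uses total times and is insensitive to
censoring direction. Partially open sojourns are idealized as their own
level when three levels are supplied, but dwell-time kinetics treat only
the fully open and fully closed classes; partial time is excluded from the
fraction-open ratio (numerator and denominator). How partial time should
be attributed is genuinely undocumented for this preparation, so exclusion
is exposed as the fixed, conservative policy rather than a guess.

## Dwell-time kinetics and model selection

Opening kinetics are read from closed-dwell CDFs and closure kinetics from
open-dwell CDFs. The model is a constrained exponential mixture

$$\mathrm{CDF}(t) = 1 - \sum_{i=1}^{m} A_i e^{-k_i t},\qquad
A_i \ge 0,\ \sum A_i = 1,\ k_i > 0,$$

fitted for $m = 1 \dots 5$. The constraints (softmax amplitudes, log
rates) guarantee a proper CDF; whether the original analysis constrained
amplitudes to sum to one is not documented, but without the constraint the
fitted curve need not be a distribution function. The number of free
parameters is therefore $k = 2m - 1$, and the goodness-of-fit score is

$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(k + 1)$$

with the natural logarithm (only rankings matter, but a base must be
fixed; the natural log is the one that derives from a Gaussian
likelihood). An RSS floor of $10^{-12}$ guards the logarithm on exact
synthetic data.

**What the RSS is computed over matters.** Per-point ECDF residuals are not
independent: the ECDF's deviation from the true CDF is a smooth
Brownian-bridge-like process, so an extra exponential component always
absorbs a sizeable fraction of the residual sum regardless of sample size,
and an RSS-based criterion evaluated at every dwell over-selects components
with probability approaching one. The package instead forms residuals on
CDF increments over `n_grid` equal-probability intervals (by default at
least 10 dwells per increment, capped at 100 increments), i.e. the
difference between observed and model probability mass per quantile bin. This is exactly the generalized-least-squares fit of
the ECDF under its sampling covariance — the bridge precision matrix is
tridiagonal and its quadratic form collapses to a sum of squared increment
residuals — and these residuals are approximately independent and
homoscedastic, which is what the AIC formula assumes. $n$ in the AIC is the
number of fitted increments.

Model selection (`select_model`) minimizes AIC over the admissible
component counts (those with at least $10m$ dwells), ties toward the
smaller $m$. Two admissibility guards encode the requirement that every
fitted component describe a resolvable kinetic state: a multi-component
fit enters the comparison only if each amplitude is at least 0.05 and
adjacent rates differ by at least a factor of 2. Components below those
limits are reparameterizations of a simpler model (two nearly equal rates,
or a component carrying a few percent of events riding on estimation
noise) rather than evidence of an additional state; with the guards, the
selected count matches the generating count in well over 80 % of simulated
records at $n = 5000$ and ≥ 10× rate separation (the test suite verifies
this over 50 seeded replicates for both one- and two-exponential data),
the regime in which the single- versus multi-exponential distinction is
scientifically meaningful.
A maximum-likelihood fitter on the raw dwells (`fit_exp_mixture_ml`) is
provided as an independent cross-check of the least-squares estimates; it
is not used for selection. No missed-event correction is applied to rate
estimates — the dead time is handled upstream at idealization, and rates
approaching its reciprocal should be interpreted cautiously.

## Conductance and pore size

Current histograms are fitted with 1-D Gaussian mixtures by EM (quantile
initialization, 500-iteration cap, explicit collapse detection when two
means approach within one standard deviation, and an exact branch when the
data take no more distinct values than components — the noiseless-trace
case). Per-state conductance is the component mean minus the closed
(nearest zero) component mean, divided by the holding potential:
$\gamma = |\Delta I| / |\Delta\psi| \times 1000$ pS. Cohorts are
summarized as mean ± SEM across trials.

Pore diameter uses the cylindrical-pore-plus-access-resistance relation

$$\frac{1}{\gamma} = \frac{4 L \rho}{\pi d^2} + \frac{\rho}{d},$$

solved in closed form as the positive root of the quadratic in $1/d$.
Defaults: $L = 15$ nm (about two bilayer thicknesses for the
nanodisc-membrane junction); $\rho$ is user-supplied because the recording
buffers are asymmetric (100/10 mM KCl) and are represented by a single
effective resistivity with no Goldman-style correction. The original
report does not state its conversion parameters, so diameters here are
approximations on the same footing as the published ones — monotone in
$\gamma$ and useful for comparisons, not absolute structure.

## Dose–response and occurrence

Hill fits use the four-parameter form
$r(c) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor})\,
c^h/(\mathrm{EC}_{50}^h + c^h)$, weighted by $1/\mathrm{SEM}^2$ when SEMs
are available, via Levenberg–Marquardt with a small multi-start over $h$.
The floor may be pinned to zero; for observables with a structural zero
baseline (occurrence of syt1-clamped pores, open time at vanishing Ca²⁺)
pinning removes an upward median bias in $\hat h$ that appears when the
baseline must be estimated from a couple of near-zero points. A fitted
EC50 outside the tested concentration range is flagged, not rejected.
Conductance dose–response data are summarized but not Hill-fitted by
default, matching the practice of not fitting a quantity that cannot be
reliably measured at low concentrations.

Occurrence (the percentage of trials in which a pore was detected) is
compared between conditions by Pearson chi-squared on the 2×2
detected/not-detected table, one degree of freedom, no continuity
correction; pairwise comparisons are unadjusted by default with a
Bonferroni option, since the original pairwise stars name no adjustment.

The synthetic dose–response generator (`simulate_hill_curve`) uses eight
log-spaced concentrations from 25 to 1200 µM — a realistic titration
spanning both reported EC50s — and Gaussian noise with sd equal to 10 % of
the dynamic range. The study itself shows four concentrations with 10–16
trials each; the denser synthetic design tests the fitter without changing
the noise regime.

## smFRET

The ratio $R = (I_A - 0.05\,I_D)/(I_D + I_A)$ uses a fixed 5 % donor
crosstalk; the coefficient is part of the ratio definition, not a fitted
parameter. The simulator inverts this formula exactly for noiseless
frames: with total intensity $T$, $I_D = T(1-R)/1.05$ and
$I_A = T(R + 0.05)/1.05$, so a noiseless single-state trace returns its
state mean bit-exactly — a useful identity check. The default total
intensity is 1000 a.u. per 100-ms frame, a typical count scale for
cy3/cy5 single molecules.

Single-molecule selection follows the photobleaching signature: recursive
binary change-point segmentation of the total intensity (maximal two-mean
split statistic, minimum segment of 5 frames); a trace is accepted iff it
shows exactly one significant step, downward, with amplitude above 3× the
pre-step noise sd. The original selection rule is not described beyond
"single photobleaching event", so this detector is a stated convention of
this package. Frames after the bleach are excluded; rejected traces
contribute nothing.

FRET states come from EM Gaussian mixtures on pooled pre-bleach ratios
(2 or 3 components). For comparing the two- and three-state descriptions,
each fit carries an AIC computed from the RSS between the observed
40-bin histogram on $[-0.1, 1.1]$ and the binned mixture probabilities
(bin count and range fixed for reproducibility), with $3m - 1$ free
parameters. No hidden-Markov state-path inference is attempted — state
assignment is histogram-level, as in the original analysis.

## Problem sizes, tolerances, determinism

The validation suite and the acceptance analysis use: 5–20 s gating traces
at 10 kHz (60 s for the conductance-recovery benchmark), $n = 5000$ dwells
and 50 seeded replicates for model-selection properties, 100 seeded
replicates for Hill recovery at 10 % noise, and ≥ 2000 pooled frames for
FRET-state recovery (tolerance 0.05 on state means, 3 % on recovered
conductances, 10 % on Hill medians). These sizes make every property run in
seconds to a few minutes on one CPU while keeping Monte-Carlo error well
inside the tolerances. Reported empirical numbers in the README are the
actual outputs of the scripts under `analysis/`.

`run_pipeline` chains the stages on one configuration and emits a
schema-versioned, timestamp-free report; with fixed seeds the report is
reproducible byte-for-byte, and unknown configuration keys are rejected
rather than ignored.

## What the simulations do and do not establish

The generators reproduce the statistical structure the analysis assumes:
exponential dwells with Ca²⁺-modulated rates, discrete conductance levels,
Gaussian recording noise shaped by a causal Bessel filter, discrete FRET
states with crosstalk, shot-like per-channel noise and single-step
bleaching. They do not model membrane physics, SNARE zippering
energetics, NSF/ATPase chemistry (disassembly "stuttering" is
representable only as a user-supplied time-varying rate schedule),
baseline drift beyond a constant offset, correlated or non-Gaussian
instrument noise, or optical effects beyond additive noise and crosstalk.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated for the assumed data-generating process — not
that real recordings satisfy those assumptions. Conclusions that depend on
features absent from the generators (for example drift robustness) require
real data.
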