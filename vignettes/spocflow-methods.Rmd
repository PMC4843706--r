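---
title: "Methods: supervised bandpower decomposition and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised bandpower decomposition and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spocflow)
```

## The model

The working assumption is the linear forward model of EEG volume
conduction: the sensor signal is a superposition of source time courses,
$x(t) = A\,s(t) + \varepsilon(t)$, where each column $a_m$ of the mixing
matrix describes how one neural source projects to the electrodes. The
behavioral hypothesis is that the *power* of some oscillatory source in a
pre-movement window covaries, trial by trial, with upcoming motor
performance $z(e)$.

SPoC$_\lambda$ searches for a backward model — a spatial filter $w$ —
whose projected per-epoch bandpower $\Phi(e) = \mathrm{Var}[w^\top x(t)](e)$
has maximal covariance with the (standardized) target:
$$ w_{opt} = \arg\max_w \mathrm{Cov}\big[\Phi(e),\, \tilde z(e)\big]
   \quad \text{s.t.} \quad \mathrm{Var}[w^\top x(t)] = 1 .$$
Writing $C(e)$ for the channel covariance of epoch $e$,
$\Phi(e) = w^\top C(e) w$, so the objective is the quadratic form
$w^\top C_z w$ with $C_z = \mathrm{mean}_e[\tilde z(e)\, C(e)]$ and the
constraint is $w^\top \bar C w = 1$ with $\bar C$ the epoch-mean
covariance. The stationary points solve the generalized eigenvalue problem
$C_z w = \lambda \bar C w$; each eigenvalue is exactly the
bandpower–target covariance of its component, which the test suite asserts
to $10^{-8}$ relative accuracy. Activation patterns — the interpretable
forward-model view of each component — are $A = \bar C W$. Predictions on
unseen epochs are the projected bandpower
$z_{est}(e) = \mathrm{Var}[w_{tr}^\top x_{te}(t)](e)$; they live on the
power scale and are scored by correlation and rank statistics, never by
absolute value.

Only the positive-eigenvalue side of the spectrum is ranked and
evaluated: the workflow targets components whose power *increases* with
the target variable, and the eigenvalue rank criterion (below) is defined
on the descending spectrum.

## Numerical choices

* **Per-epoch covariance**: sample covariance over the epoch's samples,
  per-channel mean removed within the epoch, denominator $T-1$, no
  normalization of the trace (the prediction is raw projected variance).
  Covariances are precomputed once per band and flattened to an
  $N_e \times N_c^2$ stack; every downstream refit (cross-validation
  folds, label-noise repetitions) is then a cheap re-weighting of the same
  stack — this is what makes the label-noise stress test affordable.
* **Solver**: symmetric whitening. $\bar C$ is eigendecomposed, its
  spectrum floored at $10^{-10}\cdot\mathrm{trace}$ (a warning marks
  rank-deficient input), and the whitened $C_z$ is eigendecomposed.
  Filters are rescaled to *exact* unit projected training variance, so
  the published constraint holds to machine precision by construction.
  An optional shrinkage parameter mixes $\bar C$ towards the scaled
  identity for ill-conditioned data (63 channels × 375 samples is close
  to the regime where this matters); the default is 0.
* **Sign convention**: eigenvectors are sign-ambiguous. Each filter is
  flipped so the largest-magnitude entry of its pattern is positive,
  making fold patterns comparable across folds.
* **Rank selection**: a least-squares line is fitted to the descending
  eigenvalue spectrum and ranks whose residual exceeds $1.5\,\sigma(r)$
  (restricted to $\lambda > 0$) are selected. On a featureless spectrum
  nothing is selected; the scan always evaluates rank 1 as fallback.
* **Target standardization** always uses training-fold statistics only,
  so no test-fold information leaks into the fit.

## Validation metrics and their defaults

* $R_{all}$: Pearson correlation between the true target and the
  concatenated cross-validated predictions. Pearson (not Spearman) is the
  natural partner of a covariance objective.
* $R_{folds}$: mean of the fold-wise correlations. A component that only
  tracks a slow session drift achieves high $R_{all}$ but low
  $R_{folds}$; the `classify_predictor()` defaults (|R_all| ≥ 0.2,
  fold ratio ≥ 0.5) encode that contrast. Folds are contiguous
  chronological blocks (K = 5, earlier folds take the remainder), because
  shuffled folds would hide exactly the nonstationarity this contrast is
  designed to expose.
* $H_{folds}$: the number of folds whose correlation sign matches
  $R_{all}$, with zero counting as a match ($\Theta(0)=1$). The selection
  battery requires all 5.
* **z-AUC**: the continuous prediction recast as a binary problem — trials
  split at the 50th percentile of the *true* target, ROC AUC of the
  predicted values with midrank tie handling (so median-tied trials need
  no special casing). Chance level 0.5; invariant under monotone
  transforms of the prediction, which matters because the prediction is
  on the power scale.
* **AAUC$_{SNR}$**: labels are corrupted with white noise at SNR levels
  $\{-20,-15,\dots,10\}$ dB (SNR$_{dB} = 10\log_{10}(\mathrm{Var}[\tilde
  z]/\mathrm{Var}[\epsilon])$), three draws per level; the pipeline is
  *retrained* on the noisy labels and always *scored* against the clean
  ones — the only reading under which added label noise can degrade the
  score. The summary is the mean excess over chance,
  $\mathrm{mean}(zAUC - 0.5)$, across the grid. Grid spacing, repetition
  count and the excess-area normalization are declared defaults, not
  established constants; all are configurable arguments.
* **Selection thresholds** (z-AUC ≥ 0.59, AAUC ≥ 0.18, H_folds = 5,
  N_e ≥ 150): the numeric values originate as 85th percentiles of the
  score distributions over a large population of components in the motor
  task this workflow was built for. They are defaults of
  `selection_thresholds()`, and recomputing scan-specific percentiles is
  a matter of quantile() on the scan table.

## The force metrics

CPL is the discrete total variation of the force trace over
$[t_{go}, t_{hit}]$ — a telescoping sum for monotone traces, hence the
closed-form checks. ISJ uses third derivatives by central finite
differences (5-point stencil inside, one-sided 4-point stencils at the
window ends); both stencils are exact for cubic polynomials, so ISJ is
invariant to adding any quadratic trend and reproduces
$\int (d^3 t^3/dt^3)^2 dt = 36$ exactly, while for smooth non-polynomial
traces the error vanishes with sampling rate (asserted over three rates).
No smoothing is applied before differentiation — a deliberate choice to
keep the estimator parameter-free; noisy force sensors will inflate ISJ
and should be low-pass filtered upstream. NJ is implemented exactly as
the published score, ISJ · DUR^{5/2} / CPL², with the exponent exposed
because 5/2 is what makes the printed formula, while 5 would make the
quantity dimensionless; the default follows the printed form.
Standardization before pooling the two task conditions uses the
population SD (ddof = 0) — the convention is arbitrary but fixed, and RT
is pooled raw.

Behavioral rejection applies the published intervals — RT ∈ [150, 900] ms
and NJ ∈ [0, 1300] on raw values; DUR ∈ [−1.5, 2], CPL ∈ [−0.6, 0.6],
ISJ ∈ [−1.5, 1.5] on standardized values, whose ranges are only sensible
for z-scores. The variance rejection rule is implemented as an outlier
fence — reject an epoch when any channel's variance exceeds
$P_{90} + 2(P_{90}-P_{10})$ — because the literal alternative (always
rejecting everything above the 90th percentile) would discard 10% of
every dataset regardless of quality, contradicting the outlier intent;
the fence multiplier is configurable. Min-max comparisons are strict
(> threshold rejects), fixed for determinism at the boundary.

## What the synthetic generator does and does not emulate

`generate_scene()` instantiates the forward model directly: each planted
source is band-filtered white noise whose per-epoch standard deviation
follows $\sigma_e = \sigma_0 \exp(g\,\tilde z(e))$ — an exponential law
that keeps power positive and the power–target link monotone. The gain
$g$ is calibrated in closed form from the exact relation
$r = 2g/\sqrt{4g^2 + \mathrm{Var}[\log V]}$, where $V$ is the sample
variance of the unit narrowband process over one epoch (its variance is
estimated from 200 calibration epochs drawn under the scene seed). This
relation is exact for Pearson correlation regardless of the distribution
of $\log V$, and the tests confirm the planted correlation is recovered
within ±0.05 at $N_e = 400$. An exact correlation of 1 is deliberately
rejected as unattainable: epoch bandpower is itself a noisy estimate.

Default scene geometry mirrors the analysis window of the task: 750 ms
epochs (the pre-cue prediction window) at 200 Hz, alpha-band sources in
the test fixtures. The target is standard normal; a `trend_weight`
parameter mixes in a standardized linear session trend, and
`comodulation_driver = "trend"` makes the source power follow *only* the
trend component — the construction behind the session-trend fixtures used
to validate the $R_{all}$ vs $R_{folds}$ contrast.

What is *not* emulated: realistic head-model lead fields (patterns are
arbitrary vectors), eye/muscle artifacts, continuous recordings
(epochs are generated independently, so there is no between-epoch phase
continuity), and 1/f background spectra by default (a pink-noise toggle
exists, but white noise keeps the sensor covariance closed-form:
$A\,\mathrm{diag}(p)A^\top + \sigma^2 I$, which a test verifies).
Passing tests therefore demonstrate correctness of the algorithms under
the stated generative model, not performance on real EEG — in particular,
real artifact subspaces in low frequency bands can masquerade as
predictive components and are the reason the selection battery exists.

## The grid scan

The band grid is parametric: log-spaced lower edges with constant
relative bandwidth (so neighbors overlap), bands intersecting the
power-line zone [45, 55] Hz removed; the defaults emit 55 configurations
spanning ≈1–100 Hz. The published grid's exact band edges are not
recoverable from its description, so the generator reproduces its count,
range and structure rather than its literal values — everything is an
argument of `default_band_grid()`.

Filtering is filter-then-epoch when the input is continuous (5th-order
Butterworth, zero-phase by default — doubling the effective order — with
a causal option for future online use); already-epoched input is
filtered epoch-wise with reflection padding. The regression baseline uses
*log* channel bandpower by default (standard for linear models on power;
raw variance is an option) and one OLS component per cell, with a ridge
fallback on singular designs.

## Problem sizes

The test fixtures use 3–16 channels and 150–300 epochs for the property
checks, and the full 63-channel × 400-epoch geometry for the planted
recovery battery; the brute-force oracle checks equivalence of the eigen
solution on 3-channel scenes against an exhaustive 1° grid over filter
directions. These sizes were chosen as the smallest at which the assessed
properties are statistically stable across seeds.

## Known limitations

* Only the SPoC$_\lambda$ variant is implemented (no SPoC$_{r^2}$, no
  regularized or transfer-learning extensions).
* No source reconstruction: patterns are sensor-space objects.
* The epochs container is a plain-text directory format; BrainVision/EDF
  ingestion is out of scope, and continuous input is accepted as a plain
  samples × channels matrix with event times.
* Selection thresholds transfer poorly across paradigms; recompute them
  as percentiles of your own scan before trusting the flags.
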