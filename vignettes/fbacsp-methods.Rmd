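---
title: "Filter-bank adaptive and common spatial patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-bank adaptive and common spatial patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement — modulates
sensorimotor EEG rhythms: imagining a hand movement desynchronizes the mu
(8–12 Hz) and beta (18–26 Hz) rhythms over the contralateral motor cortex
(ERD) and can synchronize them elsewhere (ERS). A brain–computer interface
decodes which movement was imagined from a short epoch of multichannel EEG.
Two kinds of class signatures coexist in such data:

* **spatial contrasts** — the *relative* distribution of band power across
  directions in sensor space differs between classes (the classical ERD/ERS
  picture), and
* **energy contrasts** — the *total* band power differs between classes
  while its spatial distribution stays the same.

Common spatial patterns (CSP) capture only the first kind: a CSP filter `w`
maximizes the variance ratio `w'C_a w / w'(C_a + C_b) w` between class
covariances, and its log-variance features are normalized so that a global
gain change is invisible to them. This package implements a filter-bank
pipeline that augments CSP with *adaptive spatial patterns* (ASP), spatial
filters optimized directly to separate log band-energy, which captures the
second kind.

## The model

**Filter bank.** Epochs are decomposed into nine 4 Hz sub-bands, 4–8 up to
36–40 Hz, with zero-phase Chebyshev type II band-passes. "Second-order
Chebyshev" is ambiguous between the filter order and the family; we read it
as the family (type II), whose flat passband is what an energy feature
wants, and choose the order per band as the smallest that keeps the
passband gain above 0.9 given 30 dB stopband attenuation and a 2 Hz
transition (all configurable). Zero phase matters because group delay would
shift the cue alignment; we apply the squared magnitude response in the
frequency domain after reflective padding, which is the magnitude response
of forward–backward filtering and vectorizes across all trials and
channels. Filtering precedes cue-locked windowing (default: the whole
trial; for competition-style recordings, 0.5–3.5 s after the cue) so filter
transients stay outside the analysis window.

**CSP per band.** One-vs-rest CSP per sub-band and class: whitening the
composite covariance and diagonalizing the class covariance gives filters
whose two diagonalized spectra sum to one. All channel filters are
retained at this stage, so the raw CSP feature count is
`subbands * K * channels`; binary problems still emit both mirrored
one-vs-rest matrices to keep this count, and redundancy is removed by the
selection stages. Trial covariances are trace-normalized before averaging
and a ridge of `1e-8 * trace/channels` is added. Features are
`log(var_j / sum(var))` — invariant to trial scaling by construction.

**ASP per band.** For every sub-band and unordered class pair, a single
weight vector `F` (unit norm; one scalar feature per filter, so the ASP
feature count is `subbands * C(K,2)`) minimizes the scatter ratio

    loss(F) = sum_k sum_{i in k} (x_i - mean_k)^2
              -----------------------------------
              sum_k n_k (mean_k - grand_mean)^2

of the log energy features `x_i = log sum_t (F . X_i[, t])^2`. The loss is
exactly invariant to affine maps of the features, hence to positive
rescaling of `F`; we therefore search the box `[-1, 1]^channels` and
normalize the result to unit norm with the largest-magnitude entry
positive, a reproducible canonical form. A degenerate between-class term
(below 1e-12) maps to `+Inf` so the optimizer avoids uninformative filters.
Energies are evaluated as quadratic forms against precomputed per-trial
cross-products, so a whole swarm is scored with one matrix product.

**Local-best PSO.** The optimizer is a ring-topology particle swarm:
velocity `v <- w v + c1 r1 (pbest - x) + c2 r2 (lbest - x)` with one
uniform draw per particle, per dimension, per attraction term (the
per-dimension variant explores better than a shared scalar draw); inertia
decreases linearly from 0.9 to 0.4; each velocity component is clipped to
`0.2 * (hi - lo)`; positions are clamped to the box. The neighbourhood is a
ring over particle indices (`k = 2` by default, floor(k/2) left /
ceil(k/2) right), the canonical local-best topology; `k = N-1` reduces
exactly to global-best PSO, which the tests exploit as a bit-level oracle.
Defaults `N = 40`, `G = 100`, `c1 = c2 = 2` follow the common tuning
literature for this optimizer family; runs stop early after 25 iterations
without an improvement above 1e-8, and every run is deterministic given its
seed.

**Feature selection.** Stage one (MIBIF) ranks each one-vs-rest CSP block's
features by mutual information with the labels — equal-frequency binning
with `min(10, floor(sqrt(n)))` bins, log base 2, a parameter-light
estimator — and keeps the top `n = 4` per block (ties to the lower index),
leaving `subbands * K * n` CSP features. The pooled matrix of
`subbands * (C(K,2) + K n)` features then passes through decision-tree
recursive feature elimination: a Gini CART is fitted (no surrogate splits),
each feature's importance is the sum over its split nodes of

    (N_t / N) * (gini_t - (N_tL/N_t) gini_L - (N_tR/N_t) gini_R)

normalized to sum one, and the single worst feature is dropped (ties drop
the highest index), one per iteration. The final count is chosen by
stratified 5-fold cross-validation over a candidate grid: the elimination
path is computed once on the full training set (its nested subsets are the
candidates — stage-one selection is likewise fixed before the CV, matching
the training-stage ordering), the downstream forest is scored per fold, and
the one-standard-error rule returns the smallest candidate within one SE of
the best mean accuracy, favouring parsimony. With fewer than five trials in
the rarest class the fold count degrades with a warning.

**Classifier.** A random forest of `T = 500` bagged Gini trees,
`mtry = ceiling(sqrt(p))`, bootstrap at full n; prediction is the majority
vote with ties resolved toward the lowest class index. Tree-based models
are deliberate here: CSP and ASP features live on different scales, and
trees are invariant to any monotone per-feature transform, which the tests
assert. Forest importances are the accumulated sample-weighted Gini
decreases normalized to sum one.

**Interpretation.** `mi_summary()` audits every pooled feature's mutual
information with provenance labels such as `FBASP 8 Hz-12 Hz 1`.
`exact_shapley()` enumerates all `2^p` coalitions (capped at 12 features —
eliminated sets are small) with the exact weights
`|S|! (p-|S|-1)! / p!`; the coalition value replaces out-of-coalition
features by background rows and averages the model output, per class for
the forest's vote fractions. Efficiency, symmetry and the dummy axiom hold
to numerical precision and are asserted in the tests. Larger feature sets
would need sampling approximations, which are out of scope.

## The synthetic generator

`sim_scenario()` / `generate_epochs()` draw band-limited Gaussian sources
(brick-wall Fourier restriction to the effect band, one source per
channel), mix them with a fixed full-rank matrix, and add 1/f plus white
sensor noise; `snr` is baseline in-band source power over total noise
power. Class effects are planted in two orthogonal ways:

* `csp_favorable`: class `l` multiplies one source's variance by the effect
  size — a direction-specific contrast whose mixed image is recorded as
  ground truth `u`;
* `asp_favorable`: class `l` scales the *entire effect-band content* of the
  trial (sources and in-band noise alike) so in-band variance grows by
  `effect_size^(l/(K-1))`. The band's covariance *shape* is then exactly
  class-independent: every scale-invariant statistic — hence every CSP
  feature of that band — is uninformative by construction, while the log
  band-energy shifts by a constant. This realizes "classes differing only
  in total band energy under a shared spatial covariance". Out-of-band
  content is untouched, so the effect stays band-specific up to the
  filters' transition-band leakage.

`mixing = "orthogonal"` replaces the random Gaussian mixing matrix with a
random orthonormal one. With correlated background mixing, the filter that
best separates log energies is pulled toward the whitened contrast
direction rather than `u` itself; the isotropic configuration is the one in
which the planted direction is the unique optimum, and it is what the
parameter-recovery checks use (at `snr = 10`). Defaults elsewhere —
8 channels, 2 s trials at 128 Hz, effect band 8–12 Hz, effect size 4,
`snr = 1`, equal pink/white noise weights — were fixed once as plausible
sensorimotor values.

What the generator does **not** emulate: volume conduction from a real
forward model, non-stationarity within and across sessions, eye and muscle
artifacts, electrode drift, and inter-subject variability. Passing tests on
this generator therefore validate the algorithmic contracts (recovery of
planted structure, invariances, count formulas, train/test hygiene), not
clinical-grade decoding performance on real recordings.

## Numerical choices and edge cases

* Time windows are half-open `[start, end)` seconds; sample index
  `floor(t * fs)`.
* Common-average re-referencing is skipped for montages under four
  channels (`reref = "auto"`) — small bipolar montages should not be CAR'd.
* An objective returning a non-finite value inside the swarm is treated as
  `+Inf` with a single warning.
* A zero-energy filter output raises an explicit error rather than a
  silent `-Inf` feature.
* The master seed derives per-stage seeds (ASP per band/pair, CV folds,
  forest) through a fixed integer hash kept below 2^31; refitting with the
  same seed is bit-identical, and transforming new data never touches any
  fitted artifact.

## Problem sizes

The end-to-end checks run 2-class, 8-channel scenarios at 200 trials per
class with a 200-tree forest, a 60-iteration swarm and the candidate grid
{4, 8, 12, 16, 24}; parameter-recovery uses 16 channels and 200 trials; the
swarm benchmark is the 5-D sphere at `N = 40`, `G = 200` over 100 seeds
(run without early stopping so the stated iteration budget is exhausted).
These sizes were chosen once as the smallest at which the planted effects
are comfortably identifiable.

## Known limitations

* One weight vector per band/pair: multi-filter ASP variants and
  alternative losses are not implemented.
* The gradient-based alternative to the swarm is supported only through the
  `optimizer` hook of `fit_asp_filter()`.
* Exact Shapley attribution is capped at 12 features.
* No GDF/EDF reader is bundled; epochs enter through the documented
  CSV + JSON bundle or in memory as a 3-D array.
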