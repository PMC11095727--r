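---
title: "Assessing fitness-landscape regressors: models, splits, calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing fitness-landscape regressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fitscape)
```

Protein engineering increasingly relies on regressors that map a variant
sequence to a predicted fitness together with a predictive uncertainty. How
good such a regressor looks depends dramatically on how the assessment is
designed: which data are held out, which metric is reported, and whether the
predicted uncertainties mean anything. `fitscape` packages the full
assessment loop — synthetic data generation, encodings, uncertainty-aware
regressors, split protocols, accuracy and calibration metrics, composition
baselines, and an optimization-as-assessment protocol — so that each of these
design choices can be studied in isolation. This vignette records the models
and the reasoning behind every open design choice.

## The data model

A variant is a set of point substitutions against a wildtype sequence,
written in the conventional notation `"A23G:T45K"` (wildtype residue,
1-based position, mutant residue; the empty string is the wildtype). The
number of substitutions is the variant's *mutation degree*. An assay dataset
couples variants with real-valued fitness labels and, for iteratively
collected data, an acquisition-round index.

## The synthetic landscape generator

Real deep-mutational-scanning (DMS) data and language-model embeddings are
deliberately out of scope; a simulator with controllable structure stands in
for them. Its latent score for a variant is

additive: sum over substitutions of effect(site, residue), plus
epistatic: sum of pairwise couplings over substituted site pairs,

with the observable fitness a link function of the score plus homoscedastic
Gaussian assay noise. The pieces, and why they look the way they do:

* **Additive effects** decompose as `b_site + e_(site,residue)` with
  `b_site ~ N(effect_mean, position_effect_sd^2)` shared across residues at a
  site and `e ~ N(0, effect_scale^2)` residue-specific. The site component
  models site conservation — how much a position tolerates any change — which
  dominates real mutational scans. It also controls learnability: with purely
  i.i.d. per-(site, residue) effects, a one-hot model can never generalize to
  an unseen substitution under *any* split, because that substitution's
  indicator column is constant-zero in training. The default is
  `position_effect_sd = 0` (fully idiosyncratic effects); the split-gap
  analyses use site-dominated settings (`position_effect_sd = 1`,
  `effect_scale = 0.1`).
* **Deleterious bias.** `effect_mean` defaults to −0.5: most mutations hurt.
  Under the sigmoid ("bimodal") link this reproduces the familiar
  functional / non-functional bimodality of single-mutant scans, and makes
  the functional fraction collapse as degree grows — the degree-shift
  phenomenon the extrapolation case study probes.
* **Epistasis** lives on `n_epistatic_pairs` site pairs drawn uniformly;
  an interacting pair carries an independent `N(0, epistasis_scale^2)` term
  for every non-wildtype residue combination, so any variant substituting
  both sites feels a coupling (Potts-like couplings). Attaching a single
  residue-specific term per pair would make epistasis fire with probability
  ~1/361 per double and have no measurable effect on any simulation.
* **Noise** is homoscedastic Gaussian. Real assays are heteroscedastic and
  often bounded; nothing in the pipeline depends on this simplification, and
  it keeps calibration ground truth exact. No biophysical realism
  (stability, ΔΔG) is attempted; conclusions about *assessment design*
  transfer, conclusions about specific proteins do not.
* **Campaign simulation.** Round 0 assays random single mutants; each later
  round proposes, with probability `greedy_fraction`, a new substitution on
  a random member of the current top 10% of observed variants (degree capped;
  at the cap an existing substitution is resampled), and otherwise a random
  variant at the current frontier degree. With high greed the mean label
  rises and mean degree grows round over round, confounding time with
  fitness — exactly the selection bias of real engineering campaigns.
* **Surrogate embeddings** are a fixed random linear projection of the
  one-hot encoding (optionally through `tanh`). They preserve the only
  property the pipeline needs from a learned representation — a
  deterministic sequence-to-vector map of controllable dimension and
  linearity — and nothing else; they carry no evolutionary information.

All generators are bit-reproducible given their parameters and a seed, and
never disturb the caller's RNG state.

## Encodings and label handling

One-hot encoding uses a frozen 22-symbol alphabet (20 canonical amino acids
in a documented order, then gap `-` and unknown `X`). The gap/unknown columns
are constant zero on clean substitution data but keep the layout stable for
gapped inputs. Mean pooling (the standard aggregation of per-residue
language-model states) is the coordinatewise mean.

Labels are standardized — `(y - mean) / sd` — **on the training fold only**,
never on pooled data: this prevents test-set leakage and matches the
zero-mean prior of the GP regressors. Predictions are always returned on the
original label scale.

## Regressors and their uncertainties

* **kNN**: mean of the k nearest training labels (Euclidean distance, ties
  broken by lowest training index); predictive variance is the empirical
  variance of those labels, floored at 1e-12. This is deliberately
  under-dispersed — kNN's variance reflects local label spread, not distance
  from the data — and no inflation is applied, so its characteristic
  over-confidence remains observable (the calibration driver typically shows
  reduced chi-squared well above 1 for kNN).
* **Random forest** (via `ranger`): across-tree mean, with predictive
  variance defined as the across-tree second moment minus the squared mean
  of the per-tree predictions.
* **Exact GPs** with three kernels: linear
  (`sigma2 * <x, x'>`, equivalent to Bayesian linear regression; shared
  signal variance by default, per-dimension ARD optional since fitting d
  variances with n << d observations is ill-posed), squared-exponential, and
  Matérn-5/2. Hyperparameters maximize the log marginal likelihood *plus*
  the log density of loose priors — inverse-gamma(3, 3) on signal variance
  and lengthscale, uniform [0.01, 1.0] on the noise variance (entering as a
  box constraint). Using both the priors and the marginal likelihood makes
  the objective a MAP estimate; that is the only reading under which the
  priors do anything at all. Optimization is multi-start L-BFGS-B (a
  median-distance start plus restarts drawn from the priors, max 500
  iterations) with analytic gradients; all solves go through a Cholesky with
  an escalating jitter ladder (1e-8 to 1e-4 of the mean diagonal) before
  failing.
* **Predictive variance includes the noise variance.** Calibration compares
  residuals of *noisy observations* against the predictive sd, so the
  noise-inclusive (predictive, not latent) distribution is the calibrated
  one. The self-consistency check — sample labels from the GP prior at fixed
  hyperparameters, predict held-out points with the true hyperparameters —
  then yields reduced chi-squared near 1 by construction.

Hyperparameter protocols for the baselines mirror common practice: an
internal three-fold CV minimizing mean absolute error, over k in
[1, floor(0.95 N / 3)] with budget 75 for kNN and trees in [2, N] with
budget 15 for the forest; the search is exhaustive when the range fits the
budget and surrogate-assisted (1-d Matérn GP + expected improvement over the
log-scaled grid) otherwise. The unoptimized kNN default is k = ceiling(N/3),
reading the conventional "a third of the data" rule.

## Split protocols

* **Random k-fold CV** (default k = 10): test sets partition the data;
  measures interpolation.
* **Positional CV**: contiguous position blocks of size p (default 15),
  ceiling(L/p) folds since L is rarely a multiple of p; a variant is in a
  fold's *test* set iff any of its mutated positions falls in the block,
  train otherwise (the symmetric reading of "train = no mutation in the
  range"); the wildtype always trains. Measures generalization to unseen
  sites.
* **Mutational CV**: train on degrees < d, test on degree d; the in-domain
  diagonal holds out 20% of the degree-d variants in a 5-fold scheme over
  the rest plus all lower degrees. Higher degrees never appear.
* **Fractional CV**: per repetition a fixed 20% evaluation set is held out
  and training subsamples of each fraction q are drawn from the remainder.
  Keeping the test set fixed across q makes test difficulty constant along
  the learning curve; a `complement` mode (test on everything not trained
  on) is available for the alternative reading. Default fractions are the
  quartiles.
* **Chronological split**: train on rounds < cut, test on rounds >= cut —
  the honest forecaster protocol for campaign data.

All plans are 1-based index pairs, disjoint within every fold, reproducible
from their inputs and seed, and exportable as long-format tables.

## Metrics

Accuracy: adjusted R² `1 - Σ(y-ŷ)²/Σ(y-μ_train)²` (improvement over the
training-mean baseline: 0 for that baseline, negative when worse), MSE, and
Spearman rho computed as the Pearson correlation of average ranks.

Uncertainty quality:

* **Reduced chi-squared** `Σ((y-ŷ)/σ̂)² / (N-1)`: 1 when calibrated, > 1
  over-confident, < 1 under-confident.
* **Calibration curves**: the quantile description in terms of grouped
  predictive variances is not directly implementable as stated; we use the
  standard regression-calibration construction of the literature the
  description points to — the empirical CDF of probability-integral-
  transformed residuals `Φ((y-ŷ)/σ̂)` evaluated at levels j/q. ECE is the
  mean absolute gap between coverage and level.
* **Sharpness**: coefficient of variation of the predictive variances
  (sample sd convention, documented since it is otherwise ambiguous).
* **Confidence curves**: mean squared error over the retained set
  {σ̂ ≤ j/q-quantile}. A printed-formula-literal mode (`literal = TRUE`)
  divides by total N instead of the retained count; the retained-set mean is
  the default because it is the interpretable convention (its final entry is
  the overall MSE). Squared error is assumed as the loss, which the source
  description leaves uninstantiated.

## Baselines

The training-mean predictor anchors adjusted R² at zero. The additive
composition baseline predicts a multi-mutant as the sum of its observed
single-mutant labels (duplicates averaged; missing constituents yield NA and
are excluded with a count). For triples the plain sum of the three singles is
the default; a `decompositions` mode averages y(observed double) + y(single)
over the three splits, falling back to singles where the double is
unobserved — the composition rule for degree ≥ 3 is genuinely ambiguous and
both readings are provided. On additive noiseless landscapes the baseline is
exact by construction, which the tests assert. A ranking "oracle" orders
candidates by any externally supplied score (stable ties) and serves as the
unsupervised selection baseline.

## Optimization as assessment

All pool labels are known; the protocol measures how quickly an acquisition
strategy *finds* the optimum. Each iteration refits the surrogate (with its
full hyperparameter protocol) on the observed points, scores all unobserved
candidates by expected improvement `(μ-best)Φ(z) + σφ(z)` (maximization
convention, no exploration jitter, `max(μ-best, 0)` at σ = 0), and reveals
the argmax's label (ties to the lowest index). Defaults the protocol leaves
open and we fix: 5 random initial observations; refitting every iteration
(a `refit_every` throttle exists for desk-scale experiments and is off in
all tests). Traces are summarized over quarters of the iteration axis with
mean and standard error across seeds, plus the median iteration at which the
optimum was found (censored at budget + 1 when never found).

## Numerical choices and degenerate inputs

Constant training labels make the standardizer (and hence every regressor
fit) fail loudly; the benchmark runner records such folds as NA cells rather
than crashing. Predictive variances are floored at 1e-12. Cholesky failures
escalate through the jitter ladder before erroring. Distance and EI ties
break by lowest index so every pipeline is deterministic given its seed.
Derived seeds are computed in double precision and kept below 2^31.

## Problem sizes

The packaged analyses are sized for a desk machine: L = 30 scans
(570 singles), campaigns of 250 variants, candidate pools of 200, BO budgets
of 100 with 10 seeds, GP simulations up to n = 500 for self-consistency and
n = 200 for hyperparameter recovery. These sizes were chosen so every
qualitative phenomenon (split gaps, acquisition bias, calibration, BO
efficiency) is comfortably resolved; all of them scale up by changing
arguments only.

## What passing tests do and do not show

The simulator reproduces the *statistical structure* the assessment
arguments rely on — bimodal single-mutant scans, degree-dependent label
collapse, acquisition-biased campaigns, smooth embeddable pools — so green
tests certify the machinery: metrics match brute force, GPs match
closed-form oracles, splits leak nothing, the acquisition loop is honest.
They do not certify that any particular real protein, assay, or language
model behaves like the simulator; on real data the size of each phenomenon
is an empirical question, which is precisely why the assessment framework
exists.

## Known limitations

No sparse/approximate GPs (exact solves cap practical n around a few
thousand); no heteroscedastic noise model; no homology-based splitting; no
conformal prediction; no batch acquisition; representations are consumed as
matrices and never learned. The ARD linear kernel is provided but
unregularized beyond its prior, and is ill-posed when d >> n.
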