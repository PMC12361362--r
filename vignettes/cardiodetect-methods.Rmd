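---
title: "Methods: ship-rescue optimization for heart-disease screening and AF-rate regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ship-rescue optimization for heart-disease screening and AF-rate regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its models: what each stage
computes, which choices were genuinely open and how they were resolved, and
what the synthetic cohorts do and do not establish about real clinical data.

## The pipeline at a glance

`cardiodetect` screens tabular patient records in three optimizer-driven
stages:

1. **Weighted feature selection** — `select_features()` searches jointly
   over which attribute columns to keep and a positive weight per kept
   column, scoring a candidate by the chi-square association between the
   binned weighted columns and the disease label.
2. **Detection** — `adsvm()` / `tune_adsvm()` fit a hybrid detector: a
   feed-forward extractor whose penultimate activations feed an RBF-kernel
   SVM; the extractor's learning rate, width and activation are tuned
   against `1/CSI + FPR` on a held-out fold.
3. **AF-rate regression** — for patients flagged as diseased,
   `amccnet()` / `tune_amccnet()` regress a continuous, normalized
   atrial-fibrillation rate with a multi-scale convolutional capsule
   network trained on squared error and tuned against validation RMSE.

All three searches use the same population metaheuristic,
`sro_optimize()`.

## The optimizer

The ship-rescue optimizer moves a population of candidate vectors (ships)
relative to the current population best (the prey, position $q$, fitness
$F_p$). A candidate at $x$ with fitness $F$ moves per gene $i$:

$$
x_i' =
\begin{cases}
x_i + v\,(q_i - I\,x_i) & F_p < F \\
x_i + v\,(x_i - q_i)    & F_p \ge F
\end{cases}
$$

The enhancement replaces the classical uniform random step coefficient with
a fitness-adaptive ratio recomputed once per generation from the
population's fitness spread,

$$
v = \frac{F_\mathrm{worst}}{\bar F + F_\mathrm{worst} + F_\mathrm{best}},
$$

which lies in $[0,1]$ for non-negative objectives: a population with a
large fitness spread takes large exploratory steps, a converged one takes
small refining steps. Setting `adaptive = FALSE` restores the uniform
coefficient for comparison.

Decisions that the update rule leaves open, and how this package resolves
them:

* **The intensity coefficient $I$** is drawn uniformly from $\{1, 2\}$ per
  gene per update — the common convention for intensity coefficients in
  this family of prey-following algorithms — and is injectable
  (`intensity =`) so tests can pin it.
* **The three fitness summaries.** The middle term is the population mean
  fitness: the adaptive coefficient is explicitly a mean-fitness
  modification, and best/worst/mean is the only reading that makes the
  ratio a normalized spread.
* **Acceptance is greedy-elitist**: a move replaces its parent only when it
  improves fitness. Convergence traces are therefore monotonically
  non-increasing by construction, which the tests assert on every run.
* **Prey selection**: the best candidate of the current generation. The
  best candidate itself lands in the retreat branch with $x - q = 0$, so
  elites are never perturbed.
* **Bound handling is clamping**, not reflection, for determinism.
* Every stage minimizes; maximization targets (chi-square, CSI) enter as
  reciprocals.

Budget defaults are a population of 10 and 50 generations, with exactly
`pop_size * (max_iter + 1)` objective evaluations. Hyperparameter searches
use a chromosome of length 3 (learning rate, width, activation index); the
feature-selection search uses `2 * k` genes.

## Weighted feature selection

A genome holds `k` feature genes in $[1, F]$ and `k` weight genes in
$[0.01, 0.99]$. Decoding rounds feature genes to column indices and drops
duplicates keeping the first occurrence — the selection may shrink below
`k`, never backfills, and is always non-empty. `k` defaults to 10, read as
a selection-size budget; it is configurable.

The score of a decoded selection sums, over selected columns, the
contingency chi-square
$\chi^2 = \sum_x (A_x - G_x)^2 / G_x$
between binned weighted column values (observed counts $A_x$ per class)
and the label-marginal expectation $G_x$. Fitness is the reciprocal
$1/(\chi^2 + 10^{-12})$; the epsilon guard keeps a zero-association
selection finite rather than special-cased.

**Discretization.** Chi-square needs counts, the columns are continuous,
and no binning rule accompanies the objective, so the package fixes one:
columns with at most 4 distinct values keep their values as bin
identities (binary/ordinal clinical attributes reproduce the plain
contingency table exactly, which is what the oracle tests check); other
columns are cut at quartile breaks of the non-negatively shifted weighted
values, with a median split as fallback when ties collapse the quartiles.
The rule is deterministic and row-order invariant.

**The role of the weights.** Quantile binning makes the chi-square
invariant to the weight's positive scale, so the weights matter downstream
rather than in the score: the transformed matrix multiplies each selected
column by its weight (the prose convention "features multiplied by their
weights"; the alternative additive reading is rejected as inconsistent
with a weighting's purpose).

## The detector

The extractor is a fixed-depth network — two hidden layers of
`hidden_neurons` units each, the tuned activation, a sigmoid output —
trained as a standalone binary classifier with binary cross-entropy,
Adam updates, batch size 16, and early stopping (patience 30 epochs) on a
held-out fifth of the training rows; the best-monitored weights are kept.
The untuned default learning rate is 0.001; the tuner searches
$[0.01, 0.99]$, widths $[5, 255]$ (per layer), and activation indices 1-5
mapping to ReLU, sigmoid, tanh, leaky-ReLU and ELU.

Training is two-stage: the extractor is fit, frozen, and its
penultimate-layer activations become the inputs of an RBF-kernel
soft-margin SVM (penalty `cost` default 1, kernel width default
`1/dim`), whose decision function is the classical support-vector
expansion $d(f) = \sum_e (\mu_e - \mu^*_e) K(f_e, f) + k$. The head
standardizes the deep features internally (constant columns excepted):
penultimate activations can land on wildly different scales across tuned
configurations, and an unscaled RBF kernel degenerates toward constancy
in that regime. Joint end-to-end training of extractor and head is out of
scope.

The tuning objective is $1/\mathrm{CSI} + \mathrm{FPR}$ on a stratified
80/20 validation fold of the training partition, with the same epsilon
guard on CSI; its global minimum of 1 is attained exactly by a perfect
classifier. Candidates whose training fails score worst-possible fitness
instead of aborting the search. The returned model is refit on all
training rows at the winning hyperparameters.

## The capsule regressor

The AF-rate network treats the selected feature vector as a 1-D signal:

* **Multi-scale stem.** Three parallel cross-correlation branches with
  kernel lengths 3, 5 and 7 under "same" zero padding (4 channels each by
  default), concatenated channel-wise. The kernels are described in their
  2-D form upstream of this package, but the data here is a tabular
  feature vector, so 1-D kernels over the feature axis are the only
  coherent reading; three branches are used because three sizes are
  specified. Same padding keeps all branch outputs position-aligned for
  concatenation.
* **Primary capsules.** One further linear convolution (kernel length 3)
  emits `8 * floor(hidden_neurons / 8)` channels; channels are regrouped
  position-wise into 8-dimensional pose vectors and squashed with
  $\mathrm{squash}(e) = \frac{\|e\|^2}{1+\|e\|^2}\frac{e}{\|e\|}$, which
  preserves direction and bounds every capsule norm below 1. The tuned
  `hidden_neurons` gene plays the role of the capsule channel budget,
  since a capsule layer has no classical hidden-neuron count; values
  below 8 are rejected.
* **Dynamic routing.** Prediction vectors $\hat v_{b|a} = z_{ab} v_a$
  route to 4 digit capsules of dimension 16 over 3 iterations: logits
  start at zero, coupling coefficients are per-primary-capsule softmaxes,
  digit inputs are coupling-weighted prediction sums, outputs are
  squashed, and logits grow by the prediction-output dot product. Capsule
  dimensions, digit count, iteration count and zero logit initialization
  follow the established capsule-network conventions and are all
  configurable.
* **Readout.** The four digit-capsule norms pass through a trained affine
  map and a sigmoid, so predictions always lie in $[0, 1]$.

Training minimizes mean squared error by Adam over all stem, capsule-conv,
transform and readout parameters. Two details matter numerically:

* **Stop-gradient through routing.** The forward routing loop is exact;
  during backpropagation the coupling coefficients are treated as
  constants. A finite-difference audit (run during development on a tiny
  configuration) shows readout gradients exact and upstream gradients
  within a few percent of the full derivative — the routing-coefficient
  term is small because couplings start uniform and saturate quickly —
  while the implementation stays tractable.
* **Learning-rate schedule and snapshotting.** The tuned learning-rate
  gene spans $[0.01, 0.99]$, two orders of magnitude. Training applies
  inverse-time decay to a tenth of the base rate by the final epoch and
  returns the parameters of the best training-RMSE epoch, so large-rate
  candidates degrade gracefully instead of diverging and the tuner
  compares configurations rather than divergence artifacts.

Inputs are standardized column-wise inside the model (the scaling is
stored and reapplied at prediction).

## Metrics

All ten evaluation formulas are implemented exactly as defined on
fractions, with percent scaling a presentation flag:

accuracy, precision, F1, MCC (zero when any marginal is zero, the standard
limit convention), CSI $= TP/(TP+FP+FN)$, FPR, RMSE, MAE, SMAPE with the
mean-of-endpoints denominator (bounded by 2; a both-zero term contributes
0), and MPE. One discrepancy is preserved deliberately: the quantity
named MPE is defined with $|{\hat r} - r|/r$ — the absolute-percentage
(MAPE) form, not a signed percentage error — and the package implements
and names it exactly as defined, documenting the mismatch here and in the
help page.

## Synthetic cohorts

`simulate_heart_data()` generates the study conditions the tests run
under: 1026 patients with exactly 500 absence / 526 presence labels and
14 clinically named attribute columns by default, of which the first 2
are informative (class-conditional normals separated by 1.5, within-class
standard deviation 1) and the rest are standard-normal noise. The
severity variant fixes 920 patients across four sites of 303, 294, 123
and 200 with a 5-level severity label that detection collapses to binary
(0 vs 1-4). An effect size of 1.5 noise-standard-deviations was chosen
once as a realistic medium-strength clinical signal — strong enough that
association tests should find it, weak enough that single columns do not
separate the classes.

No public heart-disease table carries a continuous AF-rate field, so the
generator defines one and declares it: with $z_1, z_2$ the standardized
informative columns,
$\mathrm{af} = \sigma(0.8 z_1 + 0.6 z_2^2 - 0.5) + \mathcal N(0, 0.05)$,
clipped to $[0,1]$. The closed form is exported in the table's attributes
so recovery tests know the exact truth. Real-data AF evaluation is not
possible as described and is not claimed.

The 80/20 split takes exactly $\lceil 0.8 n\rceil$ training rows —
the ceiling rule reproduces both published splits (1026 → 821/205 and
920 → 736/184) — stratified by label with largest-remainder
apportionment so the total is exact.

**What passing tests show, and what they do not.** The cohorts plant
independent Gaussian attributes; real clinical tables have correlated
attributes, ordinal codings, missingness mechanisms and site effects the
generator does not emulate. Green tests establish that each stage
recovers the structure it is designed to recover under its stated model,
not that the pipeline attains any particular accuracy on hospital data.

## Problem sizes and budgets

Development and test runs use deliberately scaled-down problems chosen as
this package's own test design: optimizer checks at the default
population 10 / 50 generations on 3-gene spheres; feature-selection
recovery on full 1026-row cohorts at `k = 5`, population 10, 25
generations across 10 seeds; detector and capsule tuning on 200-400-row
cohorts at populations 3-5 and 2-4 generations with epoch budgets of
25-60 (extractor) and 20-30 (capsule net). The end-to-end pipeline
example in the acceptance script runs a 300-row cohort at population 4,
3 generations. Full-budget runs scale linearly in population, generations
and epochs.

## Known limitations

* The capsule-network gradient is approximate through the routing
  coefficients (exact elsewhere); training relies on the snapshot rule
  for stability at the top of the learning-rate range.
* The detector's two-stage fit never propagates SVM loss into the
  extractor.
* Chi-square scoring is invariant to the positive scale of the feature
  weights; weights differentiate candidates only through the downstream
  transformed matrix.
* Multi-class severity is collapsed to binary for detection; per-severity
  modelling is out of scope.
* The AF-rate target is synthetic by construction; absolute AF metrics on
  synthetic cohorts say nothing about clinical AF burden estimation.
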