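---
title: "Window-based screening from R-R intervals: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based screening from R-R intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrscreen)
```

## The screening problem

Heart rate variability (HRV) — the beat-to-beat variation of R-R intervals —
reflects autonomic nervous system regulation, and its dysregulation
accompanies psychotic disorders such as schizophrenia and bipolar disorder.
`rrscreen` implements a screening pipeline that classifies *short rolling
windows* of a person's R-R interval recording (60 or 300 consecutive beats,
roughly one or five minutes) and then aggregates the many window-level
decisions into a single person-level call: treatment (patient) versus
control.

Two properties make this harder than generic time-series classification:

* **Recordings, not samples, are the unit of inference.** Overlapping
  windows from one person are extremely dependent; any split that puts
  windows of one person on both sides of a train/test divide leaks
  information. All cross-validation here is therefore *person-confined*:
  every person's windows live in exactly one fold, and the harness asserts
  this on every fit (a violation aborts the run).
* **Window decisions are noisy by design.** A person's physiological state
  varies — brief activity episodes depress R-R intervals and make controls
  look like patients for minutes at a time — so a substantial minority of
  windows will be misclassified even for an easy person. The person-level
  decision rules are built around this: a person is called positive when the
  *fraction* of positive windows exceeds a learned threshold, not when all
  windows agree.

## The synthetic cohort generator

The package ships a generator (`rr_generate_cohort()`) that emulates the
statistical structure the analysis assumes, so the entire pipeline is
testable without any recordings. Each person's sequence is a Gaussian AR(p)
process around a shifted mean,

$$x_t = \mu + \sum_{k=1}^{p} \phi_k (x_{t-k} - \mu) + \varepsilon_t,
  \qquad \varepsilon_t \sim N(0, \sigma^2),$$

with a burn-in of 500 beats discarded (so emitted sequences are
approximately stationary), values clipped at a physiological floor of
200 ms, and Poisson-placed *activity episodes* that multiply a stretch of
beats by $1 - \text{drop}$, mimicking short walks.

The default group profiles (`rr_default_profiles()`) encode the qualitative
contrasts the method exploits, with magnitudes chosen once as conventions —
no quantitative per-group distribution parameters are available to copy, so
the defaults aim at plausible adult resting values with a clearly shorter,
less variable treatment rhythm:

| parameter | control | treatment | rationale |
|---|---|---|---|
| mean R-R $\mu$ | 850 ms | 700 ms | patients have shorter beat-to-beat intervals (elevated heart rate) |
| innovation SD $\sigma$ | 60 ms | 25 ms | patients show lower within-window variance |
| AR coefficients $\phi$ | $(0.85)$ | $(0.30, 0, 0.10, 0.50)$ | control autocorrelation is lag-1 dominant; treatment mass is shifted to lags 3–4 |
| activity episodes | 0.3 / 1000 beats, 15 % drop, 60 beats | same | both groups move occasionally |

The treatment AR vector was chosen (and then frozen) so that the *window-level*
sample ACF orderings are robust: lag-1 mean higher in controls, lag-4 mean
higher in patients, matching the direction of the group contrast the
pipeline is meant to explain. Cohort defaults are 30 + 30 persons with
3600–5400 beats each (roughly 1–1.5 h of recording).

What the generator deliberately does **not** model: raw ECG morphology, QRS
detection error, ectopic beats and artifacts, circadian drift, medication
effects, or the overlap between group distributions seen in real cohorts.
Synthetic groups are *much* better separated than real ones — passing the
label-recovery checks shows the pipeline's plumbing is correct, not that
real-data accuracy would be high. Conversely the no-signal checks (both
groups drawn from one profile) bound optimism: every classifier must stay
near 50 % person accuracy when there is nothing to learn.

## Windowing and cross-validation

`rr_extract_windows()` emits every full-length window with stride 1
($L - w + 1$ windows for a length-$L$ recording; consecutive windows share
$w - 1$ beats). Truncated tail windows are never emitted because every
classifier needs fixed-dimension input. Starts are 0-based, slices
half-open.

`rr_cv()` runs the two-phase, person-confined protocol:

1. **Phase 1 — hyperparameter search.** One of the four training folds (the
   last in fold-index order; the choice is a convention) becomes the
   validation fold, and the method's grid is searched.
2. **Phase 2 — final fit.** The four training folds are merged; one person
   per group (seeded) is held out as the internal validation split that
   threshold learning and early stopping require; the model is retrained
   with the phase-1 hyperparameters and scored once per run on the untouched
   test fold. Stochastic methods default to 5 runs (3 in LOOCV), averaged.

Fold assignment is stratified by group and random under a stated seed — no
manual rebalancing — so at the reference scale every fold holds 6 patients
and 6 controls. Fold membership is hashed so experiments comparing methods
can assert that their test folds are identical.

## Window classifiers

All six methods sit behind `rr_classifier()` and share one contract: fit on
training windows, use only person-disjoint validation windows for tuning,
emit per-window scores/labels, and carry a learned person threshold.

* **`nn1`** — 1-nearest-neighbor, Euclidean distance on raw windows, with a
  100 000-window reference cap (sampled under the seed). Baseline.
* **`mlp`** — single hidden layer of 128 sigmoid units, softmax output,
  cross-entropy, Adam, 100 epochs; learning rate, batch size and both
  decision thresholds are grid-searched on validation person accuracy.
  Implemented in base R with hand-derived backpropagation
  (gradient-checked by finite differences in the test suite).
* **`svm_fsh`** — a wide per-window feature bank, low-variance filtering and
  Mann–Whitney ranking down to 50 features, robust normalization
  (median/IQR, fitted on training only), a balanced subsample of 1500
  windows per class, and an RBF SVM with $C, \gamma \in \{0.1, 1, 10, 100\}$.
  The built-in bank has 64 features (moments, quantiles, ACF/PACF,
  successive-difference HRV statistics, spectral band energies and entropy,
  trend, run/peak counts, Poincaré descriptors); it stands in for a large
  automatic feature bank and does not chase numerical parity with any
  external library.
* **`svm_ensemble`** — bagging with *exclusive* subsets: training windows
  (represented by min/max/var/mean/median) are partitioned into 11 disjoint
  subsets, one RBF SVM per subset, majority vote per window. 11 members is a
  package default (odd, small); member hyperparameters are grid-searched on
  a held-out slice of training persons.
* **`xgboost`** — gradient-boosted trees on raw window values,
  `n_estimators` ∈ {10, 50, 100, 200, 500} × `max_depth` ∈ {5, …, 50}.
* **`gru_fcn`** — a two-path network: a GRU path (1–2 layers, hidden state
  100/200, optional bidirectionality, dropout 0.8 on the final state) and a
  fully convolutional path (three 1-D conv blocks of 128/256/128 kernels,
  sizes 7/5/3, batch norm + ReLU, global average pooling), concatenated into
  a softmax layer. Training: Adam, at most 30 epochs, early stopping on
  validation loss with patience 10, and a scheduler dividing the learning
  rate by 10 after 5 stagnant epochs. Defaults per window length: $w = 60$ —
  lr $10^{-4}$, batch 128, hidden 100; $w = 300$ — lr $10^{-3}$, batch 64,
  hidden 200. The whole network, including backpropagation through the GRU,
  convolutions and batch norm, is implemented in base R matrix algebra and
  verified against finite-difference gradients.

Input conventions (the underlying methods are silent on this, so the
package fixes them): `nn1`/`xgboost` consume raw window values; the MLP
standardizes per position with training-set mean/SD; the GRU+FCN
standardizes globally with the training set's scalar mean/SD. Window labels
inherit the person's diagnosis.

## Person-level aggregation

`rr_positive_ratio()` is the fraction of a person's windows labeled
positive; the decision is strict (`label = 1` iff ratio `> t`), so raising
the threshold can never flip a person from control to treatment. Four
threshold rules are implemented, matched to the classifiers that use them:

* **grid** (`rr_threshold_grid()`): exhaustive search over
  $t \in \{0.01, \dots, 0.99\}$ maximizing validation person accuracy; ties
  break toward 0.50, then toward the lower threshold.
* **ensemble means** (`rr_threshold_ensemble()`): each class's validation
  ratios are cleared of values farther than two sample standard deviations
  from the class mean (a single pass; a set that would empty falls back to
  its unfiltered values), and $t$ is the midpoint of the cleaned class
  means.
* **mid-median** (`rr_threshold_mid_median()`): midpoint of the class-wise
  median scores.
* **minimum variance** (`rr_min_variance_decision()`): the variance of every
  block of 60 consecutive window predictions is computed; among the maximal
  runs of blocks attaining the minimum variance the longest (earliest on a
  tie) is taken, and its majority class is the decision. Sequences shorter
  than one block, and exact majority ties, fall back to the ratio rule.
  The run tie-breaks and the hard-label interpretation of "predictions" are
  package conventions.

A stacking combiner (`rr_stack_fit()`) fits a logistic regression on the
3-bit pattern of three base methods' window predictions (fitted on
validation windows — the natural person-disjoint choice) and thresholds the
fitted probability at 0.5; degenerate single-class fits collapse to a
constant majority model.

## Comparison statistics

`rr_stats_report()` compares methods over shared folds: the Friedman test
(average-rank ties, tie-corrected chi-square), pairwise two-sided Wilcoxon
signed-rank tests (zeros dropped; exact distribution when there are no ties
and at most 25 pairs, else a tie-corrected normal approximation with
continuity correction) with Benjamini–Hochberg adjustment over all pairs,
and paired Cohen's $d = \overline{a - b} / s_{a-b}$ with the sample SD
(undefined-spread pairs yield `NA`). These are implemented from the
definitions; the test suite requires agreement with `stats::friedman.test`,
`stats::wilcox.test` and `stats::p.adjust` to $10^{-8}$ on randomized
inputs, keeping implementation and reference independent.

## Explanation layer

For interpretation the pipeline thins the heavily overlapping window stream
(every 500th window of the person-major, start-minor global ordering — the
ordering itself is a convention), fits a random-forest probe to ten
interpretable columns (mean, min, max, SD, skewness, kurtosis, and lag-1..4
ACF — seven feature families), and attributes its predictions with *exact*
Shapley values.

The attribution engine converts the forest into a plain tree-ensemble
representation (leaf votes, per-node training covers) and computes, for
every instance, the Shapley value of each feature with respect to the
cover-weighted conditional expectation of the ensemble output, by full
enumeration of all $2^p$ feature subsets. Exactness buys two things:
local accuracy — baseline plus attributions equals the model output — holds
by construction (the package still verifies it to $10^{-6}$ and fails hard
otherwise), and the test suite can cross-check the whole engine against an
independent TreeSHAP implementation (xgboost's `predcontrib`) to $10^{-5}$.
Subset enumeration is limited to 15 features; the probe forest is kept
small (40–50 trees, depth-capped) so attribution of a thinned window set
runs in seconds. Model-agnostic sampling explainers are deliberately out of
scope: they would make the explanation layer stochastic.

`rr_acf_group_table()` summarizes per-window lag-1..4 ACF by group and
window length (mean ± SD; constant windows are excluded per cell with
counts recorded). On the default synthetic cohort the table reproduces the
documented direction of the group contrast: lag-1 autocorrelation is higher
in controls, lag-4 higher in patients, at both window lengths.

## Numerical conventions and degenerate inputs

* Variance and SD are sample statistics ($n - 1$) throughout; skewness is
  moment-based Fisher $g_1$; kurtosis is excess $g_2$.
* The sample ACF uses the biased estimator with the window mean and
  $r_0 = 1$; constant windows yield `NA`, which downstream selection and
  summaries drop explicitly.
* The low-variance cutoff in feature selection is $10^{-10}$ *after* robust
  normalization; the Mann–Whitney test is two-sided; p-value ties in the
  ranking break by feature name.
* Robust normalization passes zero-IQR features through centered; it is not
  idempotent (re-fitting on normalized data renormalizes to median 0,
  IQR 1).
* All stochastic operations run under derived child seeds; identical
  (inputs, seed) pairs reproduce bit-identically on one platform.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run everything end to end on
synthetic cohorts sized so the full battery completes on a single CPU:
label-recovery uses the default profiles at 30 + 30 persons × 3000 beats
(about 176 000 windows at $w = 60$) with `svm_ensemble` and `xgboost` and
reduced-but-in-range hyperparameter grids; the no-signal calibration band
runs all six methods over 20 seeds on 6 + 6-person cohorts with reduced
training budgets (small hidden layers, few epochs, single grid cells) —
calibration under the null does not depend on cohort size or model
capacity, which is what makes the reduction sound; deep-method
configurations at full defaults are exercised on small cohorts. Oracle
checks (ACF, thresholds, minimum variance, statistics) run at their stated
sizes (100–200 randomized cases).

## Known limitations

* The synthetic generator's separation makes absolute accuracies
  optimistic; only orderings, calibration bands and exactness checks carry
  over to real data.
* The GRU+FCN and MLP are base-R implementations: correct (gradient-checked)
  but slower than GPU frameworks; paper-scale training budgets on paper-scale
  cohorts are expensive, which is why the shipped experiments scale the
  cohort, not the protocol.
* Exact Shapley enumeration is exponential in the number of features — by
  design, for the 10-column explanatory set; it is not a general-purpose
  explainer.
* `nn1` stores its reference windows; memory grows with the cap.
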