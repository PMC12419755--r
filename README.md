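# rrscreen

Person-level screening for psychotic disorders (schizophrenia / bipolar
disorder) from beat-to-beat heart-interval recordings.

## The problem

Autonomic nervous system dysregulation changes heart rate variability: the
beat-to-beat (R-R) intervals of patients tend to be shorter, less variable,
and differently autocorrelated than those of controls. `rrscreen`
implements a complete analysis pipeline for this signal, aimed at
researchers evaluating HRV-based screening protocols:

* **Rolling windows.** Each recording is cut into step-1 rolling windows of
  `w ∈ {60, 300}` consecutive R-R intervals (≈1 or 5 minutes); a recording
  of length `L` yields `L − w + 1` windows overlapping in `w − 1` beats.
* **Window classifiers.** Six methods behind one `rr_classifier()`
  contract: 1-nearest-neighbor (`nn1`), a single-hidden-layer perceptron
  (`mlp`, 128 sigmoid units, Adam), an RBF SVM on hypothesis-test-selected
  features (`svm_fsh`), a bagged ensemble of SVMs on disjoint training
  subsets with majority vote (`svm_ensemble`), gradient-boosted trees
  (`xgboost`), and a GRU + fully-convolutional-network hybrid (`gru_fcn`,
  conv blocks 128/256/128 with kernels 7/5/3). The neural networks are
  implemented in base R with hand-derived, gradient-checked
  backpropagation.
* **Person aggregation.** A person is called positive when their fraction
  of positive windows strictly exceeds a learned threshold `t`. Rules:
  grid search over {0.01, …, 0.99}, outlier-cleaned class-mean midpoints,
  class-median midpoints, a minimum-variance stable-segment criterion, and
  a logistic stacking combiner over three base methods.
* **Person-confined evaluation.** Two-phase 5-fold CV (`rr_cv()`) and
  leave-one-person-out CV (`rr_loocv()`); all windows of a person stay in
  one fold, leakage is asserted on every fit, and fold membership is hashed
  so method comparisons provably share test folds.
* **Statistics.** Friedman test across methods over folds, pairwise
  Wilcoxon signed-rank with Benjamini–Hochberg correction, paired Cohen's
  *d* (`rr_stats_report()`), validated against base R's implementations to
  1e-8.
* **Explanation.** A random-forest probe on ten interpretable per-window
  columns (mean, min, max, SD, skewness, kurtosis, lag-1..4 ACF) with
  *exact* Shapley attributions (full subset enumeration over the
  tree-ensemble conditional expectation; local accuracy guaranteed and
  verified), plus group-level ACF summary tables (`rr_acf_group_table()`).
* **Synthetic cohorts.** `rr_generate_cohort()` simulates R-R recordings as
  mean-shifted AR(p) processes with group-dependent mean, dispersion and
  lag structure plus transient activity episodes, so the entire pipeline is
  testable without data downloads.

## Worked example

```r
library(rrscreen)

## a small synthetic cohort: 10 controls + 10 patients, 500 beats each
co <- rr_generate_cohort(rr_cohort_spec(10, 10, beats_per_person = 500, seed = 3))
co
#> R-R cohort: 20 persons (control: 10, treatment: 10), 500-500 beats each

## person-confined 5-fold CV with the bagged SVM ensemble, 1-minute windows
cv <- rr_cv(co, "svm_ensemble", w = 60, k = 5, seed = 2,
            spec = list(n_members = 5, cost_grid = c(1, 10),
                        gamma_grid = c(0.1, 1)))
cv
#> kfold cross-validation [svm_ensemble], w = 60, 5 fold(s), 1 run(s)
#>   test window accuracy: 99.30 +/- 0.98 %
#>   test person accuracy: 100.00 +/- 0.00 %

head(cv$decisions[, c("fold", "person_id", "true_group",
                      "positive_ratio", "threshold", "label")], 4)
#>   fold person_id true_group positive_ratio threshold label
#> 1    1      C001    control      0.0000000       0.5     0
#> 2    1      C006    control      0.0000000       0.5     0
#> 3    1      T004  treatment      0.9206349       0.5     1
#> 4    1      T010  treatment      1.0000000       0.5     1

## lag-structured autocorrelation by group
print(rr_acf_group_table(co, w = 60), digits = 3)
#>   lag  w control_mean control_sd treatment_mean treatment_sd n_excluded
#> 1   1 60        0.793     0.0888          0.347        0.183          0
#> 2   2 60        0.630     0.1463          0.149        0.261          0
#> 3   3 60        0.499     0.1828          0.228        0.206          0
#> 4   4 60        0.387     0.2046          0.471        0.128          0
```

Reading the output: every test-fold person's `positive_ratio` (fraction of
their ~440 windows classified as treatment) is compared with the learned
threshold; here the groups are cleanly separated, so all 20 persons are
called correctly even though ~0.7 % of individual windows are not. The ACF
table shows the group signature the explanation layer is built around:
lag-1 autocorrelation is higher in controls, lag-4 higher in patients.

For model interpretation:

```r
wins  <- rr_subsample_every_k(rr_cohort_windows(co, 60), 100)
probe <- rr_rf_probe(wins, k = 5, seed = 1)
att   <- rr_shap_attribution(probe$ensemble, probe$features)
att$ranking          # features by mean |Shapley value|
```

## Layout

```
R/                  implementation (synthetic data, windowing, features,
                    classifiers, aggregation, evaluation, stats, explain)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R  end-to-end acceptance analytics
vignettes/          methods vignette (model, parameters, design choices)
```
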