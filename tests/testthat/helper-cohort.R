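# Shared fixtures, generated in code. Small cohorts are cached per option
# set so independent tests do not regenerate them.

.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function(nc = 4, nt = 4, beats = 300, seed = 101) {
  key <- paste(nc, nt, beats, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- rr_generate_cohort(
      rr_cohort_spec(nc, nt, beats_per_person = beats, seed = seed))
  .fixture_env[[key]]
}

## A cohort whose two groups are drawn from one distribution (no signal).
null_cohort <- function(nc = 6, nt = 6, beats = 350, seed = 11) {
  base <- rr_default_profiles()$control
  trt <- rr_profile("treatment", mu_rr = base$mu_rr,
                    sigma_innov = base$sigma_innov,
                    ar_coeffs = base$ar_coeffs,
                    activity_rate = base$activity_rate,
                    activity_drop = base$activity_drop,
                    activity_len = base$activity_len)
  rr_generate_cohort(rr_cohort_spec(nc, nt, beats_per_person = beats,
                                    treatment_profile = trt, seed = seed))
}

## Reduced method configurations used by calibration checks (small nets and
## grids so that many repetitions fit in a test run).
small_specs <- function() {
  list(
    nn1 = list(ref_cap = 2000L),
    mlp = list(lr_grid = 1e-3, batch_grid = 256L, epochs = 15L, hidden = 32L),
    svm_fsh = list(cost_grid = 1, gamma_grid = 0.1, per_class = 400L),
    svm_ensemble = list(n_members = 5L, cost_grid = 1, gamma_grid = 0.1),
    xgboost = list(n_estimators = 50L, max_depth = 5L),
    gru_fcn = list(hidden = 8L, conv_channels = c(8L, 12L, 8L),
                   kernels = c(7L, 5L, 3L), epochs = 2L, batch = 256L,
                   lr = 1e-3, dropout = 0.2)
  )
}

## Independent double-loop sample ACF oracle (kept deliberately naive).
acf_oracle <- function(x, k) {
  n <- length(x)
  m <- mean(x)
  num <- 0
  for (t in seq_len(n - k)) num <- num + (x[t] - m) * (x[t + k] - m)
  den <- 0
  for (t in seq_len(n)) den <- den + (x[t] - m)^2
  num / den
}

## Independent grid-threshold oracle: plain enumeration with the documented
## tie rules.
grid_threshold_oracle <- function(ratios, truth) {
  cand <- seq(0.01, 0.99, by = 0.01)
  acc <- sapply(cand, function(t) mean(as.integer(ratios > t) == truth))
  best <- cand[acc == max(acc)]
  best[order(abs(best - 0.5), best)][1]
}

## Independent minimum-variance oracle: scan all blocks with stats::var.
min_variance_oracle <- function(preds, block = 60, t = 0.5) {
  n <- length(preds)
  if (n < block) return(as.integer(mean(preds) > t))
  v <- sapply(seq_len(n - block + 1), function(i)
    stats::var(preds[i:(i + block - 1)]))
  vmin <- min(v)
  at <- v <= vmin + 1e-12
  r <- rle(at)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[order(-r$lengths[runs], starts[runs])][1]
  covered <- preds[starts[best]:(ends[best] + block - 1)]
  if (mean(covered) == 0.5) return(as.integer(mean(preds) > t))
  as.integer(mean(covered) > 0.5)
}
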