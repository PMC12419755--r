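## Explanation layer: ordinal subsampling of the global window stream, a
## random-forest probe on the interpretable 7-family feature set, exact
## Shapley attributions for that probe, and the group-level lag-1..4 ACF
## summary table.

#' Keep every k-th window of an ordered window stream
#'
#' Selects ordinal positions 0, k, 2k, ... of the global window ordering
#' (person-major, start-minor), preserving order. Used to thin the heavily
#' overlapping rolling-window stream before fitting the explanation probe.
#'
#' @param windows An `rr_windows` object.
#' @param k Subsampling period (>= 1); `k = 1` is the identity.
#' @return An `rr_windows` object.
#' @export
rr_subsample_every_k <- function(windows, k = 500L) {
  stopifnot(inherits(windows, "rr_windows"), k >= 1)
  n <- nrow(windows$values)
  windows_subset(windows, seq.int(1L, n, by = as.integer(k)))
}

#' Random-forest probe on the interpretable feature set
#'
#' Fits a random forest to the `explain7` features of a (typically
#' subsampled) window set and reports person-confined k-fold window
#' accuracy. The forest refitted on all supplied windows is retained, with
#' its attribution representation, for [rr_shap_attribution()]. The forest
#' is deliberately small and depth-capped (defaults: 50 trees, 32 terminal
#' nodes) so exact attribution stays cheap; hyperparameters are recorded in
#' the result.
#'
#' @param windows An `rr_windows` object (windows of both groups).
#' @param k Number of person-confined folds (default 5).
#' @param seed Integer seed.
#' @param ntree,maxnodes,nodesize Random-forest size controls.
#' @return Object of class `rr_rf_probe`: `accuracy` (percent), `fold_acc`,
#'   `model`, `ensemble` (attribution representation), `features` (the
#'   feature matrix), `labels`, and `meta`.
#' @export
rr_rf_probe <- function(windows, k = 5L, seed = 1L, ntree = 50L,
                        maxnodes = 32L, nodesize = 5L) {
  stopifnot(inherits(windows, "rr_windows"))
  x <- rr_explain7(windows)
  ok <- stats::complete.cases(x)
  if (any(!ok)) rr_log(sum(!ok), " window(s) with degenerate features dropped")
  x <- x[ok, , drop = FALSE]
  labels <- windows$label[ok]
  person <- windows$person_id[ok]
  group <- windows$group[ok]

  ## person-confined, group-stratified fold assignment
  persons <- unique(person)
  pgroup <- group[match(persons, person)]
  fold_of <- with_seed(seed, {
    out <- integer(length(persons)); names(out) <- persons
    for (g in unique(pgroup)) {
      ids <- sample(persons[pgroup == g])
      out[ids] <- rep_len(seq_len(k), length(ids))
    }
    out
  })
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- person %in% names(fold_of)[fold_of == f]
    if (length(unique(labels[!te])) < 2 || sum(te) == 0)
      stop2("single-class fold in rf probe; use more persons or fewer folds")
    rf <- with_seed(child_seed(seed, f),
                    randomForest::randomForest(
                      x[!te, , drop = FALSE],
                      factor(labels[!te], levels = c(0, 1)),
                      ntree = ntree, maxnodes = maxnodes,
                      nodesize = nodesize))
    pred <- stats::predict(rf, x[te, , drop = FALSE])
    fold_acc[f] <- 100 * mean(pred == labels[te])
  }

  model <- with_seed(child_seed(seed, 999),
                     randomForest::randomForest(
                       x, factor(labels, levels = c(0, 1)),
                       ntree = ntree, maxnodes = maxnodes,
                       nodesize = nodesize))
  structure(list(accuracy = mean(fold_acc), fold_acc = fold_acc,
                 model = model,
                 ensemble = rr_ensemble_from_rf(model, x),
                 features = x, labels = labels,
                 meta = list(ntree = ntree, maxnodes = maxnodes,
                             nodesize = nodesize, k = k, seed = seed,
                             n_windows = nrow(x))),
            class = "rr_rf_probe")
}

#' @export
print.rr_rf_probe <- function(x, ...) {
  cat(sprintf(
    "random-forest probe: %.1f%% window accuracy (%d-fold, %d windows)\n",
    x$accuracy, x$meta$k, x$meta$n_windows))
  invisible(x)
}

#' Group summary of per-window ACF at lags 1-4
#'
#' Mean and standard deviation of the per-window sample autocorrelation at
#' lags 1..4, stratified by group and window length. Constant windows
#' contribute missing ACF values and are excluded per cell, with counts
#' recorded.
#'
#' @param cohort An `rr_cohort`.
#' @param w Window lengths to tabulate (default `c(60, 300)`).
#' @param lags Lags to tabulate (default `1:4`).
#' @return data.frame with one row per (lag, w): columns `lag`, `w`,
#'   `control_mean`, `control_sd`, `treatment_mean`, `treatment_sd`,
#'   `n_excluded`.
#' @export
rr_acf_group_table <- function(cohort, w = c(60L, 300L), lags = 1:4) {
  stopifnot(inherits(cohort, "rr_cohort"))
  rows <- list()
  for (wl in w) {
    wins <- rr_cohort_windows(cohort, wl)
    if (nrow(wins$values) < 2) stop2("fewer than 2 windows at w = ", wl)
    for (lg in lags) {
      a <- row_acf(wins$values, lg)
      excl <- sum(!is.finite(a))
      if (excl > 0) rr_log(excl, " constant window(s) excluded at lag ", lg)
      ctrl <- a[wins$group == "control" & is.finite(a)]
      trt <- a[wins$group == "treatment" & is.finite(a)]
      if (length(ctrl) < 2 || length(trt) < 2)
        stop2("need >= 2 windows per stratum")
      rows[[length(rows) + 1]] <- data.frame(
        lag = lg, w = wl,
        control_mean = mean(ctrl), control_sd = stats::sd(ctrl),
        treatment_mean = mean(trt), treatment_sd = stats::sd(trt),
        n_excluded = excl)
    }
  }
  do.call(rbind, rows)
}

#' Plot-ready attribution tables
#'
#' Converts an [rr_shap_attribution()] result into long-form tables: a
#' bee-swarm table (one row per instance x feature, with the feature value)
#' and a heatmap table (instances ordered by model output).
#'
#' @param attribution An `rr_attribution`.
#' @param x The instance feature matrix the attribution was computed on.
#' @return List with data.frames `beeswarm` and `heatmap`.
#' @export
rr_attribution_tables <- function(attribution, x) {
  stopifnot(inherits(attribution, "rr_attribution"))
  x <- as.matrix(x)
  sh <- attribution$shap
  stopifnot(all(dim(x) == dim(sh)))
  bees <- data.frame(
    instance = rep(seq_len(nrow(sh)), ncol(sh)),
    feature = rep(colnames(sh), each = nrow(sh)),
    shap = as.vector(sh),
    feature_value = as.vector(x))
  ord <- attribution$order
  heat <- data.frame(instance = ord,
                     model_output = attribution$output[ord])
  heat <- cbind(heat, as.data.frame(sh[ord, , drop = FALSE]))
  list(beeswarm = bees, heatmap = heat)
}
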