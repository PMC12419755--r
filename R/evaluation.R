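## Experiment orchestration: person-confined two-phase k-fold CV and LOOCV.
##
## Per fold: phase 1 designates the last training fold (in fold-index order)
## as the validation set and lets the method search its hyperparameter grid;
## phase 2 retrains on the merged training folds with the chosen values,
## holding out one person per group (seeded) as the internal validation
## split that threshold learning / early stopping require. The test fold is
## scored once per run; stochastic methods are repeated and averaged.
## Leakage guards run on every split; the fold plan is hashed so that
## experiments comparing methods can assert identical test folds.

#' Window- and person-level accuracy
#'
#' @param window_labels Predicted 0/1 labels over test windows.
#' @param window_truth True 0/1 labels over the same windows.
#' @param person_labels Predicted 0/1 labels per person.
#' @param person_truth True 0/1 labels per person.
#' @return List with `window_pct` and `person_pct` (percent, 0-100).
#' @export
rr_accuracies <- function(window_labels, window_truth,
                          person_labels, person_truth) {
  stopifnot(length(window_labels) == length(window_truth),
            length(person_labels) == length(person_truth))
  list(window_pct = 100 * mean(window_labels == window_truth),
       person_pct = 100 * mean(person_labels == person_truth))
}

## Default repetition counts: deep methods are averaged over several
## training runs (5 for k-fold, 3 for LOOCV); the others are deterministic
## under the run seed.
default_runs <- function(method, mode) {
  if (method %in% c("mlp", "gru_fcn")) {
    if (mode == "loo") 3L else 5L
  } else 1L
}

phase1_needed <- function(method, spec) {
  len <- function(x, d) length(x %||% d)
  switch(method,
         mlp = len(spec$lr_grid, c(1e-3, 1e-4, 1e-5)) *
               len(spec$batch_grid, c(256, 512, 1024)) > 1,
         svm_fsh = len(spec$cost_grid, c(0.1, 1, 10, 100)) *
                   len(spec$gamma_grid, c(0.1, 1, 10, 100)) > 1,
         svm_ensemble = len(spec$cost_grid, c(0.1, 1, 10, 100)) *
                        len(spec$gamma_grid, c(0.1, 1, 10, 100)) > 1,
         xgboost = len(spec$n_estimators, c(10, 50, 100, 200, 500)) *
                   len(spec$max_depth, seq(5, 50, by = 5)) > 1,
         FALSE)
}

fix_hypers <- function(method, spec, meta) {
  switch(method,
         mlp = utils::modifyList(spec, list(lr_grid = meta$learning_rate,
                                            batch_grid = meta$batch_size)),
         svm_fsh = utils::modifyList(spec, list(cost_grid = meta$cost,
                                                gamma_grid = meta$gamma)),
         svm_ensemble = utils::modifyList(spec, list(cost_grid = meta$cost,
                                                     gamma_grid = meta$gamma)),
         xgboost = utils::modifyList(spec,
                                     list(n_estimators = meta$n_estimators,
                                          max_depth = meta$max_depth)),
         spec)
}

## One person per group held out of `train_persons` as the phase-2 internal
## validation split. Groups with a single training person are never emptied;
## if every group is a singleton (tiny cohorts), one person overall is held
## out so the split always exists.
internal_split <- function(train_persons, groups, seed) {
  by_group <- split(train_persons, groups[train_persons])
  held <- with_seed(seed, {
    h <- unlist(lapply(by_group, function(p)
      if (length(p) > 1) sample(p, 1) else character(0)))
    if (length(h) == 0) h <- sample(train_persons, 1)
    h
  })
  list(val = unname(held), train = setdiff(train_persons, held))
}

eval_fold <- function(windows_all, person_group, train_persons, test_persons,
                      method, spec, seed, runs, min_variance) {
  assert_no_leakage(train_persons, test_persons, "eval_fold")
  test_w <- windows_for_persons(windows_all, test_persons)

  ## phase 2 (x runs): retrain on the merged training folds with an internal
  ## one-person-per-group validation split
  out <- vector("list", runs)
  for (r in seq_len(runs)) {
    sp <- internal_split(train_persons, person_group, child_seed(seed, 500 + r))
    tr_w <- windows_for_persons(windows_all, sp$train)
    va_w <- windows_for_persons(windows_all, sp$val)
    assert_no_leakage(c(sp$train, sp$val), test_persons, "phase 2")
    fit <- rr_classifier(tr_w, va_w, method, spec = spec,
                         seed = child_seed(seed, 900 + r))
    dec <- rr_person_predict(fit, test_w, min_variance = min_variance)
    wl <- predict(fit, test_w, type = "label")
    acc <- rr_accuracies(wl, test_w$label,
                         dec$label, as.integer(dec$true_group == "treatment"))
    out[[r]] <- list(acc = acc, dec = dec, meta = fit$meta)
  }
  list(window_acc = mean(vapply(out, function(o) o$acc$window_pct, numeric(1))),
       person_acc = mean(vapply(out, function(o) o$acc$person_pct, numeric(1))),
       per_run = out)
}

#' Person-confined k-fold cross-validation
#'
#' Runs the two-phase evaluation protocol for one method and window length:
#' per test fold, hyperparameters are chosen on a designated validation fold
#' (the last training fold in fold-index order), the model is then retrained
#' on all training folds (with a one-person-per-group internal validation
#' split for thresholds/early stopping) and scored on the untouched test
#' fold. Stochastic methods are repeated `runs` times per fold and averaged.
#'
#' @param cohort An `rr_cohort`.
#' @param method Classifier name, see [rr_classifier()]; `"oracle"` (reads
#'   the true labels) and `"constant"` (always positive) are available as
#'   harness calibration baselines.
#' @param w Window length (default 60).
#' @param k Number of folds (default 5).
#' @param seed Integer seed driving fold assignment, sub-splits and fits.
#' @param runs Training repetitions per fold; default depends on the method.
#' @param spec Method options, see [rr_classifier()].
#' @param min_variance Use the minimum-variance person rule.
#' @param plan Optional pre-built [rr_assign_folds()] plan (use to share
#'   identical test folds across methods).
#' @return Object of class `rr_cv`: per-fold accuracies, per-person
#'   decisions, chosen hyperparameters, summary mean/sd, and the fold-plan
#'   hash.
#' @export
rr_cv <- function(cohort, method, w = 60L, k = 5L, seed = 1L, runs = NULL,
                  spec = list(), min_variance = FALSE, plan = NULL) {
  stopifnot(inherits(cohort, "rr_cohort"))
  plan <- plan %||% rr_assign_folds(cohort, k, child_seed(seed, 0))
  runs <- runs %||% default_runs(method, plan$mode)
  windows_all <- rr_cohort_windows(cohort, w)
  if (any(!cohort$manifest$person_id %in% windows_all$person_id))
    stop2("some persons have no window of length ", w)
  person_group <- stats::setNames(cohort$manifest$group,
                                  cohort$manifest$person_id)

  folds <- data.frame()
  decisions <- list()
  metas <- list()
  for (f in seq_len(plan$k)) {
    test_persons <- fold_persons(plan, f)
    train_folds <- setdiff(seq_len(plan$k), f)
    spec_f <- spec
    if (method %in% c("nn1", "mlp", "svm_fsh", "svm_ensemble", "xgboost",
                      "gru_fcn") && phase1_needed(method, spec)) {
      val_fold <- train_folds[length(train_folds)]
      p1_train <- unlist(lapply(setdiff(train_folds, val_fold),
                                fold_persons, plan = plan))
      p1_val <- fold_persons(plan, val_fold)
      fit1 <- rr_classifier(windows_for_persons(windows_all, p1_train),
                            windows_for_persons(windows_all, p1_val),
                            method, spec = spec,
                            seed = child_seed(seed, 100 + f))
      spec_f <- fix_hypers(method, spec, fit1$meta)
      metas[[f]] <- fit1$meta
    }
    train_persons <- unlist(lapply(train_folds, fold_persons, plan = plan))
    res <- eval_fold(windows_all, person_group, train_persons, test_persons,
                     method, spec_f, child_seed(seed, 1000 * f), runs,
                     min_variance)
    folds <- rbind(folds, data.frame(fold = f, window_acc = res$window_acc,
                                     person_acc = res$person_acc))
    decisions[[f]] <- cbind(fold = f, res$per_run[[1]]$dec)
    if (is.null(metas[f][[1]])) metas[f] <- list(res$per_run[[1]]$meta)
  }
  new_rr_cv(method, w, plan, runs, folds, decisions, metas)
}

#' Leave-one-person-out cross-validation
#'
#' Each person in turn is the entire test set; all other persons form
#' training plus the internal validation split. Hyperparameter grids, if
#' non-trivial, are searched on that internal split; the supplementary
#' protocol skips the separate phase-1 fold.
#'
#' @inheritParams rr_cv
#' @return An `rr_cv` object with `mode = "loo"`, one fold per person.
#' @export
rr_loocv <- function(cohort, method, w = 60L, seed = 1L, runs = NULL,
                     spec = list(), min_variance = FALSE) {
  stopifnot(inherits(cohort, "rr_cohort"))
  plan <- rr_loo_plan(cohort)
  runs <- runs %||% default_runs(method, "loo")
  windows_all <- rr_cohort_windows(cohort, w)
  person_group <- stats::setNames(cohort$manifest$group,
                                  cohort$manifest$person_id)
  folds <- data.frame()
  decisions <- list()
  metas <- list()
  for (f in seq_len(plan$k)) {
    test_persons <- fold_persons(plan, f)
    train_persons <- setdiff(cohort$manifest$person_id, test_persons)
    res <- eval_fold(windows_all, person_group, train_persons, test_persons,
                     method, spec, child_seed(seed, 1000 * f), runs,
                     min_variance)
    folds <- rbind(folds, data.frame(fold = f, window_acc = res$window_acc,
                                     person_acc = res$person_acc))
    decisions[[f]] <- cbind(fold = f, res$per_run[[1]]$dec)
    metas[[f]] <- res$per_run[[1]]$meta
  }
  new_rr_cv(method, w, plan, runs, folds, decisions, metas)
}

new_rr_cv <- function(method, w, plan, runs, folds, decisions, metas) {
  structure(list(method = method, w = w, mode = plan$mode, k = plan$k,
                 runs = runs, folds = folds,
                 decisions = do.call(rbind, decisions),
                 metas = metas,
                 fold_hash = fold_hash(plan),
                 summary = data.frame(
                   metric = c("window_acc", "person_acc"),
                   mean = c(mean(folds$window_acc), mean(folds$person_acc)),
                   sd = c(stats::sd(folds$window_acc),
                          stats::sd(folds$person_acc)))),
            class = "rr_cv")
}

#' @export
print.rr_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation [%s], w = %d, %d fold(s), %d run(s)\n",
              x$mode, x$method, x$w, x$k, x$runs))
  s <- x$summary
  cat(sprintf("  test window accuracy: %.2f +/- %.2f %%\n",
              s$mean[1], ifelse(is.na(s$sd[1]), 0, s$sd[1])))
  cat(sprintf("  test person accuracy: %.2f +/- %.2f %%\n",
              s$mean[2], ifelse(is.na(s$sd[2]), 0, s$sd[2])))
  invisible(x)
}

#' @export
summary.rr_cv <- function(object, ...) {
  print(object)
  cat("per-fold accuracies:\n")
  print(object$folds, row.names = FALSE)
  invisible(object$folds)
}

## Oracle / constant baselines for harness calibration ---------------------

fit_oracle <- function(train, validation, spec, seed) {
  structure(list(person_rule = "fixed", person_threshold = 0.5, meta = list(),
                 w = train$w),
            class = c("rr_oracle", "rr_classifier"))
}

#' @export
predict_windows.rr_oracle <- function(object, windows, type) {
  if (type == "label") windows$label else as.numeric(windows$label)
}

fit_constant <- function(train, validation, spec, seed) {
  structure(list(value = spec$value %||% 1L, person_rule = "fixed",
                 person_threshold = 0.5, meta = list(), w = train$w),
            class = c("rr_constant", "rr_classifier"))
}

#' @export
predict_windows.rr_constant <- function(object, windows, type) {
  rep(if (type == "label") as.integer(object$value) else
    as.numeric(object$value), nrow(windows$values))
}

#' Accuracy matrix from a list of cross-validation results
#'
#' Stacks per-fold accuracies of several methods into the methods x folds
#' matrix consumed by [rr_stats_report()], asserting first (via the stored
#' fold hash) that all results used identical test folds.
#'
#' @param results Named list of `rr_cv` objects sharing one fold plan.
#' @param metric `"person_acc"` or `"window_acc"`.
#' @return Numeric matrix, methods in rows, folds in columns.
#' @export
rr_cv_matrix <- function(results, metric = c("person_acc", "window_acc")) {
  metric <- match.arg(metric)
  stopifnot(length(results) >= 2)
  hashes <- vapply(results, `[[`, character(1), "fold_hash")
  if (length(unique(hashes)) != 1)
    stop2("cross-validation results do not share identical test folds")
  out <- t(vapply(results, function(r) r$folds[[metric]],
                  numeric(nrow(results[[1]]$folds))))
  rownames(out) <- names(results) %||%
    vapply(results, `[[`, character(1), "method")
  out
}
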