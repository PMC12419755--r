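## Window classifiers behind one contract: fit on training windows (plus a
## person-disjoint validation split where the method needs one), emit
## per-window positive-class scores/labels, and carry a learned person-level
## decision threshold. Constructor: rr_classifier(); prediction:
## predict(<fit>, windows); person calls: rr_person_predict().

#' Fit a window classifier
#'
#' One entry point for the six window-classification methods. Every method
#' is fitted on the training windows only; the validation windows (from
#' persons disjoint from training — enforced) are used for hyperparameter
#' selection, early stopping and person-threshold learning, as each method
#' requires. The returned object predicts per-window positive-class scores
#' and labels and carries the learned person threshold and aggregation rule.
#'
#' Methods and their hyperparameter grids (subsets may be supplied through
#' `spec` to shrink a search):
#' \describe{
#'   \item{`nn1`}{1-nearest neighbor, Euclidean distance on raw window
#'     values, reference set capped at `ref_cap` (default 100000) windows
#'     sampled without replacement. Person threshold by grid search.}
#'   \item{`mlp`}{Single-hidden-layer perceptron (128 sigmoid units, softmax
#'     output) trained with Adam and cross-entropy for `epochs` (default
#'     100); grid over learning rate \{1e-3, 1e-4, 1e-5\} and batch size
#'     \{256, 512, 1024\}; window and person thresholds from
#'     \{0.01, ..., 0.99\}, all chosen by validation person accuracy.}
#'   \item{`svm_fsh`}{Feature-bank extraction, low-variance filter +
#'     Mann-Whitney selection of <= 50 features, robust normalization,
#'     balanced subsample of 1500 windows per class, RBF SVM with C and
#'     gamma from \{0.1, 1, 10, 100\} chosen on validation windows; person
#'     threshold as midpoint of class-wise median ratios.}
#'   \item{`svm_ensemble`}{Bagging: training windows (summary5 features)
#'     split into `n_members` (default 11, odd) disjoint subsets, one RBF
#'     SVM per subset, majority vote per window; person threshold from
#'     outlier-cleaned class mean ratios.}
#'   \item{`xgboost`}{Gradient-boosted trees on raw window values; grid over
#'     `n_estimators` \{10, 50, 100, 200, 500\} and `max_depth`
#'     \{5, 10, ..., 50\} by validation window accuracy; person threshold by
#'     grid search with ties toward 50\%.}
#'   \item{`gru_fcn`}{GRU + fully convolutional network hybrid (conv blocks
#'     128/256/128, kernels 7/5/3, batch norm + ReLU, global average
#'     pooling), trained <= 30 epochs with early stopping (patience 10) and
#'     a learning-rate scheduler (patience 5, divide by 10). Default
#'     configuration depends on `w`; see [rr_grufcn_config()].}
#' }
#'
#' @param train An `rr_windows` object of training windows.
#' @param validation An `rr_windows` object from persons disjoint from
#'   training persons.
#' @param method One of `"nn1"`, `"mlp"`, `"svm_fsh"`, `"svm_ensemble"`,
#'   `"xgboost"`, `"gru_fcn"`.
#' @param spec Named list of method options overriding the defaults above
#'   (e.g. `list(lr_grid = 1e-3, n_members = 5)`).
#' @param seed Integer seed; fits are reproducible given (inputs, seed).
#' @return Object of class `c("rr_<method>", "rr_classifier")` with at least
#'   `method`, `w`, `person_threshold`, `person_rule` and `meta` (chosen
#'   hyperparameters).
#' @examples
#' co <- rr_generate_cohort(rr_cohort_spec(4, 4, beats_per_person = 200, seed = 1))
#' tr <- rr_cohort_windows(co, 60, persons = c("C001", "C002", "T001", "T002"))
#' va <- rr_cohort_windows(co, 60, persons = c("C003", "T003"))
#' fit <- rr_classifier(tr, va, "nn1", spec = list(ref_cap = 500), seed = 1)
#' fit
#' @export
rr_classifier <- function(train, validation,
                          method = c("nn1", "mlp", "svm_fsh", "svm_ensemble",
                                     "xgboost", "gru_fcn", "oracle",
                                     "constant"),
                          spec = list(), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(train, "rr_windows"), inherits(validation, "rr_windows"))
  if (nrow(train$values) < 1) stop2("no training windows")
  if (nrow(validation$values) < 1) stop2("empty validation set")
  if (train$w != validation$w) stop2("mixed window lengths")
  assert_no_leakage(train$person_id, validation$person_id, "rr_classifier")
  fit <- switch(method,
                nn1 = fit_nn1(train, validation, spec, seed),
                mlp = fit_mlp(train, validation, spec, seed),
                svm_fsh = fit_svm_fsh(train, validation, spec, seed),
                svm_ensemble = fit_svm_ensemble(train, validation, spec, seed),
                xgboost = fit_xgb(train, validation, spec, seed),
                gru_fcn = fit_grufcn(train, validation, spec, seed),
                oracle = fit_oracle(train, validation, spec, seed),
                constant = fit_constant(train, validation, spec, seed))
  fit$method <- method
  fit$w <- train$w
  fit$seed <- seed
  class(fit) <- c(paste0("rr_", method), "rr_classifier")
  fit
}

#' @export
print.rr_classifier <- function(x, ...) {
  cat(sprintf("rrscreen window classifier [%s], w = %d\n", x$method, x$w))
  cat(sprintf("  person rule: %s, threshold t = %.4f\n",
              x$person_rule, x$person_threshold))
  if (length(x$meta))
    cat("  chosen:", paste(names(x$meta), unlist(x$meta), sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rr_classifier <- function(object, ...) print(object)

#' Predict window scores or labels
#'
#' @param object A fitted `rr_classifier`.
#' @param windows An `rr_windows` object of the same window length.
#' @param type `"label"` (0/1 per window) or `"score"` (positive-class
#'   probability, or a signed decision value for margin-based methods).
#' @param ... Unused.
#' @return Numeric vector, one element per window.
#' @export
predict.rr_classifier <- function(object, windows,
                                  type = c("label", "score"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(windows, "rr_windows"))
  if (windows$w != object$w) stop2("window length mismatch")
  predict_windows(object, windows, type)
}

predict_windows <- function(object, windows, type) UseMethod("predict_windows")

#' Person-level decisions from a fitted classifier
#'
#' Predicts window labels for the supplied windows and aggregates them per
#' person with the classifier's learned threshold and rule.
#'
#' @param object A fitted `rr_classifier`.
#' @param windows An `rr_windows` object.
#' @param min_variance Use the minimum-variance criterion instead of the
#'   ratio rule (threshold retained for its fallback).
#' @return data.frame as in [rr_person_decisions()], plus a `true_group`
#'   column.
#' @export
rr_person_predict <- function(object, windows, min_variance = FALSE) {
  labels <- predict(object, windows, type = "label")
  dec <- rr_person_decisions(labels, windows$person_id,
                             threshold = object$person_threshold,
                             rule = if (min_variance) "min_variance"
                                    else object$person_rule,
                             min_variance = min_variance)
  truth <- windows$group[match(dec$person_id, windows$person_id)]
  dec$true_group <- truth
  dec
}

## ---- shared helpers ----------------------------------------------------

## Validation positive-window ratios per person + true labels.
person_ratios <- function(labels, person_id, group) {
  ids <- unique(person_id)
  list(ids = ids,
       ratio = vapply(ids, function(p)
         mean(labels[person_id == p] == 1), numeric(1)),
       truth = as.integer(group[match(ids, person_id)] == "treatment"))
}

## Person threshold via grid rule from validation window labels.
grid_threshold_from_labels <- function(labels, validation) {
  pr <- person_ratios(labels, validation$person_id, validation$group)
  rr_threshold_grid(pr$ratio, pr$truth)
}

## ---- 1-nearest neighbor -------------------------------------------------

fit_nn1 <- function(train, validation, spec, seed) {
  ref_cap <- spec$ref_cap %||% 100000L
  n <- nrow(train$values)
  idx <- with_seed(seed, {
    if (n > ref_cap) sample.int(n, ref_cap) else seq_len(n)
  })
  fit <- list(ref = train$values[idx, , drop = FALSE],
              ref_label = train$label[idx],
              person_rule = "grid",
              meta = list(n_reference = length(idx)))
  class(fit) <- c("rr_nn1", "rr_classifier")
  fit$w <- train$w
  labels <- nn1_labels(fit, validation$values)
  fit$person_threshold <- grid_threshold_from_labels(labels, validation)
  fit
}

nn1_labels <- function(object, query, chunk = 512L) {
  ref <- object$ref
  rn2 <- rowSums(ref^2)
  out <- integer(nrow(query))
  for (i0 in seq(1, nrow(query), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(query))
    q <- query[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, `+`) - 2 * tcrossprod(q, ref)
    out[i0:i1] <- object$ref_label[max.col(-d2, ties.method = "first")]
  }
  out
}

#' @export
predict_windows.rr_nn1 <- function(object, windows, type) {
  if (ncol(windows$values) != ncol(object$ref)) stop2("mixed window lengths")
  labels <- nn1_labels(object, windows$values)
  if (type == "label") labels else as.numeric(labels)
}

## ---- SVM helpers --------------------------------------------------------

## Oriented decision values: positive score means class "1" (treatment).
svm_scores <- function(model, x) {
  dv <- attr(stats::predict(model, x, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv)
  if (identical(colnames(dv)[1], "0/1")) s <- -s
  s
}

balanced_subsample <- function(labels, per_class, seed) {
  with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      i <- which(labels == cl)
      if (length(i) > per_class) sample(i, per_class) else i
    }))
  })
}

## ---- SVM + FSH ----------------------------------------------------------

fit_svm_fsh <- function(train, validation, spec, seed) {
  if (min(table(train$label)) < 1) stop2("a class has no training windows")
  cost_grid <- spec$cost_grid %||% c(0.1, 1, 10, 100)
  gamma_grid <- spec$gamma_grid %||% c(0.1, 1, 10, 100)
  per_class <- spec$per_class %||% 1500L
  max_features <- spec$max_features %||% 50L

  xtr <- rr_fsh_bank(train)
  sel <- rr_fsh_select(xtr, train$label, max_features = max_features,
                       var_cutoff = spec$var_cutoff %||% 1e-10)
  xtr <- xtr[, sel$names, drop = FALSE]
  norm <- rr_robust_normalize(xtr)
  xtr <- norm$x
  xtr[!is.finite(xtr)] <- 0

  sub <- balanced_subsample(train$label, per_class, seed)
  xs <- xtr[sub, , drop = FALSE]
  ys <- factor(train$label[sub], levels = c(0, 1))

  xval <- rr_fsh_bank(validation)[, sel$names, drop = FALSE]
  xval <- rr_robust_normalize(xval, norm$stats)$x
  xval[!is.finite(xval)] <- 0

  best <- NULL
  for (cost in cost_grid) for (gamma in gamma_grid) {
    m <- e1071::svm(xs, ys, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
    acc <- mean((svm_scores(m, xval) >= 0) == (validation$label == 1))
    if (is.null(best) || acc > best$acc)
      best <- list(model = m, acc = acc, cost = cost, gamma = gamma)
  }

  fit <- list(model = best$model, selected = sel$names, norm_stats = norm$stats,
              person_rule = "mid_median",
              meta = list(cost = best$cost, gamma = best$gamma,
                          n_features = length(sel$names),
                          feature_bank = "builtin64",
                          n_subsample = length(sub)))
  class(fit) <- c("rr_svm_fsh", "rr_classifier")
  fit$w <- train$w

  ## mid-median person threshold from train + validation persons' ratios
  lab_tr <- svm_fsh_labels(fit, train)
  lab_va <- svm_fsh_labels(fit, validation)
  pr <- person_ratios(c(lab_tr, lab_va),
                      c(train$person_id, validation$person_id),
                      c(train$group, validation$group))
  fit$person_threshold <- rr_threshold_mid_median(pr$ratio[pr$truth == 0],
                                                  pr$ratio[pr$truth == 1])
  fit
}

svm_fsh_features <- function(object, windows) {
  x <- rr_fsh_bank(windows)[, object$selected, drop = FALSE]
  x <- rr_robust_normalize(x, object$norm_stats)$x
  x[!is.finite(x)] <- 0
  x
}

svm_fsh_labels <- function(object, windows) {
  as.integer(svm_scores(object$model, svm_fsh_features(object, windows)) >= 0)
}

#' @export
predict_windows.rr_svm_fsh <- function(object, windows, type) {
  s <- svm_scores(object$model, svm_fsh_features(object, windows))
  if (type == "label") as.integer(s >= 0) else s
}

## ---- Ensemble of SVMs ---------------------------------------------------

fit_svm_ensemble <- function(train, validation, spec, seed) {
  n_members <- spec$n_members %||% 11L
  if (n_members %% 2 == 0) stop2("n_members must be odd")
  cost_grid <- spec$cost_grid %||% c(0.1, 1, 10, 100)
  gamma_grid <- spec$gamma_grid %||% c(0.1, 1, 10, 100)
  tune_cap <- spec$tune_cap %||% 2000L

  x <- rr_summary5(train)
  n <- nrow(x)
  if (n < 2 * n_members) stop2("too few training windows for ", n_members,
                               " ensemble members")

  ## member hyperparameters: grid search on a held-out slice of training
  ## persons (the validation persons stay reserved for threshold learning)
  hyper <- with_seed(child_seed(seed, 1), {
    persons <- unique(train$person_id)
    by_group <- split(persons, train$group[match(persons, train$person_id)])
    held <- unlist(lapply(by_group, function(p)
      sample(p, max(1, round(length(p) * 0.2)))))
    in_held <- train$person_id %in% held
    if (all(in_held) || !any(in_held)) {
      ## degenerate tiny cohorts: tune on a window-level split instead
      in_held <- seq_len(n) %in% sample.int(n, max(1, round(n * 0.2)))
    }
    xt <- x[!in_held, , drop = FALSE]; yt <- train$label[!in_held]
    xh <- x[in_held, , drop = FALSE]; yh <- train$label[in_held]
    sub <- balanced_subsample(yt, tune_cap, child_seed(seed, 2))
    best <- NULL
    for (cost in cost_grid) for (gamma in gamma_grid) {
      m <- tryCatch(e1071::svm(xt[sub, , drop = FALSE],
                               factor(yt[sub], levels = c(0, 1)),
                               kernel = "radial", cost = cost, gamma = gamma),
                    error = function(e) NULL)
      if (is.null(m)) next
      acc <- mean(stats::predict(m, xh) == yh)
      if (is.null(best) || acc > best$acc)
        best <- list(acc = acc, cost = cost, gamma = gamma)
    }
    best %||% list(cost = 1, gamma = 1 / ncol(x))
  })

  ## disjoint member subsets; re-draw if any member sees a single class
  members <- NULL
  for (attempt in seq_len(10)) {
    assign <- with_seed(child_seed(seed, 10 + attempt),
                        sample(rep_len(seq_len(n_members), n)))
    ok <- all(vapply(seq_len(n_members), function(mb)
      length(unique(train$label[assign == mb])) == 2, logical(1)))
    if (!ok) next
    members <- lapply(seq_len(n_members), function(mb) {
      i <- assign == mb
      e1071::svm(x[i, , drop = FALSE],
                 factor(train$label[i], levels = c(0, 1)),
                 kernel = "radial", cost = hyper$cost, gamma = hyper$gamma)
    })
    break
  }
  if (is.null(members))
    stop2("could not draw an ensemble partition with both classes per member")

  fit <- list(members = members, assignment = assign,
              person_rule = "ensemble_means",
              meta = list(n_members = n_members, cost = hyper$cost,
                          gamma = hyper$gamma))
  class(fit) <- c("rr_svm_ensemble", "rr_classifier")
  fit$w <- train$w

  lab_val <- ensemble_vote(fit, rr_summary5(validation))
  pr <- person_ratios(lab_val, validation$person_id, validation$group)
  if (!all(c(0, 1) %in% pr$truth))
    stop2("validation set must contain persons of both groups")
  fit$person_threshold <- rr_threshold_ensemble(pr$ratio[pr$truth == 0],
                                                pr$ratio[pr$truth == 1])
  fit
}

ensemble_vote <- function(object, x) {
  votes <- vapply(object$members, function(m)
    as.integer(as.character(stats::predict(m, x))), integer(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
  as.integer(rowMeans(votes) > 0.5)
}

#' @export
predict_windows.rr_svm_ensemble <- function(object, windows, type) {
  lab <- ensemble_vote(object, rr_summary5(windows))
  if (type == "label") lab else as.numeric(lab)
}

## ---- XGBoost ------------------------------------------------------------

fit_xgb <- function(train, validation, spec, seed) {
  n_estimators <- spec$n_estimators %||% c(10L, 50L, 100L, 200L, 500L)
  max_depth <- spec$max_depth %||% seq(5L, 50L, by = 5L)
  if (length(n_estimators) == 0 || length(max_depth) == 0)
    stop2("empty hyperparameter grid")

  dtr <- xgboost::xgb.DMatrix(train$values, label = train$label)
  xval <- validation$values
  best <- NULL
  for (md in max_depth) {
    ## one model per depth at the largest round count; intermediate round
    ## counts are scored from the same boosting path (rounds are nested)
    m <- with_seed(child_seed(seed, md), xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = md,
                    nthread = 1),
      data = dtr, nrounds = max(n_estimators), verbose = 0))
    for (nr in n_estimators) {
      p <- stats::predict(m, xval, iterationrange = c(1, nr))
      acc <- mean((p >= 0.5) == (validation$label == 1))
      if (is.null(best) || acc > best$acc)
        best <- list(model = m, nrounds = nr, max_depth = md, acc = acc)
    }
  }

  fit <- list(model = best$model, nrounds = best$nrounds,
              person_rule = "grid",
              meta = list(n_estimators = best$nrounds,
                          max_depth = best$max_depth))
  class(fit) <- c("rr_xgboost", "rr_classifier")
  fit$w <- train$w
  p <- stats::predict(best$model, xval,
                      iterationrange = c(1, best$nrounds))
  fit$person_threshold <- grid_threshold_from_labels(as.integer(p >= 0.5),
                                                     validation)
  fit
}

#' @export
predict_windows.rr_xgboost <- function(object, windows, type) {
  p <- stats::predict(object$model, windows$values,
                      iterationrange = c(1, object$nrounds))
  if (type == "label") as.integer(p >= 0.5) else p
}
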