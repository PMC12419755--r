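## Person-level aggregation: turning a stream of per-window labels into one
## diagnosis. All thresholds are learned on training/validation persons only
## and applied unchanged to test persons; the decision itself is strict:
## label 1 iff positive_ratio > t.

#' Positive-window ratio for one person
#'
#' @param labels Vector of 0/1 window labels for a single person (>= 1).
#' @return Fraction of windows labeled 1.
#' @export
rr_positive_ratio <- function(labels) {
  if (length(labels) == 0) stop2("positive ratio undefined for zero windows")
  mean(labels == 1)
}

#' Apply a learned threshold to a positive-window ratio
#'
#' The decision is strict, `label = 1` iff `ratio > t`, so raising `t` can
#' never flip a person from control to treatment.
#'
#' @param ratio Positive-window ratio in `[0, 1]`.
#' @param t Threshold in `[0, 1]`.
#' @return Integer label, 0 or 1.
#' @export
rr_decide <- function(ratio, t) as.integer(ratio > t)

## Candidate grid shared by the grid-search threshold rules.
threshold_grid_candidates <- function() seq(0.01, 0.99, by = 0.01)

#' Learn a person threshold by grid search over \{0.01, ..., 0.99\}
#'
#' Selects the threshold maximizing person accuracy on validation persons'
#' positive-window ratios. Ties are broken toward 0.50, then toward the
#' lower threshold.
#'
#' @param ratios Positive-window ratios of validation persons.
#' @param truth True 0/1 person labels, same length.
#' @return Scalar threshold from the candidate grid.
#' @examples
#' rr_threshold_grid(c(0.1, 0.9), c(0, 1))  # 0.50 (all separating t tie)
#' @export
rr_threshold_grid <- function(ratios, truth) {
  stopifnot(length(ratios) == length(truth), length(ratios) >= 1)
  cand <- threshold_grid_candidates()
  acc <- vapply(cand, function(t) mean(as.integer(ratios > t) == truth),
                numeric(1))
  best <- which(acc == max(acc))
  best <- best[order(abs(cand[best] - 0.50), cand[best])]
  cand[best[1]]
}

#' Learn a person threshold from class-wise ratio sets (ensemble rule)
#'
#' Each class's validation ratios are cleared of outliers — values farther
#' than two sample standard deviations from the class mean, in a single
#' pass — and the threshold is the midpoint of the two cleaned class means.
#' A set that would be emptied by the outlier pass (or whose sd is
#' undefined, e.g. a singleton) falls back to its unfiltered values.
#'
#' @param R0 Ratios of validation persons with true label 0 (non-empty).
#' @param R1 Ratios of validation persons with true label 1 (non-empty).
#' @return Scalar threshold `(mean(R0') + mean(R1')) / 2`.
#' @examples
#' rr_threshold_ensemble(c(0.2, 0.3), c(0.7, 0.8))  # 0.5
#' @export
rr_threshold_ensemble <- function(R0, R1) {
  stopifnot(length(R0) >= 1, length(R1) >= 1)
  clear <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x)
    kept <- x[abs(x - mean(x)) <= 2 * s]
    if (length(kept) == 0) {
      rr_log("outlier pass emptied a ratio set; using unfiltered values")
      x
    } else kept
  }
  (mean(clear(R0)) + mean(clear(R1))) / 2
}

#' Learn a person threshold as the midpoint of class-wise median scores
#'
#' @param scores0 Scores (e.g. positive-window ratios) of class-0 persons.
#' @param scores1 Scores of class-1 persons.
#' @return `(median(scores0) + median(scores1)) / 2`.
#' @export
rr_threshold_mid_median <- function(scores0, scores1) {
  stopifnot(length(scores0) >= 1, length(scores1) >= 1)
  (stats::median(scores0) + stats::median(scores1)) / 2
}

#' Minimum-variance person decision
#'
#' An alternative to the ratio rule: compute the variance of every block of
#' `block` consecutive window predictions, locate the minimum variance, take
#' the longest contiguous run of block positions attaining it (earliest on a
#' length tie), and return the majority class among the window predictions
#' covered by that run. The premise is that a long stretch of stable
#' predictions is more trustworthy than windows drawn from varying states.
#' With fewer than `block` windows, or on a majority tie, the rule falls
#' back to the strict ratio-vs-threshold decision.
#'
#' @param preds Ordered 0/1 window predictions for one person.
#' @param block Number of consecutive predictions per variance block
#'   (default 60).
#' @param fallback_threshold Threshold for the ratio-rule fallback.
#' @return Integer label 0/1.
#' @export
rr_min_variance_decision <- function(preds, block = 60L,
                                     fallback_threshold = 0.5) {
  preds <- as.integer(preds)
  n <- length(preds)
  if (n < block) {
    rr_log("fewer than ", block, " windows; falling back to ratio rule")
    return(rr_decide(rr_positive_ratio(preds), fallback_threshold))
  }
  v <- rolling_block_var(preds, block)
  vmin <- min(v)
  at_min <- v <= vmin + 1e-12
  rl <- rle(at_min)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  best <- runs[order(-rl$lengths[runs], starts[runs])][1]
  covered <- preds[starts[best]:(ends[best] + block - 1L)]
  m <- mean(covered)
  if (m == 0.5) {
    rr_log("majority tie in minimum-variance run; falling back to ratio rule")
    return(rr_decide(rr_positive_ratio(preds), fallback_threshold))
  }
  as.integer(m > 0.5)
}

## Sample variance over every length-`block` window of x, via cumulative sums.
rolling_block_var <- function(x, block) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n - block + 1L)
  s <- cs[i + block] - cs[i]
  s2 <- cs2[i + block] - cs2[i]
  (s2 - s^2 / block) / (block - 1)
}

#' Fit a stacking combiner over three base classifiers
#'
#' Logistic regression on the 3-bit vector of base-method window predictions,
#' fitted on validation windows; stacked window labels threshold the fitted
#' probability at 0.5. If the validation labels are single-class the model
#' degenerates to a constant majority-class predictor.
#'
#' @param base_preds Matrix/data.frame with 3 columns of 0/1 window
#'   predictions, aligned per window.
#' @param labels True 0/1 window labels, one per row.
#' @return Object of class `rr_stack`.
#' @export
rr_stack_fit <- function(base_preds, labels) {
  x <- as.matrix(base_preds)
  stopifnot(ncol(x) == 3, nrow(x) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    rr_log("single-class stacking labels; using constant model")
    return(structure(list(constant = as.integer(round(mean(labels)))),
                     class = "rr_stack"))
  }
  df <- data.frame(y = labels, b1 = x[, 1], b2 = x[, 2], b3 = x[, 3])
  fit <- suppressWarnings(stats::glm(y ~ b1 + b2 + b3, data = df,
                                     family = stats::binomial()))
  structure(list(fit = fit, constant = NULL), class = "rr_stack")
}

#' @rdname rr_stack_fit
#' @param object An `rr_stack` model.
#' @param newdata Matrix/data.frame with 3 columns of base predictions.
#' @param ... Unused.
#' @export
predict.rr_stack <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(x)))
  df <- data.frame(b1 = x[, 1], b2 = x[, 2], b3 = x[, 3])
  p <- stats::predict(object$fit, newdata = df, type = "response")
  as.integer(p >= 0.5)
}

#' Assemble per-person decisions from window predictions
#'
#' @param window_labels 0/1 predicted labels, one per window.
#' @param person_id Person id per window.
#' @param threshold Learned person threshold.
#' @param rule Name of the rule that produced the threshold (bookkeeping).
#' @param min_variance Use [rr_min_variance_decision()] instead of the ratio
#'   rule (threshold still used for its fallback).
#' @param block Block size for the minimum-variance rule.
#' @return data.frame with columns `person_id`, `positive_ratio`,
#'   `threshold`, `rule`, `label`, one row per person (person order follows
#'   first appearance).
#' @export
rr_person_decisions <- function(window_labels, person_id, threshold,
                                rule = "grid", min_variance = FALSE,
                                block = 60L) {
  stopifnot(length(window_labels) == length(person_id))
  ids <- unique(person_id)
  ratio <- vapply(ids, function(id)
    rr_positive_ratio(window_labels[person_id == id]), numeric(1))
  label <- if (min_variance) {
    vapply(ids, function(id)
      rr_min_variance_decision(window_labels[person_id == id], block = block,
                               fallback_threshold = threshold), integer(1))
  } else {
    rr_decide(ratio, threshold)
  }
  data.frame(person_id = ids, positive_ratio = unname(ratio),
             threshold = threshold, rule = rule, label = as.integer(label),
             stringsAsFactors = FALSE)
}
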