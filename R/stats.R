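## Classifier-comparison statistics over a methods x folds accuracy matrix:
## Friedman test, pairwise Wilcoxon signed-rank with Benjamini-Hochberg
## correction, and paired Cohen's d. Implemented from the definitions (with
## average-rank tie handling); base R's friedman.test / wilcox.test /
## p.adjust serve as independent cross-checks in the test suite.

#' Friedman test across methods over folds
#'
#' Rank-based test of whether several classifiers differ in accuracy across
#' shared cross-validation folds. Folds are blocks; within each fold the
#' methods are ranked (average ranks on ties) and the tie-corrected
#' chi-square statistic is referred to a chi-square distribution with
#' `m - 1` degrees of freedom. If every fold ranks all methods identically
#' (complete ties), the statistic is 0 and p = 1.
#'
#' @param acc Numeric matrix of accuracies, methods in rows, folds in
#'   columns; >= 2 methods and >= 2 folds, no missing cells.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' m <- rbind(a = c(70, 72, 71), b = c(75, 74, 76), c = c(60, 61, 59))
#' rr_friedman(m)
#' @export
rr_friedman <- function(acc) {
  acc <- as.matrix(acc)
  m <- nrow(acc); nf <- ncol(acc)
  stopifnot(m >= 2, nf >= 2, all(is.finite(acc)))
  r <- apply(acc, 2, rank)                    # m x nf: ranks within each fold
  Rj <- rowSums(r)
  num <- 12 * sum((Rj - nf * (m + 1) / 2)^2)
  ties <- apply(r, 2, function(col) {
    tab <- table(col)
    sum(tab^3 - tab)
  })
  den <- nf * m * (m + 1) - sum(ties) / (m - 1)
  stat <- if (den <= 0) 0 else num / den
  p <- if (stat == 0 && den <= 0) 1 else
    stats::pchisq(stat, df = m - 1, lower.tail = FALSE)
  list(statistic = stat, df = m - 1, p_value = p)
}

#' Wilcoxon signed-rank test for paired accuracies
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (Wilcoxon's convention); absolute differences are ranked with average
#' ranks on ties, and the statistic is the sum of ranks of positive
#' differences. With no ties/zeros and `n <= exact_limit` pairs the exact
#' signed-rank distribution is used; otherwise a normal approximation with
#' tie correction and continuity correction.
#'
#' @param a,b Paired numeric vectors (e.g. per-fold accuracies of two
#'   methods).
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return List with `statistic`, `p_value`, `n` (pairs after zero removal).
#' @export
rr_wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    rr_log("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= exact_limit) {
    p <- if (V > n * (n + 1) / 4)
      stats::psignrank(V - 1, n, lower.tail = FALSE)
    else
      stats::psignrank(V, n)
    p <- min(2 * p, 1)
  } else {
    z <- V - n * (n + 1) / 4
    tab <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48)
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
    p <- min(p, 1)
  }
  list(statistic = V, p_value = p, n = as.integer(n))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the input order; never smaller than the raw
#'   values, and the largest raw p is unchanged.
#' @export
rr_bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[ord] * m / seq.int(m, 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Cohen's d for paired samples
#'
#' \eqn{d = \mathrm{mean}(a - b) / \mathrm{sd}(a - b)} with the sample
#' standard deviation (n - 1). When the differences have zero spread the
#' effect size is undefined and `NA` is returned.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @return Scalar d, or `NA` when `sd(a - b) == 0`.
#' @examples
#' rr_cohens_d_paired(c(2, 2, 4, 0), c(1, 1, 1, 1))  # 0.6123724
#' @export
rr_cohens_d_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    rr_log("zero-spread paired differences; Cohen's d undefined")
    return(rr_na)
  }
  mean(d) / s
}

#' Full classifier-comparison report
#'
#' Friedman test over the accuracy matrix, all pairwise Wilcoxon signed-rank
#' tests with Benjamini-Hochberg correction across the `choose(m, 2)` raw
#' p-values, and the antisymmetric paired Cohen's d matrix.
#'
#' @inheritParams rr_friedman
#' @return Object of class `rr_stats_report`: list with `friedman`,
#'   `pairwise` (data.frame: method_a, method_b, statistic, p_raw, p_bh),
#'   and `cohens_d` (m x m matrix).
#' @export
rr_stats_report <- function(acc) {
  acc <- as.matrix(acc)
  m <- nrow(acc)
  methods <- rownames(acc) %||% paste0("method", seq_len(m))
  rownames(acc) <- methods
  fr <- rr_friedman(acc)
  pairs <- utils::combn(m, 2)
  pw <- data.frame(method_a = methods[pairs[1, ]],
                   method_b = methods[pairs[2, ]],
                   statistic = NA_real_, p_raw = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    wt <- rr_wilcoxon_signed_rank(acc[pairs[1, i], ], acc[pairs[2, i], ])
    pw$statistic[i] <- wt$statistic
    pw$p_raw[i] <- wt$p_value
  }
  pw$p_bh <- rr_bh_adjust(pw$p_raw)
  dmat <- matrix(0, m, m, dimnames = list(methods, methods))
  for (i in seq_len(ncol(pairs))) {
    d <- rr_cohens_d_paired(acc[pairs[1, i], ], acc[pairs[2, i], ])
    dmat[pairs[1, i], pairs[2, i]] <- d
    dmat[pairs[2, i], pairs[1, i]] <- -d
  }
  structure(list(friedman = fr, pairwise = pw, cohens_d = dmat,
                 accuracy = acc),
            class = "rr_stats_report")
}

#' @export
print.rr_stats_report <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.4f (df = %d), p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  cat("Pairwise Wilcoxon signed-rank (BH-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  cat("Paired Cohen's d:\n")
  print(round(x$cohens_d, 3))
  invisible(x)
}
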