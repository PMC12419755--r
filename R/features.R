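## Window-level feature extraction.
##
## All extractors operate on an rr_windows object (or a bare numeric matrix
## with one window per row) and are vectorized across rows. Conventions,
## chosen once and used everywhere:
##   * `var`/`sd` are sample statistics (denominator n - 1);
##   * skewness is the moment-based Fisher g1 (population central moments);
##   * kurtosis is excess kurtosis (g2 = m4/m2^2 - 3);
##   * ACF is the biased sample estimator with the window mean, r_0 = 1;
##   * degenerate inputs (constant windows for ACF/skew/kurt) yield NA.

win_matrix <- function(windows) {
  if (inherits(windows, "rr_windows")) windows$values
  else if (is.matrix(windows)) windows
  else matrix(as.numeric(windows), nrow = 1)
}

row_medians <- function(m) apply(m, 1, stats::median)

row_quantile <- function(m, p) apply(m, 1, stats::quantile, probs = p,
                                     names = FALSE)

row_var <- function(m) {
  n <- ncol(m)
  (rowSums(m^2) - n * rowMeans(m)^2) / (n - 1)
}

row_central_moment <- function(mc, k) rowMeans(mc^k)

#' Sample autocorrelation at a fixed lag
#'
#' The biased sample estimator
#' \deqn{r_k = \frac{\sum_{t=1}^{n-k}(x_t-\bar x)(x_{t+k}-\bar x)}
#'                  {\sum_{t=1}^{n}(x_t-\bar x)^2},}
#' with \eqn{r_0 = 1}. A constant series has a zero denominator and returns
#' `NA` (the package's missing-value code for degenerate features).
#'
#' @param x Numeric vector, `length(x) > k`.
#' @param k Non-negative integer lag.
#' @return Scalar in `[-1, 1]`, or `NA` for a constant series.
#' @examples
#' rr_acf(sin(1:100), 1)
#' @export
rr_acf <- function(x, k) {
  stopifnot(k >= 0, length(x) > k)
  if (k == 0) return(1)
  drop(row_acf(matrix(x, nrow = 1), k))
}

## Vectorized sample ACF at lag k for each row of m.
row_acf <- function(m, k) {
  w <- ncol(m)
  mc <- m - rowMeans(m)
  den <- rowSums(mc^2)
  num <- rowSums(mc[, seq_len(w - k), drop = FALSE] *
                 mc[, (k + 1):w, drop = FALSE])
  out <- num / den
  out[den <= 0] <- rr_na
  out
}

row_skewness <- function(m) {
  mc <- m - rowMeans(m)
  m2 <- row_central_moment(mc, 2)
  out <- row_central_moment(mc, 3) / m2^1.5
  out[m2 <= 0] <- rr_na
  out
}

row_kurtosis <- function(m) {
  mc <- m - rowMeans(m)
  m2 <- row_central_moment(mc, 2)
  out <- row_central_moment(mc, 4) / m2^2 - 3
  out[m2 <= 0] <- rr_na
  out
}

#' Five-number summary features (ensemble-of-SVMs representation)
#'
#' Per window: `min`, `max`, `var` (sample), `mean`, `median` — the compact
#' representation consumed by the bagged SVM ensemble.
#'
#' @param windows An `rr_windows` object, numeric matrix (window per row) or
#'   a single numeric vector.
#' @return Numeric matrix, one row per window, columns
#'   `min,max,var,mean,median`.
#' @examples
#' rr_summary5(c(1, 2, 3, 4))
#' @export
rr_summary5 <- function(windows) {
  m <- win_matrix(windows)
  cbind(min = do.call(pmin, asplit(m, 2)),
        max = do.call(pmax, asplit(m, 2)),
        var = row_var(m),
        mean = rowMeans(m),
        median = row_medians(m))
}

#' Seven-family explanatory features
#'
#' The small, interpretable set used by the explanation layer: mean, min,
#' max, standard deviation, skewness, kurtosis, and lag-1..4 sample ACF
#' (the four ACF lags form one feature family, hence "seven features" across
#' ten scalar columns). Constant windows yield `NA` for sd-normalized
#' moments and the ACF columns.
#'
#' @inheritParams rr_summary5
#' @return Numeric matrix with columns
#'   `mean,min,max,sd,skewness,kurtosis,acf_1,acf_2,acf_3,acf_4`.
#' @export
rr_explain7 <- function(windows) {
  m <- win_matrix(windows)
  stopifnot(ncol(m) >= 5)
  cbind(mean = rowMeans(m),
        min = do.call(pmin, asplit(m, 2)),
        max = do.call(pmax, asplit(m, 2)),
        sd = sqrt(row_var(m)),
        skewness = row_skewness(m),
        kurtosis = row_kurtosis(m),
        acf_1 = row_acf(m, 1),
        acf_2 = row_acf(m, 2),
        acf_3 = row_acf(m, 3),
        acf_4 = row_acf(m, 4))
}

## Levinson-Durbin partial autocorrelations from sample ACF rows.
## rho: n x K matrix of ACF at lags 1..K; returns n x K PACF matrix.
row_pacf <- function(rho) {
  n <- nrow(rho); K <- ncol(rho)
  pacf <- matrix(rr_na, n, K)
  pacf[, 1] <- rho[, 1]
  phi <- matrix(rho[, 1], n, 1)
  if (K >= 2) for (k in 2:K) {
    num <- rho[, k] - rowSums(phi * rho[, (k - 1):1, drop = FALSE])
    den <- 1 - rowSums(phi * rho[, 1:(k - 1), drop = FALSE])
    a <- num / den
    a[!is.finite(a)] <- rr_na
    pacf[, k] <- a
    phi <- cbind(phi - a * phi[, (k - 1):1, drop = FALSE], a)
  }
  pacf
}

row_longest_run <- function(flag) {
  apply(flag, 1, function(r) {
    rl <- rle(r)
    m <- rl$lengths[rl$values]
    if (length(m)) max(m) else 0L
  })
}

## Count local maxima with support `s`: x_i greater than all s neighbors on
## each side (interior positions only).
row_n_peaks <- function(m, s) {
  w <- ncol(m)
  if (w < 2 * s + 1) return(rep(0L, nrow(m)))
  core <- (s + 1):(w - s)
  is_peak <- matrix(TRUE, nrow(m), length(core))
  for (d in seq_len(s)) {
    is_peak <- is_peak &
      (m[, core, drop = FALSE] > m[, core - d, drop = FALSE]) &
      (m[, core, drop = FALSE] > m[, core + d, drop = FALSE])
  }
  rowSums(is_peak)
}

row_binned_entropy <- function(m, bins = 10L) {
  apply(m, 1, function(r) {
    rng <- range(r)
    if (rng[1] == rng[2]) return(0)
    p <- tabulate(pmin(bins, 1L + floor((r - rng[1]) / diff(rng) * bins)), bins)
    p <- p[p > 0] / length(r)
    -sum(p * log(p))
  })
}

#' Built-in comprehensive window feature bank
#'
#' A reduced, dependency-free bank of 64 per-window features spanning
#' moments and quantiles, lag-1..10 ACF and lag-1..5 PACF, successive-
#' difference (HRV-style) statistics, spectral band energies and entropy,
#' linear-trend coefficients, run/peak counts and Poincare descriptors.
#' It plays the role of a large automatic feature bank ahead of
#' hypothesis-test feature selection; it does not aim for numerical parity
#' with any external feature library.
#'
#' @inheritParams rr_summary5
#' @return Numeric matrix, one row per window, 64 named columns. Degenerate
#'   windows produce `NA` in scale-normalized features.
#' @export
rr_fsh_bank <- function(windows) {
  m <- win_matrix(windows)
  w <- ncol(m)
  stopifnot(w >= 12)
  n <- nrow(m)
  mc <- m - rowMeans(m)
  dm <- m[, -1, drop = FALSE] - m[, -w, drop = FALSE]
  acfs <- vapply(1:10, function(k) row_acf(m, k), numeric(n))
  colnames(acfs) <- paste0("acf_", 1:10)
  pacfs <- row_pacf(acfs[, 1:5, drop = FALSE])
  colnames(pacfs) <- paste0("pacf_", 1:5)
  vr <- row_var(m)
  dvar <- row_var(dm)

  ## spectral features on mean-removed rows
  sp <- Mod(stats::mvfft(t(mc)))^2
  sp <- t(sp[2:(floor(w / 2) + 1), , drop = FALSE])    # positive frequencies
  tot <- rowSums(sp)
  nf <- ncol(sp)
  band <- function(lo, hi) {
    i <- seq.int(max(1, ceiling(lo * nf)), floor(hi * nf))
    rowSums(sp[, i, drop = FALSE]) / tot
  }
  pspec <- sp / tot
  spec_entropy <- -rowSums(ifelse(pspec > 0, pspec * log(pspec), 0))
  freqs <- seq_len(nf) / nf
  spec_centroid <- rowSums(sweep(pspec, 2, freqs, `*`))

  ## closed-form least-squares trend on t = 1..w
  tt <- seq_len(w)
  st2 <- sum((tt - mean(tt))^2)
  slope <- rowSums(sweep(mc, 2, tt - mean(tt), `*`)) / st2
  intercept <- rowMeans(m) - slope * mean(tt)
  r2 <- slope^2 * st2 / rowSums(mc^2)
  r2[rowSums(mc^2) <= 0] <- rr_na

  above <- m > rowMeans(m)
  signs <- sign(mc)
  crossings <- rowSums(signs[, -1, drop = FALSE] * signs[, -w, drop = FALSE] < 0)

  out <- cbind(
    mean = rowMeans(m),
    median = row_medians(m),
    min = do.call(pmin, asplit(m, 2)),
    max = do.call(pmax, asplit(m, 2)),
    range = do.call(pmax, asplit(m, 2)) - do.call(pmin, asplit(m, 2)),
    var = vr,
    sd = sqrt(vr),
    iqr = row_quantile(m, 0.75) - row_quantile(m, 0.25),
    mad = apply(m, 1, stats::mad),
    q05 = row_quantile(m, 0.05),
    q10 = row_quantile(m, 0.10),
    q25 = row_quantile(m, 0.25),
    q75 = row_quantile(m, 0.75),
    q90 = row_quantile(m, 0.90),
    q95 = row_quantile(m, 0.95),
    skewness = row_skewness(m),
    kurtosis = row_kurtosis(m),
    acfs,
    pacfs,
    acf_mean_1_10 = rowMeans(acfs),
    acf_first_neg = apply(acfs, 1, function(r) {
      i <- which(r < 0); if (length(i)) i[1] else 11L
    }),
    abs_energy = rowSums(m^2),
    rms = sqrt(rowMeans(m^2)),
    mean_abs_change = rowMeans(abs(dm)),
    max_abs_change = do.call(pmax, asplit(abs(dm), 2)),
    mean_change = (m[, w] - m[, 1]) / (w - 1),
    rmssd = sqrt(rowMeans(dm^2)),
    pnn20 = rowMeans(abs(dm) > 20),
    pnn50 = rowMeans(abs(dm) > 50),
    cid_ce = sqrt(rowSums(dm^2)),
    sd1 = sqrt(pmax(dvar / 2, 0)),
    sd2 = sqrt(pmax(2 * vr - dvar / 2, 0)),
    count_above_mean = rowSums(above),
    count_below_mean = rowSums(!above),
    mean_crossings = crossings,
    longest_run_above = row_longest_run(above),
    longest_run_below = row_longest_run(!above),
    n_peaks_1 = row_n_peaks(m, 1),
    n_peaks_3 = row_n_peaks(m, 3),
    binned_entropy = row_binned_entropy(m),
    band_low = band(0.001, 0.25),
    band_midlow = band(0.25, 0.5),
    band_midhigh = band(0.5, 0.75),
    band_high = band(0.75, 1),
    spec_entropy = spec_entropy,
    spec_centroid = spec_centroid,
    trend_slope = slope,
    trend_intercept = intercept,
    trend_r2 = r2
  )
  out
}

#' Robust normalization of a feature matrix
#'
#' Per feature: `(x - median) / IQR`, with statistics fitted on the training
#' split only and reused (via `fit_stats`) on validation/test data. Features
#' with zero IQR are centered only. Not idempotent: re-fitting on normalized
#' data gives median 0 and IQR 1.
#'
#' @param x Numeric feature matrix (windows x features).
#' @param fit_stats Optional statistics from a previous call (list with
#'   `center`, `scale`); when supplied, no fitting happens.
#' @return List with `x` (normalized matrix) and `stats`.
#' @export
rr_robust_normalize <- function(x, fit_stats = NULL) {
  x <- as.matrix(x)
  if (is.null(fit_stats)) {
    center <- apply(x, 2, stats::median, na.rm = TRUE)
    scale <- apply(x, 2, function(col)
      diff(stats::quantile(col, c(0.25, 0.75), na.rm = TRUE, names = FALSE)))
    degenerate <- !is.finite(scale) | scale == 0
    if (any(degenerate))
      rr_log(sum(degenerate), " feature(s) with zero IQR passed through centered only")
    scale[degenerate] <- 1
    fit_stats <- list(center = center, scale = scale)
  }
  xn <- sweep(sweep(x, 2, fit_stats$center, `-`), 2, fit_stats$scale, `/`)
  list(x = xn, stats = fit_stats)
}

#' Hypothesis-test feature selection (low variance filter + Mann-Whitney U)
#'
#' Robust-normalizes the training feature matrix, removes features whose
#' post-normalization variance falls below `var_cutoff`, ranks the survivors
#' by two-sided Mann-Whitney U p-value (class 0 vs class 1; missing values
#' dropped per feature), and returns the top `max_features` names. Ties in
#' p-value are broken deterministically by feature name.
#'
#' @param x Numeric feature matrix (windows x named features) from training
#'   windows only.
#' @param labels Integer/numeric vector of window labels (0/1), one per row.
#' @param max_features Maximum number of features returned (default 50).
#' @param var_cutoff Variance threshold applied after robust normalization.
#' @return List with `names` (selected, p-ordered), `p_values` (named,
#'   same order), and `n_dropped_low_variance`.
#' @export
rr_fsh_select <- function(x, labels, max_features = 50L, var_cutoff = 1e-10) {
  x <- as.matrix(x)
  stopifnot(!is.null(colnames(x)), nrow(x) == length(labels))
  labels <- as.integer(labels)
  if (min(table(labels)) < 2) stop2("need >= 2 windows per class")
  xn <- rr_robust_normalize(x)$x
  v <- apply(xn, 2, stats::var, na.rm = TRUE)
  keep <- which(is.finite(v) & v >= var_cutoff)
  if (length(keep) == 0) stop2("no features survive the low-variance filter")
  pvals <- vapply(keep, function(j) {
    col <- xn[, j]
    ok <- is.finite(col)
    a <- col[ok & labels == 0]; b <- col[ok & labels == 1]
    if (length(a) < 1 || length(b) < 1) return(1)
    stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)$p.value
  }, numeric(1))
  names(pvals) <- colnames(x)[keep]
  ord <- order(pvals, names(pvals))
  sel <- utils::head(ord, max_features)
  list(names = names(pvals)[sel],
       p_values = pvals[sel],
       n_dropped_low_variance = ncol(x) - length(keep))
}
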