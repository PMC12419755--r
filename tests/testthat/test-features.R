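test_that("summary5 matches hand-computed values and is order-invariant", {
  expect_equal(rr_summary5(c(700, 700, 700)),
               cbind(min = 700, max = 700, var = 0, mean = 700, median = 700))
  s <- rr_summary5(c(1, 2, 3, 4))
  expect_equal(s[, "mean"], 2.5, ignore_attr = TRUE)
  expect_equal(s[, "median"], 2.5, ignore_attr = TRUE)
  expect_equal(s[, "var"], 5 / 3, ignore_attr = TRUE)  # sample variance

  set.seed(4)
  x <- rnorm(60, 800, 50)
  expect_equal(rr_summary5(x), rr_summary5(sample(x)))
})

test_that("sample ACF matches a double-loop oracle to 1e-12", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(c(60, 300), 1)
    x <- rnorm(n, 800, 50)
    for (k in 1:4) {
      expect_equal(rr_acf(x, k), acf_oracle(x, k), tolerance = 1e-12)
    }
  }
  expect_equal(rr_acf(rnorm(30), 0), 1)
  expect_true(is.na(rr_acf(rep(5, 30), 1)))
})

test_that("explain7 layout, degenerate handling and moment oracle", {
  x7 <- rr_explain7(c(1, 2, 3, 4, 5, 6))     # symmetric values
  expect_equal(colnames(x7),
               c("mean", "min", "max", "sd", "skewness", "kurtosis",
                 paste0("acf_", 1:4)))
  expect_equal(x7[, "skewness"], 0, ignore_attr = TRUE)

  cst <- rr_explain7(rep(7, 10))
  expect_equal(cst[, "sd"], 0, ignore_attr = TRUE)
  expect_true(all(is.na(cst[, c("skewness", "kurtosis", paste0("acf_", 1:4))])))

  ## independent definition-by-formula oracle for the moments
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(60, 800, 40)
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    f <- rr_explain7(x)
    expect_equal(f[, "mean"], m, ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(f[, "sd"], sd(x), ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(f[, "skewness"], m3 / m2^1.5, ignore_attr = TRUE,
                 tolerance = 1e-10)
    expect_equal(f[, "kurtosis"], m4 / m2^2 - 3, ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
})

test_that("moments are permutation-invariant, ACF is not", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.8), 60, sd = 10)) + 800
  xs <- sample(x)
  a <- rr_explain7(x); b <- rr_explain7(xs)
  expect_equal(a[, 1:6], b[, 1:6])
  expect_false(isTRUE(all.equal(a[, "acf_1"], b[, "acf_1"])))
})

test_that("built-in feature bank is wide, named and total on regular input", {
  co <- tiny_cohort(1, 1, beats = 200, seed = 23)
  wins <- rr_cohort_windows(co, 60, step = 10)
  bank <- rr_fsh_bank(wins)
  expect_gte(ncol(bank), 60)
  expect_false(anyDuplicated(colnames(bank)) > 0)
  expect_true(all(is.finite(bank)))
})

test_that("robust normalization centers by median and scales by IQR", {
  x <- cbind(a = c(8, 9, 10, 11, 12), b = rep(3, 5))
  rn <- rr_robust_normalize(x)
  expect_equal(rn$x[, "a"][3], 0, ignore_attr = TRUE)
  expect_equal((12 - 10) / 2, rn$x[5, "a"], ignore_attr = TRUE)
  ## zero-IQR feature passes through centered
  expect_equal(rn$x[, "b"], rep(0, 5), ignore_attr = TRUE)

  set.seed(3)
  y <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  fit <- rr_robust_normalize(y)
  expect_equal(unname(apply(fit$x, 2, median)), rep(0, 4))
  ## reusing fitted stats reproduces the transform; refit renormalizes
  again <- rr_robust_normalize(y, fit$stats)
  expect_equal(again$x, fit$x)
  refit <- rr_robust_normalize(fit$x)
  expect_equal(unname(apply(refit$x, 2, median)), rep(0, 4))
  expect_equal(unname(apply(refit$x, 2, function(c)
    diff(quantile(c, c(.25, .75), names = FALSE)))), rep(1, 4))
})

test_that("feature selection removes flat features and ranks separators first", {
  set.seed(5)
  n <- 80
  labels <- rep(c(0, 1), each = n / 2)
  x <- cbind(flat = rep(1, n),
             sep = labels + rnorm(n, 0, 1e-3),
             noise1 = rnorm(n), noise2 = rnorm(n))
  sel <- rr_fsh_select(x, labels, max_features = 3)
  expect_false("flat" %in% sel$names)
  expect_equal(sel$names[1], "sep")
  expect_equal(sel$n_dropped_low_variance, 1)

  ## informative features dominate the selected set
  hits <- sapply(1:3, function(s) {
    set.seed(s)
    ni <- 30; nn <- 300
    xi <- sapply(seq_len(ni), function(i) labels * 0.8 + rnorm(n))
    xn <- matrix(rnorm(n * nn), n)
    xx <- cbind(xi, xn)
    colnames(xx) <- c(sprintf("inf%02d", seq_len(ni)),
                      sprintf("noi%03d", seq_len(nn)))
    picked <- rr_fsh_select(xx, labels, max_features = 25)$names
    mean(grepl("^inf", picked))
  })
  expect_gte(median(hits), 0.8)

  expect_error(rr_fsh_select(cbind(f = rep(1, n)), labels), "survive")
})
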