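test_that("positive ratio is a plain fraction and order-invariant", {
  expect_equal(rr_positive_ratio(rep(1, 10)), 1)
  expect_equal(rr_positive_ratio(c(rep(1, 3), rep(0, 7))), 0.3)
  set.seed(2)
  l <- rbinom(50, 1, 0.4)
  expect_equal(rr_positive_ratio(l), rr_positive_ratio(sample(l)))
  expect_error(rr_positive_ratio(integer(0)), "zero windows")
})

test_that("strict decision rule and monotonicity in the threshold", {
  expect_equal(rr_decide(0.5, 0.5), 0L)   # strict: must exceed
  expect_equal(rr_decide(0.51, 0.5), 1L)
  set.seed(3)
  for (i in 1:20) {
    ratio <- runif(1)
    ts <- sort(runif(5))
    labs <- vapply(ts, function(t) rr_decide(ratio, t), integer(1))
    expect_true(all(diff(labs) <= 0))     # raising t never flips 0 -> 1
  }
})

test_that("grid threshold matches exhaustive enumeration with tie rules", {
  ## separable case: all separating thresholds tie; rule returns 0.50
  expect_equal(rr_threshold_grid(c(0.1, 0.9), c(0, 1)), 0.50)
  ## single-class set: all thresholds below min ratio tie; rule picks 0.50
  expect_equal(rr_threshold_grid(c(0.8, 0.9), c(1, 1)), 0.50)

  set.seed(7)
  for (i in 1:100) {
    np <- sample(2:12, 1)
    truth <- c(0, 1, rbinom(np - 2, 1, 0.5))
    ratios <- round(runif(np), 3)
    expect_equal(rr_threshold_grid(ratios, truth),
                 grid_threshold_oracle(ratios, truth))
  }
})

test_that("ensemble threshold clears 2-sd outliers then averages class means", {
  expect_equal(rr_threshold_ensemble(c(0.2, 0.3), c(0.7, 0.8)), 0.5)
  ## singletons: sd undefined, nothing removed
  expect_equal(rr_threshold_ensemble(0.2, 0.9), 0.55)
  ## planted far outlier in R0 is removed (hand-worked single pass)
  R0 <- c(0.10, 0.12, 0.14, 0.16, 0.12, 0.10, 0.14, 0.90)
  keep <- R0[abs(R0 - mean(R0)) <= 2 * sd(R0)]
  expect_equal(keep, R0[1:7])
  R1 <- c(0.7, 0.8)
  expect_equal(rr_threshold_ensemble(R0, R1), (mean(R0[1:7]) + 0.75) / 2)
})

test_that("mid-median threshold is the midpoint of class medians", {
  expect_equal(rr_threshold_mid_median(0, 1), 0.5)
  expect_equal(rr_threshold_mid_median(c(0.3, 0.3), c(0.3, 0.3)), 0.3)
  set.seed(11)
  s0 <- runif(7); s1 <- runif(9)
  expect_equal(rr_threshold_mid_median(s0, s1),
               (median(s0) + median(s1)) / 2)
})

test_that("minimum-variance decision agrees with an all-blocks scan oracle", {
  expect_equal(rr_min_variance_decision(rep(1L, 200)), 1L)
  ## fewer windows than a block: ratio fallback
  expect_equal(rr_min_variance_decision(rep(1L, 10),
                                        fallback_threshold = 0.5), 1L)
  expect_equal(rr_min_variance_decision(c(rep(1L, 4), rep(0L, 6)),
                                        fallback_threshold = 0.5), 0L)
  ## structured case: zeros then ones then an alternating tail
  p <- c(rep(0L, 100), rep(1L, 100), rep(c(0L, 1L), 20))
  expect_equal(rr_min_variance_decision(p, fallback_threshold = 0.5),
               min_variance_oracle(p))
  set.seed(13)
  for (i in 1:50) {
    n <- sample(60:240, 1)
    p <- rbinom(n, 1, runif(1, 0.2, 0.8))
    expect_equal(rr_min_variance_decision(p, fallback_threshold = 0.5),
                 min_variance_oracle(p))
  }
})

test_that("stacking combiner: unanimity, lookup consistency, degenerate fit", {
  set.seed(17)
  base <- matrix(rbinom(300, 1, 0.5), 100, 3)
  ## all bases agree: stacked output equals them
  agree <- cbind(base[, 1], base[, 1], base[, 1])
  st <- rr_stack_fit(agree, base[, 1])
  expect_equal(predict(st, agree), base[, 1])

  ## decision depends only on the 3-bit pattern: matches an 8-cell lookup
  y <- as.integer(xor(base[, 1], rbinom(100, 1, 0.2)))
  st2 <- rr_stack_fit(base, y)
  cells <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  lookup <- predict(st2, cells)
  key <- base[, 1] * 4 + base[, 2] * 2 + base[, 3] + 1
  cellkey <- cells[, 1] * 4 + cells[, 2] * 2 + cells[, 3] + 1
  expect_equal(predict(st2, base), lookup[match(key, cellkey)])

  ## one perfect base + two random: stacked tracks the best base closely
  deficits <- sapply(1:10, function(s) {
    set.seed(s)
    yy <- rbinom(400, 1, 0.5)
    b <- cbind(yy, rbinom(400, 1, 0.5), rbinom(400, 1, 0.5))
    fit <- rr_stack_fit(b[1:200, ], yy[1:200])
    mean(predict(fit, b[201:400, ]) == yy[201:400])
  })
  expect_gte(mean(deficits), 0.98)

  ## single-class labels: constant majority model
  stc <- rr_stack_fit(base, rep(1L, 100))
  expect_equal(predict(stc, cells), rep(1L, 8))
})

test_that("person decisions summarize window streams per person", {
  labels <- c(1, 1, 0, 1, 0, 0, 0, 0)
  pid <- rep(c("a", "b"), each = 4)
  dec <- rr_person_decisions(labels, pid, threshold = 0.5, rule = "grid")
  expect_equal(dec$positive_ratio, c(0.75, 0))
  expect_equal(dec$label, c(1L, 0L))
  expect_equal(dec$rule, rep("grid", 2))
})
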