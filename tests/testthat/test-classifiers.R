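ns <- asNamespace("rrscreen")

test_that("MLP backward pass matches finite-difference gradients", {
  set.seed(41)
  x <- matrix(rnorm(7 * 6), 7, 6)
  y <- rbinom(7, 1, 0.5)
  par <- ns$mlp_init(6, 5, seed = 3)
  loss <- function(p) {
    fw <- ns$mlp_forward(p, x)
    -mean(log(ifelse(y == 1, fw$p[, 2], fw$p[, 1])))
  }
  gr <- ns$mlp_backward(par, x, y, ns$mlp_forward(par, x))
  eps <- 1e-6
  for (nm in names(par)) {
    for (i in sample(length(par[[nm]]), min(3, length(par[[nm]])))) {
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + eps; up <- loss(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- loss(p2)
      expect_equal(gr[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }
})

test_that("GRU+FCN backward pass matches finite-difference gradients", {
  set.seed(43)
  B <- 4; T <- 9
  cfg <- list(lr = 1e-3, batch = B, hidden = 3, layers = 2,
              bidirectional = TRUE, dropout = 0.5, epochs = 1,
              patience_es = 10, patience_lr = 5,
              conv_channels = c(3L, 4L, 3L), kernels = c(3L, 3L, 3L))
  x <- matrix(rnorm(B * T), B, T)
  y <- c(0, 1, 1, 0)
  par <- ns$grufcn_init(T, cfg, seed = 7)
  run <- ns$grufcn_run_init(cfg)
  mask <- matrix(rbinom(B * cfg$hidden * 2, 1, 0.5) / 0.5, B, cfg$hidden * 2)
  loss <- function(p) {
    fw <- ns$grufcn_forward(p, run, x, cfg, training = TRUE, drop_mask = mask)
    ns$grufcn_loss(fw$p, y)
  }
  fw <- ns$grufcn_forward(par, run, x, cfg, training = TRUE, drop_mask = mask)
  bw <- ns$grufcn_backward(par, fw, y, cfg)
  eps <- 1e-5
  for (nm in names(par)) {
    for (i in sample(length(par[[nm]]), min(2, length(par[[nm]])))) {
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + eps; up <- loss(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- loss(p2)
      num <- (up - dn) / (2 * eps)
      expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-3,
                   ignore_attr = TRUE)
    }
  }
  ## softmax output is a 2-class distribution
  expect_equal(rowSums(fw$p), rep(1, B), tolerance = 1e-12)
})

test_that("1-NN returns the label of an exactly matching reference window", {
  co <- tiny_cohort(2, 2, beats = 150, seed = 47)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "T001"))
  va <- rr_cohort_windows(co, 60, persons = c("C002", "T002"))
  fit <- rr_classifier(tr, va, "nn1", seed = 1)
  ## query = training windows themselves: zero distance, perfect recall
  expect_equal(predict(fit, tr, type = "label"), tr$label)
  ## reference subsample respects the cap
  fit2 <- rr_classifier(tr, va, "nn1", spec = list(ref_cap = 50), seed = 1)
  expect_lte(fit2$meta$n_reference, 50)
})

test_that("classifier contract: leakage and window-length mismatches abort", {
  co <- tiny_cohort(2, 2, beats = 150, seed = 47)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "T001"))
  expect_error(rr_classifier(tr, tr, "nn1"), "leakage")
  va <- rr_cohort_windows(co, 60, persons = c("C002", "T002"))
  fit <- rr_classifier(tr, va, "nn1", seed = 1)
  va90 <- rr_cohort_windows(co, 90, persons = c("C002", "T002"))
  expect_error(predict(fit, va90), "mismatch")
})

test_that("MLP trains to a separable optimum and picks thresholds on the grid", {
  co <- tiny_cohort(3, 3, beats = 200, seed = 53)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "C002", "T001", "T002"))
  va <- rr_cohort_windows(co, 60, persons = c("C003", "T003"))
  fit <- rr_classifier(tr, va, "mlp", seed = 5,
                       spec = list(lr_grid = 1e-3, batch_grid = 256L,
                                   epochs = 25L, hidden = 16L))
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(fit$window_threshold %in% grid)
  expect_true(fit$person_threshold %in% grid)
  p <- predict(fit, va, type = "score")
  expect_true(all(p >= 0 & p <= 1))
  ## separable cohort: validation persons all called correctly
  dec <- rr_person_predict(fit, va)
  expect_equal(dec$label, as.integer(dec$true_group == "treatment"))
})

test_that("SVM+FSH selects hyperparameters within the stated range", {
  co <- tiny_cohort(3, 3, beats = 200, seed = 59)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "C002", "T001", "T002"))
  va <- rr_cohort_windows(co, 60, persons = c("C003", "T003"))
  fit <- rr_classifier(tr, va, "svm_fsh", seed = 2,
                       spec = list(per_class = 150L,
                                   cost_grid = c(0.1, 1, 10, 100),
                                   gamma_grid = c(0.1, 1)))
  expect_true(fit$meta$cost >= 0.1 && fit$meta$cost <= 100)
  expect_true(fit$meta$gamma >= 0.1 && fit$meta$gamma <= 100)
  expect_lte(fit$meta$n_features, 50)
  ## balanced subsample is exactly balanced when both classes are plentiful
  expect_equal(fit$meta$n_subsample, 2 * 150L)
  ## separable features: near-perfect training window accuracy
  expect_gte(mean(predict(fit, tr, type = "label") == tr$label), 0.99)
})

test_that("SVM ensemble partitions training windows into exclusive subsets", {
  co <- tiny_cohort(3, 3, beats = 200, seed = 61)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "C002", "T001", "T002"))
  va <- rr_cohort_windows(co, 60, persons = c("C003", "T003"))
  fit <- rr_classifier(tr, va, "svm_ensemble", seed = 3,
                       spec = list(n_members = 5L, cost_grid = 1,
                                   gamma_grid = 0.1))
  ## every training window used by exactly one member
  expect_length(fit$assignment, nrow(tr$values))
  expect_setequal(unique(fit$assignment), 1:5)
  ## an even member count has no defined majority
  expect_error(rr_classifier(tr, va, "svm_ensemble",
                             spec = list(n_members = 4L)), "odd")
  ## single-member ensemble: vote equals the member's own prediction
  fit1 <- rr_classifier(tr, va, "svm_ensemble", seed = 3,
                        spec = list(n_members = 1L, cost_grid = 1,
                                    gamma_grid = 0.1))
  x5 <- rr_summary5(va)
  member <- as.integer(as.character(predict(fit1$members[[1]], x5)))
  expect_equal(predict(fit1, va, type = "label"), member)
})

test_that("XGBoost picks grid cells from the stated sets and a 50%-biased person threshold", {
  co <- tiny_cohort(3, 3, beats = 200, seed = 67)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "C002", "T001", "T002"))
  va <- rr_cohort_windows(co, 60, persons = c("C003", "T003"))
  fit <- rr_classifier(tr, va, "xgboost", seed = 4,
                       spec = list(n_estimators = c(10L, 50L),
                                   max_depth = c(5L, 10L)))
  expect_true(fit$meta$n_estimators %in% c(10L, 50L))
  expect_true(fit$meta$max_depth %in% c(5L, 10L))
  ## separable validation: every threshold near 0.5 is optimal, rule picks 0.50
  expect_equal(fit$person_threshold, 0.50)
  expect_error(rr_classifier(tr, va, "xgboost",
                             spec = list(n_estimators = integer(0))), "grid")
})

test_that("GRU+FCN trains under its epoch budget and separates the cohort", {
  co <- tiny_cohort(2, 2, beats = 150, seed = 71)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "T001"))
  va <- rr_cohort_windows(co, 60, persons = c("C002", "T002"))
  spec <- list(hidden = 8L, conv_channels = c(8L, 12L, 8L), epochs = 4L,
               batch = 64L, lr = 1e-2, dropout = 0.2)
  fit <- rr_classifier(tr, va, "gru_fcn", seed = 6, spec = spec)
  p <- predict(fit, va, type = "score")
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean(predict(fit, va, type = "label") == va$label), 0.9)
  ## window shorter than the largest kernel is rejected
  tr6 <- rr_cohort_windows(co, 6, persons = c("C001", "T001"))
  va6 <- rr_cohort_windows(co, 6, persons = c("C002", "T002"))
  expect_error(rr_classifier(tr6, va6, "gru_fcn", spec = spec), "kernel")
})

test_that("stochastic fits are bit-reproducible under a fixed seed", {
  co <- tiny_cohort(2, 2, beats = 150, seed = 73)
  tr <- rr_cohort_windows(co, 60, persons = c("C001", "T001"))
  va <- rr_cohort_windows(co, 60, persons = c("C002", "T002"))
  for (m in c("nn1", "svm_ensemble", "xgboost")) {
    sp <- small_specs()[[m]]
    f1 <- rr_classifier(tr, va, m, spec = sp, seed = 9)
    f2 <- rr_classifier(tr, va, m, spec = sp, seed = 9)
    expect_identical(predict(f1, va, type = "score"),
                     predict(f2, va, type = "score"))
    expect_identical(f1$person_threshold, f2$person_threshold)
  }
  sp <- small_specs()$mlp
  f1 <- rr_classifier(tr, va, "mlp", spec = sp, seed = 9)
  f2 <- rr_classifier(tr, va, "mlp", spec = sp, seed = 9)
  expect_identical(predict(f1, va, type = "score"),
                   predict(f2, va, type = "score"))
})
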