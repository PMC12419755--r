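ns <- asNamespace("rrscreen")

test_that("ordinal subsampling keeps positions 0, k, 2k, ... in order", {
  co <- tiny_cohort(2, 2, beats = 360, seed = 107)
  wins <- rr_cohort_windows(co, 60)          # 301 windows per person, 1204 total
  sub <- rr_subsample_every_k(wins, 500)
  expect_equal(nrow(sub$values), 3)
  expect_equal(sub$values[1, ], wins$values[1, ])
  expect_equal(sub$values[2, ], wins$values[501, ])
  expect_equal(sub$values[3, ], wins$values[1001, ])
  ## k = 1 is the identity; order preserved
  id <- rr_subsample_every_k(wins, 1)
  expect_equal(id$values, wins$values)
  expect_equal(id$person_id, wins$person_id)
})

test_that("random-forest probe separates the default cohort and is seeded", {
  co <- tiny_cohort(4, 4, beats = 400, seed = 109)
  sub <- rr_subsample_every_k(rr_cohort_windows(co, 60), 15)
  probe <- rr_rf_probe(sub, k = 2, seed = 5, ntree = 25, maxnodes = 16)
  expect_gte(probe$accuracy, 95)
  probe2 <- rr_rf_probe(sub, k = 2, seed = 5, ntree = 25, maxnodes = 16)
  expect_identical(probe$accuracy, probe2$accuracy)
})

test_that("label-shuffled probe accuracy sits at the permutation null", {
  co <- tiny_cohort(4, 4, beats = 400, seed = 113)
  sub <- rr_subsample_every_k(rr_cohort_windows(co, 60), 15)
  accs <- sapply(1:10, function(s) {
    shuf <- sub
    ## shuffle group labels at the person level (windows stay person-pure)
    persons <- unique(shuf$person_id)
    newg <- setNames(sample(c(rep("control", 4), rep("treatment", 4))),
                     persons)
    shuf$group <- unname(newg[shuf$person_id])
    shuf$label <- as.integer(shuf$group == "treatment")
    set.seed(s)
    rr_rf_probe(shuf, k = 2, seed = s, ntree = 25, maxnodes = 16)$accuracy
  })
  expect_gte(mean(accs), 40)
  expect_lte(mean(accs), 60)
})

test_that("single-split trees attribute everything to the split feature", {
  tr <- list(feature = c(1L, 0L, 0L), split = c(0.5, 0, 0),
             yes = c(2L, 0L, 0L), no = c(3L, 0L, 0L),
             value = c(0, 0, 1), cover = c(10, 5, 5))
  ens <- ns$new_tree_ensemble(list(tr), c("f1", "f2"))
  x <- cbind(f1 = c(0.2, 0.9), f2 = c(5, -5))
  att <- rr_shap_attribution(ens, x)
  expect_equal(unname(att$shap[, "f2"]), c(0, 0))
  expect_equal(unname(att$shap[, "f1"]), c(-0.5, 0.5))
  expect_equal(att$baseline, 0.5)
  expect_equal(att$output, c(0, 1))
})

test_that("local accuracy holds exactly for the synthetic probe", {
  co <- tiny_cohort(3, 3, beats = 400, seed = 127)
  sub <- rr_subsample_every_k(rr_cohort_windows(co, 60), 20)
  probe <- rr_rf_probe(sub, k = 3, seed = 7, ntree = 25, maxnodes = 16)
  att <- rr_shap_attribution(probe$ensemble, probe$features)
  expect_lte(att$local_accuracy_error, 1e-6)
  ## representation output equals the forest's vote fraction
  rfp <- predict(probe$model, probe$features, type = "prob")[, "1"]
  expect_equal(att$output, unname(rfp), tolerance = 1e-12)
})

test_that("attributions agree with an independent TreeSHAP implementation", {
  set.seed(131)
  x <- matrix(rnorm(200 * 6), 200, 6)
  colnames(x) <- paste0("f", 1:6)
  y <- as.integer(x[, 1] + 0.5 * x[, 3] + rnorm(200, 0, 0.3) > 0)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = 15, verbose = 0)
  cfg <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(bst,
                                                            raw_format = "json")))
  base <- as.numeric(cfg$learner$learner_model_param$base_score)
  ens <- rr_ensemble_from_xgb(bst, colnames(x), base_offset = qlogis(base))
  att <- rr_shap_attribution(ens, x[1:30, ])
  ref <- predict(bst, xgboost::xgb.DMatrix(x[1:30, ]), predcontrib = TRUE)
  expect_equal(unname(att$shap), unname(ref[, 1:6]), tolerance = 1e-5)
  expect_equal(att$baseline, unname(ref[1, 7]), tolerance = 1e-5)
})

test_that("group ACF table is shaped by strata and directionally faithful", {
  co <- tiny_cohort(5, 5, beats = 800, seed = 137)
  tab <- rr_acf_group_table(co, w = c(60, 300), lags = 1:4)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$control_sd >= 0) && all(tab$treatment_sd >= 0))
  r60 <- tab[tab$w == 60, ]
  expect_gt(r60$control_mean[r60$lag == 1], r60$treatment_mean[r60$lag == 1])
  expect_gt(r60$treatment_mean[r60$lag == 4], r60$control_mean[r60$lag == 4])
})

test_that("one-profile groups show no systematic ACF separation", {
  co <- null_cohort(5, 5, beats = 800, seed = 139)
  ## near-disjoint windows so window-level standard errors are meaningful
  wins <- rr_cohort_windows(co, 60, step = 60)
  a <- ns$row_acf(wins$values, 1)
  ctrl <- a[wins$group == "control"]; trt <- a[wins$group == "treatment"]
  se <- sqrt(var(ctrl) / length(ctrl) + var(trt) / length(trt))
  expect_lte(abs(mean(ctrl) - mean(trt)), 2 * se + 0.02)
})

test_that("attribution export tables are plot-ready", {
  co <- tiny_cohort(2, 2, beats = 300, seed = 149)
  sub <- rr_subsample_every_k(rr_cohort_windows(co, 60), 30)
  probe <- rr_rf_probe(sub, k = 2, seed = 3, ntree = 10, maxnodes = 8)
  att <- rr_shap_attribution(probe$ensemble, probe$features[1:12, ])
  tabs <- rr_attribution_tables(att, probe$features[1:12, ])
  expect_equal(nrow(tabs$beeswarm), 12 * 10)
  expect_equal(nrow(tabs$heatmap), 12)
  expect_false(is.unsorted(tabs$heatmap$model_output))
})
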