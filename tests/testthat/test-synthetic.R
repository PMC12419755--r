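test_that("zero-innovation AR generator collapses to the profile mean", {
  p <- rr_profile("control", mu_rr = 800, sigma_innov = 0, ar_coeffs = 0.5)
  r <- rr_generate_person(p, 100, seed = 1)
  expect_equal(r$rr_ms, rep(800, 100))
})

test_that("AR(1) generator reproduces the closed-form lag-1 autocorrelation", {
  p <- rr_profile("control", mu_rr = 800, sigma_innov = 20, ar_coeffs = 0.8)
  for (s in 1:5) {
    r <- rr_generate_person(p, 10000, seed = s)
    expect_lt(abs(rr_acf(r$rr_ms, 1) - 0.8), 0.05)
  }
})

test_that("generation is bit-reproducible under a seed and varies across seeds", {
  p <- rr_default_profiles()$treatment
  a <- rr_generate_person(p, 500, seed = 42)
  b <- rr_generate_person(p, 500, seed = 42)
  c <- rr_generate_person(p, 500, seed = 43)
  expect_identical(a$rr_ms, b$rr_ms)
  expect_false(identical(a$rr_ms, c$rr_ms))
})

test_that("non-stationary AR coefficients are rejected, stationary accepted", {
  expect_error(rr_profile("control", 800, 10, ar_coeffs = 1.0),
               "non-stationary")
  expect_error(rr_profile("control", 800, 10, ar_coeffs = c(0.6, 0.6)),
               "non-stationary")
  expect_s3_class(rr_profile("control", 800, 10, ar_coeffs = 0.5),
                  "rr_profile")
})

test_that("activity injection follows the episode model", {
  prof <- rr_profile("control", 800, 0, activity_rate = 0,
                     activity_drop = 0.2, activity_len = 10)
  rec <- rr_recording("p", "control", rep(800, 100))

  ## rate 0, no forced starts: identity
  out0 <- rr_inject_activity(rec, prof, seed = 1)
  expect_equal(out0$rr_ms, rec$rr_ms)

  ## forced episode: covered beats scaled by 1 - drop
  out <- rr_inject_activity(rec, prof, starts = 11)
  expect_equal(out$rr_ms[11:20], rep(640, 10))
  expect_equal(out$rr_ms[-(11:20)], rep(800, 90))
  expect_length(out$rr_ms, 100)

  ## on AR data, affected beats are shorter on average
  prof2 <- rr_profile("control", 850, 40, ar_coeffs = 0.5,
                      activity_rate = 5, activity_drop = 0.3,
                      activity_len = 30)
  rec2 <- rr_generate_person(prof2, 2000, seed = 5)
  out2 <- rr_inject_activity(rec2, prof2, seed = 9)
  idx <- attr(out2, "activity_idx")
  expect_gt(length(idx), 0)
  expect_lt(mean(out2$rr_ms[idx]), mean(out2$rr_ms[-idx]))
  expect_true(all(out2$rr_ms >= 200))
})

test_that("cohort generation matches its specification and round-trips CSV", {
  co <- tiny_cohort(2, 2, beats = 400, seed = 7)
  expect_length(co$recordings, 4)
  expect_equal(nrow(co$manifest), 4)
  expect_equal(as.integer(table(co$manifest$group)[c("control", "treatment")]),
               c(2L, 2L))
  expect_false(anyDuplicated(co$manifest$person_id) > 0)
  expect_true(all(vapply(co$recordings, length, integer(1)) == 400))

  ## same spec reproduces; different seed gives different data, same shape
  co2 <- rr_generate_cohort(rr_cohort_spec(2, 2, beats_per_person = 400,
                                           seed = 7))
  expect_identical(co$recordings[["C001"]]$rr_ms,
                   co2$recordings[["C001"]]$rr_ms)
  co3 <- rr_generate_cohort(rr_cohort_spec(2, 2, beats_per_person = 400,
                                           seed = 8))
  expect_false(identical(co$recordings[["C001"]]$rr_ms,
                         co3$recordings[["C001"]]$rr_ms))
  expect_identical(co$manifest[, c("person_id", "group")],
                   co3$manifest[, c("person_id", "group")])

  dir <- withr::local_tempdir()
  mf <- rr_write_cohort(co, dir)
  back <- rr_read_cohort(mf)
  expect_equal(back$manifest$person_id, co$manifest$person_id)
  expect_equal(back$recordings[["T002"]]$rr_ms, co$recordings[["T002"]]$rr_ms)
})

test_that("default profiles encode the documented group orderings", {
  co <- tiny_cohort(5, 5, beats = 1500, seed = 31)
  wins <- rr_cohort_windows(co, 60, step = 60)
  is_ctrl <- wins$group == "control"

  ## mean R-R: control longer
  expect_gt(mean(wins$values[is_ctrl, ]), mean(wins$values[!is_ctrl, ]))

  ## within-window SD: control larger
  s5 <- rr_summary5(wins)
  expect_gt(mean(sqrt(s5[is_ctrl, "var"])), mean(sqrt(s5[!is_ctrl, "var"])))

  ## lag structure: lag-1 control-dominant, lag-4 treatment-dominant
  x7 <- rr_explain7(wins)
  expect_gt(mean(x7[is_ctrl, "acf_1"], na.rm = TRUE),
            mean(x7[!is_ctrl, "acf_1"], na.rm = TRUE))
  expect_gt(mean(x7[!is_ctrl, "acf_4"], na.rm = TRUE),
            mean(x7[is_ctrl, "acf_4"], na.rm = TRUE))
})
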