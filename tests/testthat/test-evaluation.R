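test_that("relative accuracy follows the <3% discrepancy definition", {
  expect_identical(estimation_accuracy(10.2, 10.0), 1)   # 1.96% discrepancy
  expect_identical(estimation_accuracy(10.0, 11.0), 0)   # 10% discrepancy
  expect_identical(estimation_accuracy(c(10.2, 10.0), c(10.0, 11.0)), 0.5)
  x <- c(3.7, 6.9, 10.4)
  expect_identical(estimation_accuracy(x, x), 1)
  # non-decreasing in the tolerance
  true <- seq(2, 12, length.out = 11)
  est <- true + seq(-0.5, 0.5, length.out = 11)
  accs <- vapply(c(0.01, 0.03, 0.05, 0.10, 0.5),
                 function(tol) estimation_accuracy(true, est, tol), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_error(estimation_accuracy(c(1, 0), c(1, 1)), "positive")
})

test_that("Bland-Altman statistics use est-true errors and n-1 SD", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(ba0$bias, ba0$error_sd, ba0$loa_low, ba0$loa_high),
                   c(0, 0, 0, 0))

  ba <- bland_altman(c(5, 5), c(5.1, 4.9))
  expect_equal(ba$bias, 0)
  expect_equal(ba$error_sd, sqrt(0.02), tolerance = 1e-12)    # 0.1414
  expect_equal(ba$loa_high, 1.96 * sqrt(0.02), tolerance = 1e-12)  # 0.2772

  expect_error(bland_altman(1, 1), "2 pairs")

  # LoA identity on arbitrary data
  set.seed(1)
  for (i in 1:5) {
    true <- runif(20, 2, 12)
    est <- true + rnorm(20, 0, 0.4)
    b <- bland_altman(true, est)
    expect_equal(b$loa_high - b$bias, 1.96 * b$error_sd, tolerance = 1e-12)
    expect_equal(b$loa_high - b$loa_low, 2 * 1.96 * b$error_sd, tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches hand computation", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5) + 7), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(1:2, 1:2), "3 pairs")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "degenerate")
})

test_that("cross-validation folds are balanced, disjoint and reproducible", {
  f32 <- lactecg:::cv_fold_assignment(32, 4, seed = 2)
  expect_identical(sort(as.integer(table(f32))), rep(8L, 4))
  f31 <- lactecg:::cv_fold_assignment(31, 4, seed = 2)
  expect_identical(sort(as.integer(table(f31))), c(7L, 8L, 8L, 8L))
  expect_identical(f31, lactecg:::cv_fold_assignment(31, 4, seed = 2))
  expect_false(identical(f31, lactecg:::cv_fold_assignment(31, 4, seed = 3)))
})

test_that("a perfect oracle predictor yields accuracy 1 with zero variance", {
  prep <- lm_prep_small()
  oracle <- function(train, session) session$true_blc
  cv <- fourfold_cv(prep, seed = 4, predictor = oracle)
  expect_identical(cv$fold_accuracies, rep(1, 4))
  expect_identical(cv$mean, 1)
  expect_identical(cv$variance, 0)
  # folds cover all sessions exactly once
  expect_identical(sort(cv$per_session$session_id),
                   sort(vapply(prep, `[[`, character(1), "session_id")))
  expect_error(fourfold_cv(structure(prep[1:3], class = "prepared_sessions")),
               "at least 4")
})

test_that("the beat-count sweep reuses cached per-beat predictions", {
  prep <- lm_prep_small()
  oracle <- function(train, session) session$true_blc
  sw <- sweep_beat_count(prep, counts = c(1, 10, 180), seed = 4,
                         predictor = oracle)
  expect_identical(sw$count, c(1L, 10L, 180L))
  expect_identical(sw$accuracy, rep(1, 3))

  sw1 <- sweep_beat_count(prep, counts = 180, seed = 4, predictor = oracle)
  expect_identical(nrow(sw1), 1L)

  # a biased predictor whose per-beat noise only averages out over a window
  noisy <- function(train, session) {
    n <- dim(session$images)[3]
    session$true_blc + rep(c(-2, 2), length.out = n)
  }
  cvn <- fourfold_cv(prep, seed = 4, predictor = noisy)
  swn <- sweep_beat_count(prep, counts = c(1, 50), cv_result = cvn)
  expect_gte(swn$accuracy[2], swn$accuracy[1])
})

test_that("evaluation reports carry the LoA identity and regime guard", {
  bundle <- lm_bundle_small()
  prep <- lm_prep_small()
  rep_lm <- evaluate_sessions(bundle, prep, n_beats = 50)
  expect_s3_class(rep_lm, "evaluation_report")
  expect_equal(rep_lm$loa_high - rep_lm$bias, 1.96 * rep_lm$error_sd,
               tolerance = 1e-12)
  expect_true(rep_lm$accuracy >= 0 && rep_lm$accuracy <= 1)
  expect_identical(nrow(rep_lm$per_session), length(prep))

  h_cohort <- simulate_cohort(2, "H", n_beats = 20, seed = 33)
  h_prep <- prepare_session_inputs(h_cohort, image_size = 32)
  expect_error(evaluate_sessions(bundle, h_prep), "refuses")
  expect_message(
    evaluate_sessions(bundle, h_prep, allow_regime_mismatch = TRUE),
    "override")
})
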