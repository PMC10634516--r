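test_that("architecture constants: 300-d features, 304-wide fusion, 16 outputs", {
  for (depth in c(6, 34)) {
    cfg <- model_config("LM", backbone_depth = depth,
                        image_size = if (depth == 34) 128 else 32)
    expect_identical(cfg$feature_dim, 300L)
    expect_identical(cfg$fusion_input_dim, 304L)
    expect_identical(cfg$fusion_layers, 4L)
    expect_identical(cfg$n_outputs, 16L)
    bundle <- build_blc_model(cfg)
    expect_identical(nrow(bundle$params[["feat.w"]]), 300L)
    expect_identical(ncol(bundle$params[["fc1.w"]]), 304L)
    expect_identical(nrow(bundle$params[["out.w"]]), 16L)
  }
  # a forward pass through the reduced backbone emits a 300-vector and
  # 16 probabilities
  cfg <- test_config()
  bundle <- build_blc_model(cfg)
  x <- array(runif(32 * 32), dim = c(32, 32, 1, 1))
  fwd <- lactecg:::nn_forward(bundle$params, cfg, x, matrix(0, 4, 1))
  expect_identical(dim(fwd$feat), c(300L, 1L))
  expect_identical(dim(fwd$probs), c(16L, 1L))
  expect_true(all(fwd$probs > 0 & fwd$probs < 1))
})

test_that("a one-sample dataset is memorized", {
  rec <- tiny_record(n_beats = 6, blc = 4.8)
  beats <- segment_beats(rec, rec$r_peaks)
  imgs <- beats_to_images(beats[1], 32, 32)
  ds <- list(images = imgs$images,
             cov = make_covariates(list(age = 30, sex = "female", bmi = 22),
                                   imgs$rr),
             blc = 4.8, intensity = "M", session_id = "s1")
  cfg <- test_config(epochs = 150, batch_size = 1, learning_rate = 1e-2)
  bundle <- train_blc_model(ds, cfg)
  expect_lt(tail(bundle$training_log$loss, 1), 0.01)
  est <- predict_blc_beat(bundle, imgs$images[, , 1],
                          list(age = 30, sex = "female", bmi = 22), imgs$rr[1])
  expect_identical(est, 4.8)
})

test_that("training is deterministic under a fixed seed", {
  prep <- lm_prep_small()
  ds <- build_beat_dataset(prep, beats_per_session = 4)
  cfg <- test_config(epochs = 3)
  b1 <- train_blc_model(ds, cfg)
  b2 <- train_blc_model(ds, cfg)
  expect_identical(b1$training_log$loss, b2$training_log$loss)
  expect_identical(b1$params, b2$params)

  s <- prep[[1]]
  v1 <- predict_blc_session(b1, list(images = s$images, rr = s$rr), s$subject)
  v2 <- predict_blc_session(b2, list(images = s$images, rr = s$rr), s$subject)
  expect_identical(v1, v2)
})

test_that("bundles reload to identical predictions", {
  bundle <- lm_bundle_small()
  path <- withr::local_tempfile(fileext = ".rds")
  save_blc_model(bundle, path)
  back <- load_blc_model(path)
  s <- lm_prep_small()[[2]]
  expect_identical(
    predict_blc_session(back, list(images = s$images, rr = s$rr), s$subject),
    predict_blc_session(bundle, list(images = s$images, rr = s$rr), s$subject))
})

test_that("beats held out from training sessions are recovered accurately", {
  # capacity check: training uses an evenly spaced subset of each session's
  # beats; the remaining beats of the *same* sessions must decode to their
  # session's lactate. (This within-session regime is the easy one; true
  # across-session generalization is measured by the cross-validation suite.)
  bundle <- lm_bundle_small()
  prep <- lm_prep_small()
  vals <- numeric(0); truth <- numeric(0)
  for (s in prep) {
    n <- dim(s$images)[3]
    # complement of the evenly spaced subsample build_beat_dataset trains on
    held <- setdiff(seq_len(n), unique(round(seq(1, n, length.out = 40))))
    pred <- lactecg:::predict_blc_beats(
      bundle, s$images[, , held], make_covariates(s$subject, s$rr[held]))
    vals <- c(vals, pred$values)
    truth <- c(truth, rep(s$true_blc, length(held)))
  }
  expect_gt(length(vals), 100)
  expect_gte(mean(abs(vals - truth) / truth < 0.03), 0.80)
})

test_that("prediction validates image size and decodes into codec range", {
  bundle <- lm_bundle_small()
  expect_error(predict_blc_beat(bundle, matrix(0, 64, 64),
                                list(age = 30, sex = "male", bmi = 22), 0.5),
               "image size")
  vals <- lactecg:::predict_blc_beats(
    bundle, array(runif(32 * 32 * 5), dim = c(32, 32, 5)),
    make_covariates(list(age = 30, sex = "male", bmi = 22), rep(0.5, 5)))$values
  expect_true(all(vals >= 0 & vals <= 255.9))
})

test_that("session prediction aggregates by median over the end window", {
  expect_identical(lactecg:::aggregate_beat_predictions(c(5.0, 5.2, 9.9), n_beats = 3),
                   5.2)
  expect_identical(lactecg:::aggregate_beat_predictions(rep(7.4, 10), n_beats = 180),
                   7.4)
  # window: only the final n values enter the median
  vals <- c(rep(1, 320), rep(6.8, 180))
  expect_identical(lactecg:::aggregate_beat_predictions(vals, n_beats = 180), 6.8)
  expect_identical(lactecg:::aggregate_beat_predictions(vals, n_beats = 1), 6.8)
  expect_identical(
    lactecg:::aggregate_beat_predictions(vals, n_beats = 180, anchor = "start"), 1)

  # n_beats = 1 reduces session prediction to the final beat
  bundle <- lm_bundle_small()
  s <- lm_prep_small()[[1]]
  n <- length(s$rr)
  last_beat <- lactecg:::predict_blc_beats(
    bundle, s$images[, , n], make_covariates(s$subject, s$rr[n]))$values
  expect_identical(
    predict_blc_session(bundle, list(images = s$images, rr = s$rr), s$subject,
                        n_beats = 1),
    round(last_beat, 1))
})

test_that("the default analysis window is 180 beats", {
  expect_identical(formals(predict_blc_session)$n_beats, 180)
  expect_identical(formals(select_beat_window)$n, 180)
})

test_that("training refuses empty regimes and uncodable labels", {
  prep <- lm_prep_small()
  ds <- build_beat_dataset(prep, beats_per_session = 2)
  expect_error(train_blc_model(ds, test_config(regime = "H")), "regime")
  ds$blc[] <- 300
  expect_error(train_blc_model(ds, test_config()), "codable")
})
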