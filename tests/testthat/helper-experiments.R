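# The parameter-recovery experiment at desk scale: 12 synthetic subjects,
# three sessions each (L, M, H), 200 beats per session, reduced 6-layer
# backbone on 32x32 images. Built once per test run and cached; used by the
# cross-validation, window-sweep and weighting tests.

recovery_config <- function(seed = 7) {
  model_config("LM", backbone_depth = 6, image_size = 32, fusion_hidden = 64,
               seed = seed, epochs = 40, batch_size = 32, learning_rate = 3e-3)
}

recovery_prepared <- function() {
  cached("recovery_prepared", {
    cohort <- simulate_cohort(12, c("L", "M", "H"), n_beats = 200,
                              noise_sd = 0.01, seed = 20240)
    prep <- prepare_session_inputs(cohort, image_size = 32)
    keep <- vapply(prep, `[[`, character(1), "intensity") %in% c("L", "M")
    structure(prep[keep], class = "prepared_sessions")
  })
}

recovery_cv <- function() {
  cached("recovery_cv", {
    fourfold_cv(recovery_prepared(), recovery_config(), seed = 7,
                n_beats = 180, beats_per_session = 40)
  })
}

# Five independent train/holdout splits (one fold held out per seed); per-beat
# predictions on held-out sessions let any window size be scored afterwards.
recovery_seed_runs <- function(seeds = 101:105) {
  cached("recovery_seed_runs", {
    prep <- recovery_prepared()
    lapply(seeds, function(s) {
      folds <- lactecg:::cv_fold_assignment(length(prep), 4, seed = s)
      test_idx <- which(folds == 1)
      train_prep <- structure(prep[folds != 1], class = "prepared_sessions")
      ds <- build_beat_dataset(train_prep, beats_per_session = 40)
      bundle <- train_blc_model(ds, recovery_config(seed = s))
      held <- lapply(test_idx, function(i) {
        sess <- prep[[i]]
        list(true = sess$true_blc,
             beat_values = lactecg:::predict_blc_beats(
               bundle, sess$images, make_covariates(sess$subject, sess$rr))$values)
      })
      list(seed = s, bundle = bundle, held = held)
    })
  })
}

# Session accuracy and MAE for a given window size from one seed run.
score_seed_run <- function(run, n_beats, tolerance = 0.03) {
  true <- vapply(run$held, `[[`, numeric(1), "true")
  est <- vapply(run$held, function(h) {
    lactecg:::aggregate_beat_predictions(h$beat_values, n_beats = n_beats)
  }, numeric(1))
  c(accuracy = estimation_accuracy(true, est, tolerance),
    mae = mean(abs(est - true)))
}
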