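# Shared fixtures. Expensive artifacts (prepared cohorts, trained bundles)
# are built lazily once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, clean single-session record with ground truth.
tiny_record <- function(n_beats = 30, intensity = "M", blc = 5.2,
                        noise_sd = 0, jitter = 0, seed = 42) {
  spec <- session_spec(intensity, true_blc = blc, n_beats = n_beats)
  generate_session_ecg(list(age = 30, sex = "female", bmi = 22), spec,
                       noise_sd = noise_sd, rr_jitter_cv = jitter, seed = seed,
                       wander_amp = if (noise_sd == 0 && jitter == 0) 0 else 0.05)
}

# The reduced desk-scale model configuration used throughout the suite.
test_config <- function(regime = "LM", seed = 5, epochs = 40, batch_size = 32,
                        learning_rate = 3e-3, fusion_hidden = 64, ...) {
  model_config(regime = regime, backbone_depth = 6, image_size = 32,
               fusion_hidden = fusion_hidden, seed = seed, epochs = epochs,
               batch_size = batch_size, learning_rate = learning_rate, ...)
}

# Small low-noise LM cohort, preprocessed once.
lm_prep_small <- function() {
  cached("lm_prep_small", {
    cohort <- simulate_cohort(6, c("L", "M"), n_beats = 80, noise_sd = 0.01,
                              seed = 11)
    prepare_session_inputs(cohort, image_size = 32)
  })
}

# A trained bundle on the small LM cohort (memorization-scale).
lm_bundle_small <- function() {
  cached("lm_bundle_small", {
    ds <- build_beat_dataset(lm_prep_small(), beats_per_session = 40)
    train_blc_model(ds, test_config())
  })
}
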