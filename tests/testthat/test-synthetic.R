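test_that("subject generation is deterministic and matches cohort moments", {
  s1 <- generate_subjects(5, seed = 3)
  s2 <- generate_subjects(5, seed = 3)
  expect_identical(s1, s2)

  big <- generate_subjects(10000, seed = 9)
  # Monte-Carlo check against the truncated-normal oracle: truncating
  # Normal(mu, sigma) to [a, b] shifts the mean by
  # sigma * (phi(alpha) - phi(beta)) / (Phi(beta) - Phi(alpha))
  trunc_mean <- function(mu, sigma, a, b) {
    al <- (a - mu) / sigma; be <- (b - mu) / sigma
    mu + sigma * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  }
  expect_true(abs(mean(big$age) - trunc_mean(33, 9, 18, 80)) < 0.3)
  expect_true(abs(mean(big$bmi) - trunc_mean(22.8, 2.7, 15, 40)) < 0.2)
  expect_true(all(big$age >= 18 & big$age <= 80))
  expect_true(all(big$bmi >= 15 & big$bmi <= 40))
  expect_true(abs(mean(big$sex == "female") - 17 / 31) < 0.02)
})

test_that("lactate draws follow the per-intensity distributions", {
  draws <- sample_blc("H", n = 20000, seed = 4)
  expect_true(abs(mean(draws) - 10.4) < 0.3)
  expect_true(all(draws >= 0.5 & draws <= 25.5))
  # exactly one decimal place
  expect_equal(draws, round(draws, 1))
  # degenerate distribution collapses to the mean
  expect_identical(sample_blc("L", seed = 1, sd = 0), 3.7)
  expect_error(sample_blc("X"), "arg")
})

test_that("beat template applies the declared lactate-morphology mapping", {
  rest <- beat_template(0, 0.8)
  expect_identical(beat_template(0, 0.8), rest)        # lambda = 0 identity
  expect_length(rest, round(0.8 * 200))

  r_ix <- attr(rest, "r_index")
  t_peak <- function(v) max(v[(r_ix + 30):length(v)])  # T region, past QRS
  full <- beat_template(15, 0.8)
  half <- beat_template(7.5, 0.8)
  expect_equal(t_peak(full) / t_peak(rest), 1.50, tolerance = 0.01)
  expect_equal(max(half) / max(rest), 0.95, tolerance = 0.01)
  # saturation at 15 mmol/L
  expect_identical(beat_template(20, 0.8), full)
  expect_error(beat_template(5, 0.2), "rr")
})

test_that("morphology is monotone in lactate on the template", {
  blcs <- c(0, 3, 6, 9, 12, 15)
  r_amp <- numeric(length(blcs))
  t_amp <- numeric(length(blcs))
  for (i in seq_along(blcs)) {
    v <- beat_template(blcs[i], 0.7)
    r_ix <- attr(v, "r_index")
    r_amp[i] <- max(v)
    t_amp[i] <- max(v[(r_ix + 25):length(v)])
  }
  expect_true(all(diff(r_amp) < 0))
  expect_true(all(diff(t_amp) > 0))
})

test_that("session generation is deterministic with exact noiseless spacing", {
  subj <- list(age = 30, sex = "male", bmi = 23)
  spec <- session_spec("H", true_blc = 9.0, duration = 240)
  rec1 <- generate_session_ecg(subj, spec, noise_sd = 0, rr_jitter_cv = 0,
                               wander_amp = 0, seed = 1)
  rec2 <- generate_session_ecg(subj, spec, noise_sd = 0, rr_jitter_cv = 0,
                               wander_amp = 0, seed = 1)
  expect_identical(rec1$samples, rec2$samples)
  expect_identical(rec1$r_peaks, rec2$r_peaks)

  # noiseless, jitter-free: peaks spaced exactly round(fs * 60 / hr)
  expect_true(all(diff(rec1$r_peaks) == round(200 * 60 / 170)))
  # duration * hr / 60 beats, ground truth peaks = concatenated beats
  expect_identical(length(rec1$r_peaks), as.integer(floor(240 * 170 / 60)))

  expect_error(
    generate_session_ecg(subj, session_spec("H", true_blc = 9, duration = 0.1)),
    "too short")
})

test_that("cohort simulation round-trips through CSV", {
  cohort <- simulate_cohort(2, c("L", "H"), n_beats = 12, seed = 21)
  expect_s3_class(cohort, "blc_cohort")
  expect_length(cohort, 4)
  info <- cohort_table(cohort)
  expect_identical(info$intensity, rep(c("L", "H"), 2))
  expect_true(all(info$true_blc >= 0.5 & info$true_blc <= 25.5))

  dir <- withr::local_tempdir()
  write_cohort_csv(cohort, dir)
  back <- read_cohort_csv(dir)
  expect_length(back, 4)
  expect_equal(back[[3]]$record$samples, cohort[[3]]$record$samples,
               tolerance = 1e-9)
  expect_identical(back[[3]]$record$r_peaks, cohort[[3]]$record$r_peaks)
  expect_identical(back[[3]]$spec$true_blc, cohort[[3]]$spec$true_blc)
})
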