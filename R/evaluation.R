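#' Preprocess a cohort into per-session model inputs
#'
#' Runs R-peak detection (or uses ground-truth annotations), beat
#' segmentation and image rendering for every session of a cohort.
#'
#' @param cohort a [simulate_cohort()] / [read_cohort_csv()] result.
#' @param image_size image side length in pixels.
#' @param v_range voltage window in mV for image rendering.
#' @param use_annotations use the record's ground-truth R peaks instead of
#'   running the detector.
#' @return An object of class `prepared_sessions`: per session a list with
#'   `images` (H x W x n), `rr` (seconds), `subject`, `true_blc`,
#'   `intensity`, `session_id`.
#' @export
prepare_session_inputs <- function(cohort, image_size = 128,
                                   v_range = c(-1.5, 2.0),
                                   use_annotations = FALSE) {
  out <- lapply(cohort, function(s) {
    peaks <- if (use_annotations && !is.null(s$record$r_peaks)) {
      s$record$r_peaks
    } else {
      detect_r_peaks(s$record)
    }
    beats <- segment_beats(s$record, peaks)
    imgs <- beats_to_images(beats, image_size, image_size, v_range)
    list(images = imgs$images, rr = imgs$rr, subject = s$subject,
         true_blc = s$spec$true_blc, intensity = s$spec$intensity,
         session_id = s$session_id)
  })
  structure(out, class = "prepared_sessions")
}

#' Fraction of estimates within a relative tolerance of the truth
#'
#' An estimate counts as correct when its discrepancy from the true value is
#' below 3% of the true value (the sweep and cross-validation statistic):
#' `|est - true| / true < tolerance`.
#'
#' @param true_vals true lactate values, mmol/L (all > 0).
#' @param est_vals estimated values, same length.
#' @param tolerance relative tolerance (default 0.03).
#' @return Fraction in \[0, 1\].
#' @export
estimation_accuracy <- function(true_vals, est_vals, tolerance = 0.03) {
  stopifnot(length(true_vals) == length(est_vals), length(true_vals) >= 1)
  if (any(true_vals <= 0)) {
    stop("true values must be positive for relative accuracy", call. = FALSE)
  }
  mean(abs(est_vals - true_vals) / true_vals < tolerance)
}

#' Bland-Altman agreement statistics
#'
#' Errors are `est - true`; the bias is their mean, the error SD uses the
#' n - 1 denominator, and the 95% limits of agreement are bias +/- 1.96 SD.
#'
#' @param true_vals,est_vals paired measurements (n >= 2).
#' @return Object of class `bland_altman` with `bias`, `error_sd`, `loa_low`,
#'   `loa_high`, `errors` and `means`.
#' @export
bland_altman <- function(true_vals, est_vals) {
  stopifnot(length(true_vals) == length(est_vals))
  if (length(true_vals) < 2) stop("need at least 2 pairs", call. = FALSE)
  errors <- est_vals - true_vals
  bias <- mean(errors)
  error_sd <- sd(errors)
  structure(list(bias = bias, error_sd = error_sd,
                 loa_low = bias - 1.96 * error_sd,
                 loa_high = bias + 1.96 * error_sd,
                 errors = errors, means = (true_vals + est_vals) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4f, SD %.4f, LoA [%.4f, %.4f] mmol/L (n = %d)\n",
              x$bias, x$error_sd, x$loa_low, x$loa_high, length(x$errors)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$errors, xlab = "mean of true and estimated (mmol/L)",
                 ylab = "estimation error (mmol/L)", pch = 16, ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param true_vals,est_vals paired values (n >= 3, both with nonzero
#'   variance).
#' @return Correlation coefficient.
#' @export
pearson_r <- function(true_vals, est_vals) {
  stopifnot(length(true_vals) == length(est_vals))
  if (length(true_vals) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(true_vals) < 1e-12 || sd(est_vals) < 1e-12) {
    stop("degenerate variance: correlation undefined", call. = FALSE)
  }
  cor(true_vals, est_vals)
}

#' Evaluate a trained model on prepared sessions
#'
#' One prediction per session (median over the beat window), compared with
#' the true lactate. A bundle refuses sessions outside its regime unless
#' explicitly overridden.
#'
#' @param bundle a trained `blc_model`.
#' @param prepared a `prepared_sessions` object.
#' @param n_beats analysis window (default 180 beats).
#' @param tolerance relative accuracy tolerance (default 0.03).
#' @param allow_regime_mismatch evaluate sessions outside the bundle's regime
#'   anyway (logged with a message).
#' @return Object of class `evaluation_report`: `per_session` data frame
#'   (`session_id`, `true_blc`, `est_blc`, `error`), `bias`, `error_sd`,
#'   `loa_low`, `loa_high`, `pearson_r`, `accuracy`, `regime`.
#' @export
evaluate_sessions <- function(bundle, prepared, n_beats = 180,
                              tolerance = 0.03,
                              allow_regime_mismatch = FALSE) {
  stopifnot(inherits(bundle, "blc_model"), inherits(prepared, "prepared_sessions"))
  intens <- vapply(prepared, `[[`, character(1), "intensity")
  ok <- intens %in% regime_intensities(bundle$config$regime)
  if (!all(ok)) {
    if (!allow_regime_mismatch) {
      stop(sprintf("bundle regime %s refuses %d session(s) of other regimes; set allow_regime_mismatch = TRUE to override",
                   bundle$config$regime, sum(!ok)), call. = FALSE)
    }
    message(sprintf("evaluating %d session(s) outside regime %s by explicit override",
                    sum(!ok), bundle$config$regime))
  }
  est <- vapply(prepared, function(s) {
    predict_blc_session(bundle, list(images = s$images, rr = s$rr), s$subject,
                        n_beats = n_beats)
  }, numeric(1))
  true <- vapply(prepared, `[[`, numeric(1), "true_blc")
  ba <- bland_altman(true, est)
  structure(list(
    per_session = data.frame(
      session_id = vapply(prepared, `[[`, character(1), "session_id"),
      true_blc = true, est_blc = est, error = est - true,
      stringsAsFactors = FALSE),
    bias = ba$bias, error_sd = ba$error_sd,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    pearson_r = tryCatch(pearson_r(true, est), error = function(e) NA_real_),
    accuracy = estimation_accuracy(true, est, tolerance),
    regime = bundle$config$regime
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> regime %s, %d sessions\n", x$regime,
              nrow(x$per_session)))
  cat(sprintf("  accuracy (<3%% discrepancy): %.3f\n", x$accuracy))
  cat(sprintf("  bias %.3f, error SD %.3f, LoA [%.3f, %.3f] mmol/L, r = %.3f\n",
              x$bias, x$error_sd, x$loa_low, x$loa_high, x$pearson_r))
  invisible(x)
}

# Random fold assignment: 4 folds of equal size +/- 1, reproducible by seed.
cv_fold_assignment <- function(n, k = 4, seed = 1) {
  with_local_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
}

#' Fourfold cross-validation at the session level
#'
#' Sessions are randomly partitioned into four folds of equal size (+/- 1);
#' each fold is held out once while a model is trained on the remaining
#' three, and held-out sessions are scored with [estimation_accuracy()].
#' Partitioning is at the session level so a session's beats never straddle
#' folds. Per-beat predictions for every held-out session are retained so
#' window sweeps can be recomputed without retraining.
#'
#' @param prepared a `prepared_sessions` object (sessions outside
#'   `config$regime` are dropped first).
#' @param config a [model_config()]; ignored when `predictor` is supplied.
#' @param seed seed for the fold assignment.
#' @param n_beats analysis window for session predictions.
#' @param beats_per_session training-time beat subsample per session.
#' @param tolerance relative accuracy tolerance.
#' @param predictor optional stand-in for the trained model: a
#'   `function(train_sessions, test_session)` returning per-beat lactate
#'   estimates (recycled if length 1) for the test session. Used for
#'   plumbing tests and baselines.
#' @return Object of class `cv_result`: `fold_accuracies` (4 fractions),
#'   `mean`, `variance`, `per_session` data frame (with fold and estimate),
#'   `beat_values` (list of per-beat estimates per session).
#' @export
fourfold_cv <- function(prepared, config = NULL, seed = 1, n_beats = 180,
                        beats_per_session = NULL, tolerance = 0.03,
                        predictor = NULL) {
  stopifnot(inherits(prepared, "prepared_sessions"))
  if (!is.null(config)) {
    keep <- vapply(prepared, `[[`, character(1), "intensity") %in%
      regime_intensities(config$regime)
    prepared <- structure(prepared[keep], class = "prepared_sessions")
  }
  n <- length(prepared)
  if (n < 4) stop("need at least 4 sessions for fourfold CV", call. = FALSE)
  folds <- cv_fold_assignment(n, 4, seed)

  beat_values <- vector("list", n)
  for (f in 1:4) {
    test_idx <- which(folds == f)
    train_prep <- structure(prepared[folds != f], class = "prepared_sessions")
    if (is.null(predictor)) {
      dataset <- build_beat_dataset(train_prep, beats_per_session)
      fold_cfg <- config
      fold_cfg$seed <- config$seed + f
      bundle <- train_blc_model(dataset, fold_cfg)
      for (i in test_idx) {
        s <- prepared[[i]]
        beat_values[[i]] <- predict_blc_beats(
          bundle, s$images, make_covariates(s$subject, s$rr))$values
      }
    } else {
      for (i in test_idx) {
        s <- prepared[[i]]
        v <- predictor(train_prep, s)
        beat_values[[i]] <- rep_len(v, dim(s$images)[3])
      }
    }
  }
  true <- vapply(prepared, `[[`, numeric(1), "true_blc")
  est <- vapply(beat_values, aggregate_beat_predictions, numeric(1),
                n_beats = n_beats)
  fold_acc <- vapply(1:4, function(f) {
    idx <- which(folds == f)
    estimation_accuracy(true[idx], est[idx], tolerance)
  }, numeric(1))
  structure(list(
    fold_accuracies = fold_acc, mean = mean(fold_acc),
    variance = var(fold_acc),
    per_session = data.frame(
      session_id = vapply(prepared, `[[`, character(1), "session_id"),
      fold = folds, true_blc = true, est_blc = est,
      stringsAsFactors = FALSE),
    beat_values = beat_values, n_beats = n_beats, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> fold accuracies: %s; mean %.4f, variance %.5f\n",
              paste(sprintf("%.3f", x$fold_accuracies), collapse = ", "),
              x$mean, x$variance))
  invisible(x)
}

#' Accuracy as a function of the beat-window size
#'
#' For each candidate window size n, session predictions are re-aggregated
#' from the cross-validation's cached per-beat estimates (median of the final
#' n beats) and scored; no retraining is needed. The result is the
#' machine-readable analog of an accuracy-versus-beat-count curve.
#'
#' @param prepared a `prepared_sessions` object.
#' @param config a [model_config()]; ignored when `predictor` is given.
#' @param counts integer vector of window sizes (each >= 1).
#' @param seed fold-assignment seed.
#' @param out optional CSV path for the (count, accuracy) table.
#' @param cv_result optionally reuse an existing [fourfold_cv()] result.
#' @inheritParams fourfold_cv
#' @return `data.frame` with columns `count` and `accuracy`.
#' @export
sweep_beat_count <- function(prepared, config = NULL, counts = c(1, 10, 50, 100, 180),
                             seed = 1, beats_per_session = NULL,
                             tolerance = 0.03, predictor = NULL, out = NULL,
                             cv_result = NULL) {
  stopifnot(length(counts) >= 1, all(counts >= 1))
  if (is.null(cv_result)) {
    cv_result <- fourfold_cv(prepared, config, seed = seed,
                             beats_per_session = beats_per_session,
                             tolerance = tolerance, predictor = predictor)
  }
  true <- cv_result$per_session$true_blc
  res <- data.frame(count = as.integer(counts), accuracy = NA_real_)
  for (j in seq_along(counts)) {
    est <- vapply(cv_result$beat_values, aggregate_beat_predictions,
                  numeric(1), n_beats = counts[j])
    res$accuracy[j] <- estimation_accuracy(true, est, tolerance)
  }
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}
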