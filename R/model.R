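#' Model configuration
#'
#' Describes the full estimator: a residual CNN backbone over beat images
#' producing a 300-dimensional waveform feature, fused with the four scalars
#' \[age, sex, BMI, RR\] (placed at the head of the feature vector) through
#' four fully connected layers into two 8-bit sigmoid heads (16 outputs).
#' The reference backbone has 34 weighted layers; shallower presets (6, 10,
#' 18) exist for desk-scale experiments and keep the feature dimension at 300
#' so the weighting analysis is invariant to depth.
#'
#' @param regime `"LM"` (low + moderate intensity) or `"H"` (high); separate
#'   models are trained per regime because the lactate-ECG relationship
#'   differs between them.
#' @param backbone_depth 6, 10, 18 or 34 weighted layers.
#' @param image_size beat-image side length in pixels.
#' @param feature_dim length of the backbone's feature vector (300).
#' @param fusion_hidden width of the fusion network's hidden layers.
#' @param seed integer seed governing initialization and data order.
#' @param epochs,batch_size,learning_rate Adam training hyperparameters.
#' @param v_range voltage window (mV) used when rendering beat images.
#' @return An object of class `model_config`.
#' @export
model_config <- function(regime = c("LM", "H"), backbone_depth = 34,
                         image_size = 128, feature_dim = 300,
                         fusion_hidden = 64, seed = 1, epochs = 30,
                         batch_size = 32, learning_rate = 3e-3,
                         v_range = c(-1.5, 2.0)) {
  regime <- match.arg(regime)
  stopifnot(feature_dim >= 1, image_size >= 32, fusion_hidden >= 1,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  cfg <- list(regime = regime, backbone_depth = backbone_depth,
              image_size = image_size, feature_dim = as.integer(feature_dim),
              fusion_input_dim = as.integer(feature_dim) + 4L,
              fusion_layers = 4L, n_outputs = 16L,
              fusion_hidden = as.integer(fusion_hidden),
              seed = as.integer(seed), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, v_range = v_range)
  arch_spec(cfg)  # validates the depth
  structure(cfg, class = "model_config")
}

regime_intensities <- function(regime) {
  switch(regime, LM = c("L", "M"), H = "H",
         stop("unknown regime ", regime, call. = FALSE))
}

#' Build an untrained estimator
#'
#' Allocates and seeds all parameters of the backbone, feature layer and
#' fusion network described by a [model_config()].
#'
#' @param config a [model_config()].
#' @return An object of class `blc_model` with `params`, `config`, `norm`
#'   (input normalization constants; identity until trained) and
#'   `training_log`.
#' @export
build_blc_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  structure(list(
    params = nn_init_params(config),
    config = config,
    norm = list(center = c(age = 0, sex = 0, bmi = 0, rr = 0),
                scale = c(age = 1, sex = 1, bmi = 1, rr = 1)),
    training_log = NULL
  ), class = "blc_model")
}

#' @export
print.blc_model <- function(x, ...) {
  cat(sprintf(paste0("<blc_model> regime %s, %d-layer backbone, %d-d features",
                     " + 4 scalars -> %d fusion inputs, 2x8-bit heads\n"),
              x$config$regime, x$config$backbone_depth, x$config$feature_dim,
              x$config$fusion_input_dim))
  if (is.null(x$training_log)) {
    cat("  untrained\n")
  } else {
    cat(sprintf("  trained %d epochs, final loss %.5f\n",
                nrow(x$training_log), tail(x$training_log$loss, 1)))
  }
  invisible(x)
}

#' Assemble the raw covariate matrix for the fusion network
#'
#' Builds the 4 x n matrix of fusion scalars in the fixed input order
#' \[age, sex, bmi, rr\]. Sex is coded male = 0, female = 1.
#'
#' @param subject list/row with `age` (years), `sex` (`"female"`/`"male"` or
#'   0/1), `bmi` (kg/m^2).
#' @param rr numeric vector of RR intervals in seconds (one per beat).
#' @return A 4 x `length(rr)` numeric matrix with rownames
#'   `age`, `sex`, `bmi`, `rr`.
#' @export
make_covariates <- function(subject, rr) {
  sex_num <- if (is.numeric(subject$sex)) subject$sex else
    as.numeric(subject$sex == "female")
  rbind(age = rep(as.numeric(subject$age), length(rr)),
        sex = rep(sex_num, length(rr)),
        bmi = rep(as.numeric(subject$bmi), length(rr)),
        rr = as.numeric(rr))
}

apply_norm <- function(cov, norm) (cov - norm$center) / norm$scale

#' Assemble a per-beat training dataset from prepared sessions
#'
#' @param prepared a `prepared_sessions` object from
#'   [prepare_session_inputs()].
#' @param beats_per_session optionally subsample each session to this many
#'   beats (evenly spaced) to bound training cost.
#' @return A list with `images` (H x W x N), `cov` (4 x N raw covariates),
#'   `blc`, `intensity` and `session_id` (each length N).
#' @export
build_beat_dataset <- function(prepared, beats_per_session = NULL) {
  stopifnot(inherits(prepared, "prepared_sessions"))
  pieces <- lapply(prepared, function(s) {
    n <- dim(s$images)[3]
    idx <- if (!is.null(beats_per_session) && n > beats_per_session) {
      unique(round(seq(1, n, length.out = beats_per_session)))
    } else seq_len(n)
    list(images = s$images[, , idx, drop = FALSE],
         cov = make_covariates(s$subject, s$rr[idx]),
         blc = rep(s$true_blc, length(idx)),
         intensity = rep(s$intensity, length(idx)),
         session_id = rep(s$session_id, length(idx)))
  })
  d <- dim(pieces[[1]]$images)
  n_tot <- sum(vapply(pieces, function(p) dim(p$images)[3], integer(1)))
  images <- array(0, dim = c(d[1], d[2], n_tot))
  at <- 0L
  for (p in pieces) {
    k <- dim(p$images)[3]
    images[, , at + seq_len(k)] <- p$images
    at <- at + k
  }
  list(images = images,
       cov = do.call(cbind, lapply(pieces, `[[`, "cov")),
       blc = unlist(lapply(pieces, `[[`, "blc")),
       intensity = unlist(lapply(pieces, `[[`, "intensity")),
       session_id = unlist(lapply(pieces, `[[`, "session_id")))
}

#' Train the lactate estimator
#'
#' Minimizes the mean per-bit binary cross-entropy of the 16 sigmoid outputs
#' against the dual binary code of each beat's session lactate, using Adam.
#' The dataset is first filtered to the configured regime. Age, BMI and RR
#' are standardized by training-set mean/SD (constants frozen into the
#' bundle); sex stays 0/1. Deterministic given `config$seed`.
#'
#' @param dataset a [build_beat_dataset()] result (fields `images`, `cov`,
#'   `blc`, `intensity`).
#' @param config a [model_config()].
#' @param verbose print per-epoch losses.
#' @return A trained `blc_model` bundle with a `training_log` data frame of
#'   per-epoch losses.
#' @export
train_blc_model <- function(dataset, config, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  keep <- dataset$intensity %in% regime_intensities(config$regime)
  if (!any(keep)) stop("no samples in regime ", config$regime, call. = FALSE)
  images <- dataset$images[, , keep, drop = FALSE]
  cov <- dataset$cov[, keep, drop = FALSE]
  blc <- dataset$blc[keep]
  if (any(blc < 0 | blc > 255.9)) stop("labels outside codable range", call. = FALSE)
  n <- length(blc)

  center <- c(age = mean(cov["age", ]), sex = 0, bmi = mean(cov["bmi", ]),
              rr = mean(cov["rr", ]))
  scl <- c(age = sd(cov["age", ]), sex = 1, bmi = sd(cov["bmi", ]),
           rr = sd(cov["rr", ]))
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  norm <- list(center = center, scale = scl)
  cov_n <- apply_norm(cov, norm)

  targets <- vapply(blc, function(b) {
    code <- encode_blc(b)
    c(code$s1, code$s2)
  }, numeric(16))

  params <- nn_init_params(config)
  state <- adam_init(params)
  log_loss <- numeric(config$epochs)
  with_local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      losses <- numeric(length(starts))
      for (k in seq_along(starts)) {
        idx <- ord[starts[k]:min(starts[k] + config$batch_size - 1L, n)]
        xb <- images[, , idx, drop = FALSE]
        dim(xb) <- c(dim(images)[1], dim(images)[2], 1L, length(idx))
        fwd <- nn_forward(params, config, xb, cov_n[, idx, drop = FALSE],
                          keep_cache = TRUE)
        loss <- bce_loss(get("logits", fwd$cache), targets[, idx, drop = FALSE])
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d batch %d", epoch, k),
               call. = FALSE)
        }
        losses[k] <- loss
        grads <- nn_backward(params, config, fwd, targets[, idx, drop = FALSE])
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      log_loss[epoch] <- mean(losses)
      if (verbose) message(sprintf("epoch %3d  loss %.5f", epoch, log_loss[epoch]))
    }
  })
  structure(list(params = params, config = config, norm = norm,
                 training_log = data.frame(epoch = seq_len(config$epochs),
                                           loss = log_loss)),
            class = "blc_model")
}

# Batched per-beat inference. images: H x W x n array (or matrix for n = 1);
# cov_raw: 4 x n raw covariates. Returns decoded values and bit probabilities.
predict_blc_beats <- function(bundle, images, cov_raw) {
  stopifnot(inherits(bundle, "blc_model"))
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1L))
  d <- dim(images)
  if (d[1] != bundle$config$image_size || d[2] != bundle$config$image_size) {
    stop(sprintf("image size %dx%d does not match model config (%d)",
                 d[1], d[2], bundle$config$image_size), call. = FALSE)
  }
  x <- images
  dim(x) <- c(d[1], d[2], 1L, d[3])
  fwd <- nn_forward(bundle$params, bundle$config, x,
                    apply_norm(cov_raw, bundle$norm))
  values <- apply(fwd$probs, 2, soft_decode_blc)
  list(values = values, probs = fwd$probs)
}

#' Predict lactate from a single beat
#'
#' @param bundle a trained `blc_model`.
#' @param image a `beat_image` (or bare pixel matrix) matching the model's
#'   image size.
#' @param subject list/row with `age`, `sex`, `bmi`.
#' @param rr the beat's RR interval in seconds.
#' @return Estimated blood lactate in mmol/L.
#' @export
predict_blc_beat <- function(bundle, image, subject, rr) {
  pixels <- if (inherits(image, "beat_image")) image$pixels else image
  predict_blc_beats(bundle, pixels, make_covariates(subject, rr))$values[1]
}

# Median (or mean) aggregation of per-beat estimates over the analysis
# window, rounded to the codec resolution.
aggregate_beat_predictions <- function(values, n_beats = 180,
                                       anchor = c("end", "start"),
                                       agg = c("median", "mean")) {
  anchor <- match.arg(anchor)
  agg <- match.arg(agg)
  stopifnot(length(values) >= 1, n_beats >= 1)
  if (length(values) > n_beats) {
    values <- if (anchor == "end") tail(values, n_beats) else head(values, n_beats)
  }
  round(match.fun(agg)(values), 1)
}

#' Predict lactate for a whole session
#'
#' Applies the analysis window (by default the final 180 beats, where blood
#' for the reference assay is drawn), predicts each beat independently, and
#' aggregates with the median, which is robust to occasional mis-segmented
#' beats.
#'
#' @param bundle a trained `blc_model`.
#' @param beats either a `beat_list` from [segment_beats()] or a
#'   [beats_to_images()] result (`images` + `rr`).
#' @param subject list/row with `age`, `sex`, `bmi`.
#' @param n_beats number of beats in the analysis window (default 180).
#' @param anchor `"end"` (default) or `"start"` of the session.
#' @param agg `"median"` (default) or `"mean"` per-beat aggregation.
#' @return Estimated blood lactate in mmol/L, rounded to one decimal.
#' @export
predict_blc_session <- function(bundle, beats, subject, n_beats = 180,
                                anchor = "end", agg = "median") {
  if (inherits(beats, "beat_list")) {
    beats <- beats_to_images(beats, bundle$config$image_size,
                             bundle$config$image_size, bundle$config$v_range)
  }
  stopifnot(is.list(beats), !is.null(beats$images), !is.null(beats$rr))
  if (dim(beats$images)[3] < 1) stop("empty beat list", call. = FALSE)
  pred <- predict_blc_beats(bundle, beats$images,
                            make_covariates(subject, beats$rr))
  aggregate_beat_predictions(pred$values, n_beats = n_beats, anchor = anchor,
                             agg = agg)
}

#' Save / load a trained model bundle
#'
#' The bundle is a single versioned file; reloading reproduces predictions
#' bit for bit.
#'
#' @param bundle a `blc_model`.
#' @param path file path.
#' @return `path` (save) or the reloaded `blc_model` (load).
#' @export
save_blc_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "blc_model"))
  saveRDS(list(format = "lactecg-model-v1", bundle = bundle), path)
  invisible(path)
}

#' @rdname save_blc_model
#' @export
load_blc_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "lactecg-model-v1")) {
    stop("not a lactecg model bundle", call. = FALSE)
  }
  obj$bundle
}
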