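#' Default run configuration
#'
#' Central configuration for the command pipeline. Defaults: 200 Hz sampling,
#' 128x128 beat images, a 180-beat analysis window, and the reference
#' 34-layer backbone.
#'
#' @return Object of class `run_config` (a named list).
#' @export
default_run_config <- function() {
  structure(list(
    sampling_rate = 200, image_size = 128, n_beats = 180,
    regime = NULL, backbone_depth = 34, fusion_hidden = 64,
    epochs = 30, batch_size = 32, learning_rate = 3e-3,
    seed = 1, n_subjects = 4, intensities = c("L", "M", "H"),
    session_beats = NULL, noise_sd = 0.01, beats_per_session = NULL,
    counts = c(1, 10, 50, 100, 180), tolerance = 0.03,
    data_dir = NULL, model_file = NULL, out_dir = "lactecg_out"
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults of [default_run_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param overrides optional named list applied on top of the file (e.g.
#'   parsed command-line flags).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    bad <- setdiff(names(vals), names(cfg))
    if (length(bad) > 0) {
      stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[names(vals)] <- vals
  }
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0) {
      stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg, need_regime = FALSE) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (cfg$image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  if (cfg$n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  if (!all(cfg$intensities %in% c("L", "M", "H"))) {
    stop("intensities must be drawn from L, M, H", call. = FALSE)
  }
  if (need_regime && (is.null(cfg$regime) || !cfg$regime %in% c("LM", "H"))) {
    stop("config must set regime to 'LM' or 'H' for this command", call. = FALSE)
  }
  invisible(cfg)
}

run_model_config <- function(cfg) {
  model_config(regime = cfg$regime, backbone_depth = cfg$backbone_depth,
               image_size = cfg$image_size, fusion_hidden = cfg$fusion_hidden,
               seed = cfg$seed, epochs = cfg$epochs,
               batch_size = cfg$batch_size, learning_rate = cfg$learning_rate)
}

# Write the resolved configuration (and the seed actually used) next to the
# artifacts so every run is reproducible from its output directory alone.
write_resolved_config <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plain <- unclass(cfg)
  plain <- plain[!vapply(plain, is.null, logical(1))]
  yaml::write_yaml(plain, file.path(dir, "run_config.yaml"))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to CSV), `preprocess` (beat table
#' from an ECG CSV), `train`, `predict`, `evaluate`, `cv`, `sweep`,
#' `weights`. Every stage derives all randomness from `config$seed` and
#' writes the resolved configuration next to its outputs.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param command stage name.
#' @param ... stage-specific arguments: `ecg_file` (preprocess, predict);
#'   `subject` list with age/sex/bmi (predict).
#' @return The stage's principal artifact, invisibly (paths or data).
#' @export
run_pipeline <- function(config, command = c("simulate", "preprocess", "train",
                                             "predict", "evaluate", "cv",
                                             "sweep", "weights"), ...) {
  command <- match.arg(command)
  validate_run_config(config,
                      need_regime = command %in% c("train", "evaluate", "cv",
                                                   "sweep", "predict", "weights"))
  extra <- list(...)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(command,
    simulate = {
      cohort <- simulate_cohort(config$n_subjects, config$intensities,
                                n_beats = config$session_beats,
                                noise_sd = config$noise_sd, seed = config$seed,
                                fs = config$sampling_rate)
      write_cohort_csv(cohort, out)
    },
    preprocess = {
      rec <- read_ecg_csv(extra$ecg_file, fs = config$sampling_rate)
      beats <- segment_beats(rec)
      beats <- select_beat_window(beats, config$n_beats)
      imgs <- beats_to_images(beats, config$image_size, config$image_size)
      tab <- data.frame(beat_id = seq_along(beats),
                        r_index = vapply(beats, `[[`, integer(1), "r_index"),
                        rr_prev = vapply(beats, `[[`, numeric(1), "rr_prev"))
      write.csv(tab, file.path(out, "beats.csv"), row.names = FALSE)
      saveRDS(imgs, file.path(out, "beat_images.rds"))
      file.path(out, "beats.csv")
    },
    train = {
      cohort <- read_cohort_csv(config$data_dir)
      prepared <- prepare_session_inputs(cohort, config$image_size)
      dataset <- build_beat_dataset(prepared, config$beats_per_session)
      bundle <- train_blc_model(dataset, run_model_config(config))
      path <- config$model_file %||% file.path(out, "model.rds")
      save_blc_model(bundle, path)
      path
    },
    predict = {
      bundle <- load_blc_model(config$model_file)
      rec <- read_ecg_csv(extra$ecg_file, fs = config$sampling_rate)
      beats <- segment_beats(rec)
      est <- predict_blc_session(bundle, beats, extra$subject,
                                 n_beats = config$n_beats)
      cat(sprintf("estimated BLC: %.1f mmol/L\n", est))
      est
    },
    evaluate = {
      bundle <- load_blc_model(config$model_file)
      cohort <- read_cohort_csv(config$data_dir)
      prepared <- prepare_session_inputs(cohort, config$image_size)
      keep <- vapply(prepared, `[[`, character(1), "intensity") %in%
        regime_intensities(config$regime)
      prepared <- structure(prepared[keep], class = "prepared_sessions")
      report <- evaluate_sessions(bundle, prepared, n_beats = config$n_beats,
                                  tolerance = config$tolerance)
      json <- list(regime = report$regime, accuracy = report$accuracy,
                   bias = report$bias, error_sd = report$error_sd,
                   loa_low = report$loa_low, loa_high = report$loa_high,
                   pearson_r = report$pearson_r,
                   per_session = report$per_session)
      jsonlite::write_json(json, file.path(out, "report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      report
    },
    cv = {
      cohort <- read_cohort_csv(config$data_dir)
      prepared <- prepare_session_inputs(cohort, config$image_size)
      cvres <- fourfold_cv(prepared, run_model_config(config),
                           seed = config$seed, n_beats = config$n_beats,
                           beats_per_session = config$beats_per_session,
                           tolerance = config$tolerance)
      jsonlite::write_json(
        list(fold_accuracies = cvres$fold_accuracies, mean = cvres$mean,
             variance = cvres$variance),
        file.path(out, "cv.json"), auto_unbox = TRUE, digits = NA)
      cvres
    },
    sweep = {
      cohort <- read_cohort_csv(config$data_dir)
      prepared <- prepare_session_inputs(cohort, config$image_size)
      sweep_beat_count(prepared, run_model_config(config),
                       counts = config$counts, seed = config$seed,
                       beats_per_session = config$beats_per_session,
                       tolerance = config$tolerance,
                       out = file.path(out, "sweep.csv"))
    },
    weights = {
      bundle <- load_blc_model(config$model_file)
      prof <- fusion_weight_profile(bundle)
      tab <- data.frame(index = seq_along(prof$raw),
                        label = names(prof$raw), raw = unname(prof$raw),
                        proportion = unname(prof$proportions),
                        centered = unname(prof$centered),
                        rescaled = unname(prof$rescaled))
      write.csv(tab, file.path(out, "weights.csv"), row.names = FALSE)
      tab
    })
  write_resolved_config(config, out)
  message(sprintf("[lactecg] %s finished in %.1f s -> %s", command,
                  proc.time()[["elapsed"]] - t0, out))
  invisible(res)
}
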