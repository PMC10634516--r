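#' @useDynLib lactecg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom median approx cor sd var quantile
#' @importFrom utils read.csv write.csv head tail
NULL

# Run expr with a deterministic, locally scoped RNG stream.  The caller's RNG
# state is untouched; seed = NULL uses (and advances) the global stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Rejection sampler for a normal truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate synthetic subject profiles
#'
#' Draws age, sex and BMI from the distributions of the study cohort this
#' package emulates: age ~ Normal(33, 9) truncated to \[18, 80\] and rounded to
#' whole years, BMI ~ Normal(22.8, 2.7) truncated to \[15, 40\], and sex
#' Bernoulli with P(female) = 17/31 (14 men, 17 women).
#'
#' @param n number of subjects.
#' @param seed optional integer seed; the global RNG state is preserved.
#' @return A `data.frame` with columns `subject_id`, `age` (years), `sex`
#'   (`"female"`/`"male"`) and `bmi` (kg/m^2).
#' @export
generate_subjects <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    age <- round(rtruncnorm(n, 33, 9, 18, 80))
    bmi <- rtruncnorm(n, 22.8, 2.7, 15, 40)
    sex <- ifelse(rbinom(n, 1, 17 / 31) == 1, "female", "male")
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = as.integer(age), sex = sex, bmi = bmi,
      stringsAsFactors = FALSE
    )
  })
}

# (mu, sd) of end-exercise BLC per constant-work-rate intensity, mmol/L.
blc_intensity_params <- function() {
  list(L = c(3.7, 2.3), M = c(6.9, 4.2), H = c(10.4, 4.1))
}

#' Sample an end-exercise blood lactate value
#'
#' Draws from Normal(mu, sigma) with (mu, sigma) = (3.7, 2.3), (6.9, 4.2),
#' (10.4, 4.1) mmol/L for low, moderate and high intensity, truncated to
#' \[0.5, 25.5\] (the upper bound is the largest value the session generator
#' accepts) and rounded to one decimal place, the codec's resolution.
#' Truncation is by rejection, so sample means carry the (small) truncation
#' bias of the parent normal.
#'
#' @param intensity `"L"`, `"M"` or `"H"`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param sd override of the intensity's standard deviation (e.g. 0 for a
#'   degenerate draw at the mean).
#' @return Numeric vector of BLC values in mmol/L with one decimal place.
#' @export
sample_blc <- function(intensity, n = 1, seed = NULL, sd = NULL) {
  pars <- blc_intensity_params()[[match.arg(intensity, c("L", "M", "H"))]]
  if (is.null(sd)) sd <- pars[2]
  with_local_seed(seed, round(rtruncnorm(n, pars[1], sd, 0.5, 25.5), 1))
}

# Versioned sum-of-Gaussians beat template coefficients.  Six components
# (P, Q, R, S, ST, T); centers/widths in seconds, amplitudes in mV.  P timing
# scales with the RR interval, QRS timing is fixed, ST/T timing follows a
# rate-compressed QT scale (rr^0.6).  Changing these invalidates golden
# expectations, hence the explicit version tag.
beat_template_config <- function() {
  list(
    version = 1L,
    p_center = -0.20, p_sigma = 0.025, p_amp = 0.12,   # *rr^0.8 / *rr^0.5 / mV
    q_center = -0.022, q_sigma = 0.008, q_amp = -0.15,
    r_sigma = 0.011, r_amp = 1.2,
    s_center = 0.028, s_sigma = 0.009, s_amp = -0.25,
    st_center = 0.16, st_sigma = 0.035,                 # *rr^0.6
    t_center = 0.30, t_sigma = 0.045, t_amp = 0.30,     # *rr^0.6
    # lactate modulation at lambda = 1 (blc >= 15 mmol/L)
    r_drop = 0.10, t_rise = 0.50, st_depression = 0.08, qt_shortening = 0.15
  )
}

#' One synthetic cardiac beat as a function of lactate and RR interval
#'
#' Builds a lead-II-like P-QRS-T beat from a sum of six Gaussians and applies
#' the package's declared lactate-to-morphology mapping. With
#' lambda = min(blc, 15)/15, relative to the rest (blc = 0) template: the R
#' amplitude is scaled by (1 - 0.10 lambda), the T amplitude by
#' (1 + 0.50 lambda), the ST segment is offset by -0.08 lambda mV, and the QT
#' interval is scaled by (1 - 0.15 lambda). These magnitudes are this
#' package's ground-truth convention (exercise ECG literature fixes only the
#' directions); they are chosen so lactate is recoverable from morphology.
#'
#' @param blc blood lactate concentration, mmol/L (>= 0).
#' @param rr RR interval in seconds, in \[0.3, 1.5\].
#' @param fs sampling rate in Hz.
#' @return Numeric vector of `round(rr * fs)` voltages (mV) covering
#'   \[-0.35 rr, +0.65 rr\] around the R peak, with attribute `r_index`
#'   giving the 1-based sample of the R-wave center.
#' @export
beat_template <- function(blc, rr, fs = 200) {
  stopifnot(is.numeric(blc), length(blc) == 1L, blc >= 0)
  if (rr < 0.3 || rr > 1.5) {
    stop("rr must lie in [0.3, 1.5] seconds", call. = FALSE)
  }
  cfg <- beat_template_config()
  lambda <- min(blc, 15) / 15
  qts <- 1 - cfg$qt_shortening * lambda

  len <- as.integer(round(rr * fs))
  r_off <- as.integer(round(0.35 * len))
  t_ax <- (seq_len(len) - 1 - r_off) / fs

  g <- function(center, sigma, amp) amp * exp(-((t_ax - center)^2) / (2 * sigma^2))
  v <- g(cfg$p_center * rr^0.8, cfg$p_sigma * sqrt(rr), cfg$p_amp) +
    g(cfg$q_center, cfg$q_sigma, cfg$q_amp) +
    g(0, cfg$r_sigma, cfg$r_amp * (1 - cfg$r_drop * lambda)) +
    g(cfg$s_center, cfg$s_sigma, cfg$s_amp) +
    g(cfg$st_center * rr^0.6 * qts, cfg$st_sigma * rr^0.6, -cfg$st_depression * lambda) +
    g(cfg$t_center * rr^0.6 * qts, cfg$t_sigma * rr^0.6, cfg$t_amp * (1 + cfg$t_rise * lambda))
  attr(v, "r_index") <- r_off + 1L
  v
}

#' Construct an ECG record
#'
#' @param samples numeric vector of voltages in mV.
#' @param fs sampling rate in Hz (200 by default, the rate the estimator
#'   assumes).
#' @param r_peaks optional strictly increasing 1-based sample indices of known
#'   R peaks (ground truth for synthetic records).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs = 200, r_peaks = NULL) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 1, is.numeric(fs), fs > 0)
  if (!is.null(r_peaks)) {
    r_peaks <- as.integer(r_peaks)
    if (length(r_peaks) > 1 && any(diff(r_peaks) <= 0)) {
      stop("r_peaks must be strictly increasing", call. = FALSE)
    }
    if (any(r_peaks < 1L) || any(r_peaks > length(samples))) {
      stop("r_peaks must index into samples", call. = FALSE)
    }
  }
  structure(list(samples = samples, fs = fs, r_peaks = r_peaks),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s), %s annotated R peaks\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$r_peaks)) "no" else length(x$r_peaks)))
  invisible(x)
}

#' Specify an exercise session
#'
#' @param intensity `"L"`, `"M"` or `"H"` (35/60/90% of maximal work rate).
#' @param true_blc end-exercise blood lactate in mmol/L (<= 25.5); drawn with
#'   [sample_blc()] when omitted.
#' @param duration session length in seconds; defaults per intensity to the
#'   protocol lengths 900 (L), 600 (M), 240 (H). Ignored when `n_beats` is
#'   given.
#' @param n_beats alternatively, the number of beats the session should
#'   contain.
#' @param mean_hr mean heart rate in bpm; defaults 110 (L), 140 (M), 170 (H),
#'   typical of constant-work-rate cycling at these intensities.
#' @param seed optional seed for the lactate draw.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(intensity, true_blc = NULL, duration = NULL,
                         n_beats = NULL, mean_hr = NULL, seed = NULL) {
  intensity <- match.arg(intensity, c("L", "M", "H"))
  if (is.null(mean_hr)) mean_hr <- c(L = 110, M = 140, H = 170)[[intensity]]
  if (!is.null(n_beats)) {
    stopifnot(n_beats >= 1)
    duration <- n_beats * 60 / mean_hr
  }
  if (is.null(duration)) duration <- c(L = 900, M = 600, H = 240)[[intensity]]
  if (is.null(true_blc)) true_blc <- sample_blc(intensity, seed = seed)
  stopifnot(duration > 0, true_blc >= 0, true_blc <= 25.5)
  structure(list(intensity = intensity, true_blc = round(true_blc, 1),
                 duration = duration, mean_hr = mean_hr),
            class = "session_spec")
}

#' Generate a synthetic exercise ECG session
#'
#' Concatenates lactate-modulated beats from [beat_template()] with per-beat
#' RR jitter (lognormal with the given coefficient of variation around
#' 60/`mean_hr`), then adds 0.2 Hz sinusoidal baseline wander and white
#' Gaussian noise. Ground-truth R-peak indices are recorded on the returned
#' record.
#'
#' @param subject one-row data.frame (or list) with `age`, `sex`, `bmi`; only
#'   carried through, the ECG depends on the session's lactate and heart rate.
#' @param spec a [session_spec()].
#' @param noise_sd white-noise standard deviation in mV.
#' @param seed optional integer seed making the record reproducible.
#' @param rr_jitter_cv coefficient of variation of per-beat RR intervals
#'   (0.03 by default; 0 disables jitter).
#' @param wander_amp amplitude of the 0.2 Hz baseline wander in mV.
#' @param fs sampling rate in Hz.
#' @return An [ecg_record()] with ground-truth `r_peaks`.
#' @export
generate_session_ecg <- function(subject, spec, noise_sd = 0.01, seed = NULL,
                                 rr_jitter_cv = 0.03, wander_amp = 0.05,
                                 fs = 200) {
  stopifnot(inherits(spec, "session_spec"), noise_sd >= 0)
  base_rr <- 60 / spec$mean_hr
  n_beats <- floor(spec$duration * spec$mean_hr / 60)
  if (n_beats < 1) {
    stop("session too short to contain one beat", call. = FALSE)
  }
  with_local_seed(seed, {
    rr <- if (rr_jitter_cv > 0) {
      sdlog <- sqrt(log(1 + rr_jitter_cv^2))
      pmin(pmax(base_rr * exp(rnorm(n_beats, -sdlog^2 / 2, sdlog)), 0.3), 1.5)
    } else {
      rep(base_rr, n_beats)
    }
    beats <- lapply(rr, function(r) beat_template(spec$true_blc, r, fs))
    lens <- vapply(beats, length, integer(1))
    offsets <- c(0L, cumsum(lens))[seq_len(n_beats)]
    r_peaks <- offsets + vapply(beats, function(b) attr(b, "r_index"), integer(1))
    x <- unlist(beats, use.names = FALSE)
    t_ax <- (seq_along(x) - 1) / fs
    phase <- runif(1, 0, 2 * pi)
    x <- x + wander_amp * sin(2 * pi * 0.2 * t_ax + phase)
    if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
    ecg_record(x, fs, r_peaks)
  })
}

#' Simulate a cohort of subjects and exercise sessions
#'
#' Generates `n_subjects` profiles and, for each, one session per requested
#' intensity with a lactate value drawn from that intensity's distribution.
#' The whole cohort is a pure function of `seed`.
#'
#' @param n_subjects number of subjects.
#' @param intensities character vector drawn from `c("L", "M", "H")`.
#' @param n_beats beats per session (overrides protocol durations); `NULL`
#'   uses the per-intensity protocol durations.
#' @param noise_sd,rr_jitter_cv,wander_amp,fs forwarded to
#'   [generate_session_ecg()].
#' @param seed integer seed.
#' @return An object of class `blc_cohort`: a list of sessions, each with
#'   elements `subject` (list), `spec` ([session_spec()]) and `record`
#'   ([ecg_record()]).
#' @export
simulate_cohort <- function(n_subjects, intensities = c("L", "M", "H"),
                            n_beats = NULL, noise_sd = 0.01, seed = 1,
                            rr_jitter_cv = 0.03, wander_amp = 0.05, fs = 200) {
  stopifnot(all(intensities %in% c("L", "M", "H")))
  with_local_seed(seed, {
    subjects <- generate_subjects(n_subjects)
    sessions <- list()
    for (i in seq_len(n_subjects)) {
      for (intensity in intensities) {
        spec <- session_spec(intensity, n_beats = n_beats)
        rec <- generate_session_ecg(as.list(subjects[i, ]), spec,
                                    noise_sd = noise_sd,
                                    rr_jitter_cv = rr_jitter_cv,
                                    wander_amp = wander_amp, fs = fs)
        sessions[[length(sessions) + 1L]] <- list(
          subject = as.list(subjects[i, ]), spec = spec, record = rec,
          session_id = sprintf("%s_%s", subjects$subject_id[i], intensity))
      }
    }
    structure(sessions, class = "blc_cohort")
  })
}

#' @export
print.blc_cohort <- function(x, ...) {
  info <- cohort_table(x)
  cat(sprintf("<blc_cohort> %d sessions, %d subjects\n",
              length(x), length(unique(info$subject_id))))
  print(head(info, 6))
  if (nrow(info) > 6) cat("...\n")
  invisible(x)
}

#' Tabulate a cohort's sessions
#'
#' @param cohort a [simulate_cohort()] result.
#' @return A `data.frame` with one row per session: `session_id`,
#'   `subject_id`, `age`, `sex`, `bmi`, `intensity`, `true_blc`, `mean_hr`,
#'   `duration`.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(session_id = s$session_id, subject_id = s$subject$subject_id,
               age = s$subject$age, sex = s$subject$sex, bmi = s$subject$bmi,
               intensity = s$spec$intensity, true_blc = s$spec$true_blc,
               mean_hr = s$spec$mean_hr, duration = s$spec$duration,
               stringsAsFactors = FALSE)
  }))
}

#' Write / read an ECG record as two-column CSV
#'
#' Columns are `t` (seconds) and `mv` (millivolts). Ground-truth R-peak
#' annotations, when present, travel in a companion single-column CSV of
#' 1-based sample indices.
#'
#' @param record an [ecg_record()].
#' @param path output CSV path.
#' @param annotations_path optional path for the R-peak annotation CSV.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, annotations_path = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(t = (seq_along(record$samples) - 1) / record$fs,
                   mv = record$samples)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(annotations_path) && !is.null(record$r_peaks)) {
    write.csv(data.frame(r_peak = record$r_peaks), annotations_path,
              row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ecg_csv
#' @param fs sampling rate; inferred from the time column when `NULL`.
#' @export
read_ecg_csv <- function(path, fs = NULL, annotations_path = NULL) {
  df <- read.csv(path)
  if (!all(c("t", "mv") %in% names(df))) {
    stop("ECG CSV must have columns 't' and 'mv'", call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / median(diff(df$t))
  r_peaks <- NULL
  if (!is.null(annotations_path) && file.exists(annotations_path)) {
    r_peaks <- read.csv(annotations_path)$r_peak
  }
  ecg_record(df$mv, fs = round(fs, 6), r_peaks = r_peaks)
}

#' Write a cohort to a directory of CSV files
#'
#' Produces `sessions.csv` (one row per session with subject metadata,
#' intensity and true lactate) plus per-session ECG and annotation CSVs.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- cohort_table(cohort)
  info$ecg_file <- paste0(info$session_id, "_ecg.csv")
  info$annot_file <- paste0(info$session_id, "_rpeaks.csv")
  write.csv(info, file.path(dir, "sessions.csv"), row.names = FALSE)
  for (i in seq_along(cohort)) {
    write_ecg_csv(cohort[[i]]$record, file.path(dir, info$ecg_file[i]),
                  file.path(dir, info$annot_file[i]))
  }
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  info <- read.csv(file.path(dir, "sessions.csv"), stringsAsFactors = FALSE)
  sessions <- lapply(seq_len(nrow(info)), function(i) {
    rec <- read_ecg_csv(file.path(dir, info$ecg_file[i]),
                        annotations_path = file.path(dir, info$annot_file[i]))
    list(subject = list(subject_id = info$subject_id[i], age = info$age[i],
                        sex = info$sex[i], bmi = info$bmi[i]),
         spec = session_spec(info$intensity[i], true_blc = info$true_blc[i],
                             duration = info$duration[i],
                             mean_hr = info$mean_hr[i]),
         record = rec, session_id = info$session_id[i])
  })
  structure(sessions, class = "blc_cohort")
}
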