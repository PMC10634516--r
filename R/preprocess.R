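#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: 5-15 Hz Butterworth band-pass (zero-phase),
#' differentiation, squaring, 150 ms moving-window integration, adaptive
#' thresholding of integration-signal maxima with a 200 ms refractory
#' constraint, and final refinement of each candidate to the raw-signal
#' maximum in a +/-150 ms neighbourhood. When a record already carries
#' ground-truth annotations the caller may bypass detection entirely by
#' reading `record$r_peaks`.
#'
#' @param record an [ecg_record()] of at least 2 seconds.
#' @param min_rr minimum peak separation (refractory period) in seconds.
#' @param threshold_frac fraction of the adaptive level an integration maximum
#'   must exceed to count as a QRS candidate.
#' @return Strictly increasing integer vector of 1-based R-peak sample
#'   indices.
#' @export
detect_r_peaks <- function(record, min_rr = 0.2, threshold_frac = 0.35) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) < 2 * fs) {
    stop("record too short: need at least 2 seconds of signal", call. = FALSE)
  }
  if (max(x) - min(x) < 1e-9) {
    stop("no beats detected: flat signal", call. = FALSE)
  }

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bp, x)
  d <- c(0, diff(filt))
  integ <- stats::filter(d^2, rep(1 / round(0.15 * fs), round(0.15 * fs)),
                         sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  # local maxima of the integrated energy
  is_max <- c(FALSE, diff(integ) > 0) & c(diff(integ) <= 0, FALSE)
  cand <- which(is_max)
  if (length(cand) == 0) {
    stop("no beats detected: no QRS-band energy maxima", call. = FALSE)
  }
  # adaptive level: a high quantile of candidate amplitudes is a robust proxy
  # for the typical QRS energy even when noise maxima dominate in number
  level <- quantile(integ[cand], 0.95, names = FALSE)
  cand <- cand[integ[cand] > threshold_frac * level]
  if (length(cand) == 0) {
    stop("no beats detected: no peak exceeds the adaptive threshold",
         call. = FALSE)
  }
  # refractory: greedy by energy, keep candidates >= min_rr apart
  keep <- logical(length(cand))
  ord <- order(integ[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - taken) >= min_rr * fs)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- sort(cand[keep])

  # refine each candidate to the raw-signal maximum nearby (the integration
  # window delays/smears the energy peak)
  w <- as.integer(round(0.15 * fs))
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, i - w)
    hi <- min(length(x), i + w)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; enforce the refractory again
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if (p - out[length(out)] >= min_rr * fs) {
        out <- c(out, p)
      } else if (x[p] > x[out[length(out)]]) {
        out[length(out)] <- p
      }
    }
    peaks <- out
  }
  as.integer(peaks)
}

#' Segment an ECG record into one-beat units
#'
#' Beat i, for each interior R peak, spans from 35% of the previous RR
#' interval before the peak to 65% of the next RR interval after it, so
#' consecutive beats tile the signal between the first and last peak exactly
#' (concatenating the segments reconstructs that span sample for sample).
#' The first and last peaks have no complete window and are dropped:
#' `length(beats) == length(r_peaks) - 2`.
#'
#' @param record an [ecg_record()].
#' @param r_peaks R-peak indices; defaults to the record's annotations, else
#'   [detect_r_peaks()].
#' @param pre_frac fraction of the previous RR interval kept before the peak
#'   (0.35 by default; the complement 0.65 of the next interval is kept after
#'   it).
#' @return List of class `beat_list`; each element has `samples` (mV),
#'   `rr_prev` (seconds, interval to the previous R peak) and `r_index`
#'   (the peak's sample index in the parent record).
#' @export
segment_beats <- function(record, r_peaks = NULL, pre_frac = 0.35) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.null(r_peaks)) {
    r_peaks <- if (!is.null(record$r_peaks)) record$r_peaks else detect_r_peaks(record)
  }
  r_peaks <- as.integer(r_peaks)
  n <- length(r_peaks)
  if (n < 3) {
    stop("need at least 3 R peaks to segment complete beats", call. = FALSE)
  }
  post_frac <- 1 - pre_frac
  # boundary between beat i and i+1, placed post_frac of the way into the
  # RR interval; contiguity by construction makes segmentation lossless
  bounds <- r_peaks[-n] + round(post_frac * diff(r_peaks))
  beats <- vector("list", n - 2L)
  for (i in 2:(n - 1)) {
    idx <- bounds[i - 1]:(bounds[i] - 1L)
    beats[[i - 1L]] <- structure(
      list(samples = record$samples[idx],
           rr_prev = (r_peaks[i] - r_peaks[i - 1]) / record$fs,
           r_index = r_peaks[i]),
      class = "beat")
  }
  structure(beats, class = "beat_list", fs = record$fs)
}

#' Render one beat as a fixed-size grayscale image
#'
#' The beat is resampled to `width` time points (x axis = time) and its
#' voltage is affinely mapped from a fixed window (default -1.5 to +2.0 mV,
#' clipping outside) onto image rows, row 1 being the top of the window
#' (y axis = voltage). The trace is drawn as a connected one-pixel polyline:
#' each column covers the vertical interval linking it to its neighbours, and
#' pixel intensities are the fractional coverage of that interval
#' (anti-aliasing), so sub-pixel amplitude information survives
#' rasterization. Every column contains at least one nonzero pixel.
#'
#' @param beat a `beat` from [segment_beats()], or a bare numeric vector of
#'   voltages.
#' @param height,width image size in pixels (>= 32).
#' @param v_range voltage window `c(min, max)` in mV mapped onto the rows.
#' @return An object of class `beat_image`: `pixels` (height x width matrix
#'   in \[0, 1\]), `rr_prev` (seconds, `NA` for bare vectors) and
#'   `source_beat_index`.
#' @export
beat_to_image <- function(beat, height = 128, width = 128,
                          v_range = c(-1.5, 2.0)) {
  if (is.numeric(beat)) beat <- structure(list(samples = beat, rr_prev = NA_real_,
                                               r_index = NA_integer_), class = "beat")
  stopifnot(height >= 32, width >= 32, v_range[2] > v_range[1])
  v <- beat$samples
  if (length(v) == 0) stop("empty beat", call. = FALSE)
  if (length(v) == 1) v <- rep(v, 2)
  y <- approx(seq_along(v), v, xout = seq(1, length(v), length.out = width))$y
  y <- pmin(pmax(y, v_range[1]), v_range[2])
  # continuous row coordinate; row 1 = top of the voltage window
  r <- 1 + (v_range[2] - y) / (v_range[2] - v_range[1]) * (height - 1)

  pixels <- matrix(0, nrow = height, ncol = width)
  # midpoints between neighbouring columns; end columns reuse their own value
  m <- (r[-1] + r[-width]) / 2
  lo_b <- pmin(c(r[1], m), c(m, r[width]), r)
  hi_b <- pmax(c(r[1], m), c(m, r[width]), r)
  for (cix in seq_len(width)) {
    a <- lo_b[cix]; b <- hi_b[cix]
    if (b - a < 1) {              # expand to one pixel, preserving the center
      mid <- (a + b) / 2
      a <- mid - 0.5; b <- mid + 0.5
    }
    rows <- max(1L, floor(a + 0.5)):min(height, ceiling(b - 0.5))
    cov <- pmin(b, rows + 0.5) - pmax(a, rows - 0.5)
    pixels[rows, cix] <- pmin(pmax(cov, 0), 1)
  }
  structure(list(pixels = pixels, rr_prev = beat$rr_prev,
                 source_beat_index = attr(beat, "source_index") %||% NA_integer_),
            class = "beat_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beat_image <- function(x, ...) {
  cat(sprintf("<beat_image> %dx%d, rr_prev = %s s\n", nrow(x$pixels),
              ncol(x$pixels), format(x$rr_prev)))
  invisible(x)
}

#' @export
plot.beat_image <- function(x, ...) {
  graphics::image(t(x$pixels)[, rev(seq_len(nrow(x$pixels)))],
                  col = gray.colors(64, start = 1, end = 0), axes = FALSE, ...)
  invisible(x)
}

#' Select the analysis window of beats
#'
#' Blood for the lactate assay is drawn at the end of exercise, so by default
#' the last `n` beats are analysed. If fewer than `n` beats exist, all are
#' returned with a warning.
#'
#' @param beats a `beat_list` (or plain list).
#' @param n number of beats to keep (default 180, the estimator's standard
#'   window).
#' @param anchor `"end"` (default) for the final `n` beats, `"start"` for the
#'   first `n`.
#' @return The selected beats, same class as the input.
#' @export
select_beat_window <- function(beats, n = 180, anchor = c("end", "start")) {
  anchor <- match.arg(anchor)
  stopifnot(n >= 1)
  if (length(beats) == 0) stop("empty beat sequence", call. = FALSE)
  if (length(beats) < n) {
    warning(sprintf("only %d beats available for a window of %d; using all",
                    length(beats), n), call. = FALSE)
    return(beats)
  }
  idx <- if (anchor == "end") {
    seq.int(length(beats) - n + 1L, length(beats))
  } else {
    seq_len(n)
  }
  out <- beats[idx]
  attributes(out) <- attributes(beats)[setdiff(names(attributes(beats)), "names")]
  if (!is.null(class(beats))) class(out) <- class(beats)
  out
}

#' Convert beats to a stacked image array
#'
#' @param beats a `beat_list`.
#' @inheritParams beat_to_image
#' @return List with `images` (height x width x n array) and `rr` (seconds,
#'   length n).
#' @export
beats_to_images <- function(beats, height = 128, width = 128,
                            v_range = c(-1.5, 2.0)) {
  n <- length(beats)
  stopifnot(n >= 1)
  arr <- array(0, dim = c(height, width, n))
  rr <- numeric(n)
  for (i in seq_len(n)) {
    img <- beat_to_image(beats[[i]], height, width, v_range)
    arr[, , i] <- img$pixels
    rr[i] <- img$rr_prev
  }
  list(images = arr, rr = rr)
}
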