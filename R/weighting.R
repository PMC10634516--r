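#' Extract the 304 fusion-input weights from a trained bundle
#'
#' The first fusion layer consumes the 304-vector \[age, sex, BMI, RR,
#' ECG feature 1..300\]. Each input's aggregate weight is the mean (or max)
#' of the absolute outgoing weights from that input across the layer's
#' units, in that fixed order.
#'
#' @param bundle a `blc_model`.
#' @param agg `"mean"` (default) or `"max"` aggregation across units.
#' @return Named numeric vector of length 304.
#' @export
extract_fusion_weights <- function(bundle, agg = c("mean", "max")) {
  stopifnot(inherits(bundle, "blc_model"))
  agg <- match.arg(agg)
  w <- bundle$params[["fc1.w"]]
  if (ncol(w) != bundle$config$fusion_input_dim) {
    stop(sprintf("fusion layer width %d does not match expected %d",
                 ncol(w), bundle$config$fusion_input_dim), call. = FALSE)
  }
  vals <- apply(abs(w), 2, match.fun(agg))
  names(vals) <- c("age", "sex", "bmi", "rr",
                   paste0("ecg", seq_len(ncol(w) - 4L)))
  vals
}

#' Normalize fusion weights to the \[-1, 1\] interpretability scale
#'
#' From the nonnegative ordinary weights w_1..w_t (absolute values of the
#' raw weights): proportions y_i = w_i / sum(w), centered weights
#' w'_i = y_i - mean(y), and a rescaled form w' / max|w'| lying in
#' \[-1, 1\]. The proportions sum to 1 and the centered weights to 0; the
#' whole profile is invariant to positive rescaling of the input.
#'
#' @param raw numeric vector of at least 2 weights, not all zero.
#' @return Object of class `weight_profile` with fields `raw`, `nonnegative`,
#'   `proportions`, `centered`, `rescaled`.
#' @export
normalize_weights <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 2) stop("need at least 2 weights", call. = FALSE)
  nonneg <- abs(raw)
  tot <- sum(nonneg)
  if (tot == 0) stop("all-zero weight vector cannot be normalized", call. = FALSE)
  y <- nonneg / tot
  centered <- y - mean(y)
  mx <- max(abs(centered))
  rescaled <- if (mx == 0) centered else centered / mx
  structure(list(raw = raw, nonnegative = nonneg, proportions = y,
                 centered = centered, rescaled = rescaled),
            class = "weight_profile")
}

#' @export
print.weight_profile <- function(x, ...) {
  cat(sprintf("<weight_profile> t = %d weights; sum(y) = %g, sum(w') = %g, max|rescaled| = %g\n",
              length(x$raw), sum(x$proportions), sum(x$centered),
              max(abs(x$rescaled))))
  invisible(x)
}

#' Fusion-weight profile of a trained model
#'
#' Convenience wrapper: [extract_fusion_weights()] then
#' [normalize_weights()], keeping the input labels.
#'
#' @inheritParams extract_fusion_weights
#' @return A `weight_profile` whose vectors carry the input names.
#' @export
fusion_weight_profile <- function(bundle, agg = "mean") {
  raw <- extract_fusion_weights(bundle, agg)
  prof <- normalize_weights(raw)
  for (f in c("raw", "nonnegative", "proportions", "centered", "rescaled")) {
    names(prof[[f]]) <- names(raw)
  }
  prof
}

#' Per-variable contribution summary
#'
#' Reduces a 304-weight profile to five labelled values on the centered
#' scale: age, sex, BMI and RR taken directly, and ECG as the mean of the
#' 300 ECG-feature weights. The analog of a per-variable contribution bar
#' chart.
#'
#' @param profile a `weight_profile` of length 304.
#' @return Named numeric vector `c(ecg, age, sex, bmi, rr)`.
#' @export
summarize_contributions <- function(profile) {
  stopifnot(inherits(profile, "weight_profile"))
  if (length(profile$centered) != 304) {
    stop("expected a 304-weight profile (4 scalars + 300 ECG features)",
         call. = FALSE)
  }
  w <- profile$centered
  c(ecg = mean(w[-(1:4)]), age = unname(w[1]), sex = unname(w[2]),
    bmi = unname(w[3]), rr = unname(w[4]))
}

#' Plot per-variable contributions
#'
#' @param contributions result of [summarize_contributions()].
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_weight_contributions <- function(contributions, ...) {
  graphics::barplot(abs(contributions),
                    ylab = "absolute centered weight",
                    main = "Variable weighting in the lactate model", ...)
}

#' Map the 300 ECG-feature weights onto the beat's time axis
#'
#' Places the rescaled ECG weights at 300 evenly spaced positions along the
#' resampled beat width, producing the waveform-weighting curve. Note the
#' backbone's 300 features are not literally time points; this
#' index-to-time mapping is an explicit visualization assumption, recorded
#' in the result's `mapping` attribute.
#'
#' @param profile a 304-length `weight_profile`.
#' @param image_width the beat image width the positions refer to.
#' @return `data.frame` with `position` (pixel coordinate along the beat)
#'   and `weight` (rescaled, in \[-1, 1\]), 300 rows.
#' @export
waveform_weight_curve <- function(profile, image_width = 128) {
  stopifnot(inherits(profile, "weight_profile"))
  if (length(profile$rescaled) != 304) {
    stop("expected a 304-weight profile (4 scalars + 300 ECG features)",
         call. = FALSE)
  }
  curve <- data.frame(position = seq(1, image_width, length.out = 300),
                      weight = unname(profile$rescaled[-(1:4)]))
  attr(curve, "mapping") <-
    "feature index mapped uniformly onto the resampled beat time axis (assumption, not a property of the backbone)"
  curve
}
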