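#' Dual binary coding of blood lactate values
#'
#' The estimator's output head does not regress lactate directly: it treats the
#' value as two 8-bit binary classification targets. `S1` codes the integer
#' part of the blood lactate concentration (BLC, mmol/L) and `S2` codes the
#' first decimal digit. A BLC of 5.2 is coded as S1 = `00000101` (decimal 5)
#' and S2 = `00000010` (decimal 2). Bit strings are written most significant
#' bit first, i.e. the rightmost character carries weight 2^0.
#'
#' @param s1_bits,s2_bits integer vectors of length 8 with elements 0/1, or
#'   8-character strings of `"0"`/`"1"`. Most significant bit first.
#' @return An object of class `blc_code` with integer-vector fields `s1` and
#'   `s2` (each 8 bits, most significant first).
#' @examples
#' blc_code("00000101", "00000010")  # codes 5.2 mmol/L
#' @seealso [encode_blc()], [decode_blc_code()], [soft_decode_blc()]
#' @export
blc_code <- function(s1_bits, s2_bits) {
  s1 <- as_bits(s1_bits)
  s2 <- as_bits(s2_bits)
  structure(list(s1 = s1, s2 = s2), class = "blc_code")
}

#' @export
format.blc_code <- function(x, ...) {
  paste0("S1=", paste(x$s1, collapse = ""), " S2=", paste(x$s2, collapse = ""))
}

#' @export
print.blc_code <- function(x, ...) {
  cat("<blc_code> ", format(x), "  (", format(decode_blc_code(x, quiet = TRUE), nsmall = 1),
      " mmol/L)\n", sep = "")
  invisible(x)
}

# Coerce a bit string or 0/1 vector to a validated integer vector.
as_bits <- function(bits, width = NULL) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L)
    bits <- suppressWarnings(as.integer(strsplit(bits, "")[[1]]))
  }
  bits <- suppressWarnings(as.integer(bits))
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("bits must contain only binary digits 0 and 1", call. = FALSE)
  }
  if (!is.null(width) && length(bits) != width) {
    stop(sprintf("expected %d bits, got %d", width, length(bits)), call. = FALSE)
  }
  bits
}

#' Decode a binary digit string to its integer value
#'
#' Standard positional decoding: the rightmost digit has weight 2^0, so the
#' string `"1011"` decodes to 1*2^3 + 0*2^2 + 1*2^1 + 1*2^0 = 11.
#'
#' @param bits a string of binary digits or an integer 0/1 vector, most
#'   significant bit first.
#' @return A single non-negative integer.
#' @examples
#' bits_to_int("1011")  # 11
#' @export
bits_to_int <- function(bits) {
  bits <- as_bits(bits)
  n <- length(bits)
  sum(bits * 2^((n - 1):0))
}

#' Encode an integer as a fixed-width bit vector
#'
#' @param x non-negative integer representable in `width` bits.
#' @param width number of bits (default 8, the width of each output head).
#' @return Integer vector of 0/1, most significant bit first.
#' @export
int_to_bits <- function(x, width = 8L) {
  x <- as.integer(x)
  stopifnot(length(x) == 1L, !is.na(x))
  if (x < 0L || x > 2^width - 1) {
    stop(sprintf("integer %d not representable in %d bits", x, width), call. = FALSE)
  }
  rev(as.integer(intToBits(x)[seq_len(width)]))
}

#' Encode a blood lactate value into the dual binary code
#'
#' The value is first rounded to one decimal place (the codec's resolution);
#' the integer part goes to S1 and the first decimal digit to S2, each as
#' 8 bits.
#'
#' @param blc blood lactate concentration in mmol/L, in \[0, 255.9\].
#' @return A [blc_code()] object.
#' @examples
#' encode_blc(5.2)  # S1=00000101 S2=00000010
#' @export
encode_blc <- function(blc) {
  stopifnot(is.numeric(blc), length(blc) == 1L, is.finite(blc))
  if (blc < 0 || blc > 255.9) {
    stop("blc must lie in [0, 255.9] mmol/L to be codable", call. = FALSE)
  }
  tenths <- as.integer(round(blc * 10))
  blc_code(int_to_bits(tenths %/% 10L), int_to_bits(tenths %% 10L))
}

#' Decode a dual binary code back to mmol/L
#'
#' A trained network can emit S2 patterns whose value exceeds 9 (there is no
#' architectural constraint forcing a valid decimal digit); such codes are
#' clamped to a decimal digit of 9 with a warning rather than rejected.
#'
#' @param code a [blc_code()] object.
#' @param quiet suppress the clamping warning.
#' @return Blood lactate concentration in mmol/L.
#' @examples
#' decode_blc_code(blc_code("00000101", "00000010"))  # 5.2
#' @export
decode_blc_code <- function(code, quiet = FALSE) {
  stopifnot(inherits(code, "blc_code"))
  s1 <- bits_to_int(code$s1)
  s2 <- bits_to_int(code$s2)
  if (s2 > 9) {
    if (!quiet) {
      warning(sprintf("S2 decodes to %d; clamping decimal digit to 9", s2), call. = FALSE)
    }
    s2 <- 9
  }
  s1 + s2 / 10
}

#' Decode 16 per-bit probabilities to mmol/L
#'
#' The network's heads are 16 independent sigmoid units (8 for S1, 8 for S2).
#' Each probability is thresholded at 0.5 to a hard bit and the hard code is
#' decoded with [decode_blc_code()].
#'
#' @param probs numeric vector of 16 probabilities in \[0, 1\]: the S1 bits
#'   (most significant first) followed by the S2 bits.
#' @param quiet suppress the S2 clamping warning.
#' @return Blood lactate concentration in mmol/L.
#' @export
soft_decode_blc <- function(probs, quiet = TRUE) {
  probs <- as.numeric(probs)
  if (length(probs) != 16L) {
    stop("expected 16 bit probabilities (8 for S1, 8 for S2)", call. = FALSE)
  }
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("bit probabilities must lie in [0, 1]", call. = FALSE)
  }
  bits <- as.integer(probs >= 0.5)
  decode_blc_code(blc_code(bits[1:8], bits[9:16]), quiet = quiet)
}
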