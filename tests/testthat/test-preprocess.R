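test_that("R-peak detection recovers ground truth on clean records", {
  rec <- tiny_record(n_beats = 40, noise_sd = 0, jitter = 0)
  det <- detect_r_peaks(rec)
  # every ground-truth peak matched within 2 samples
  dev <- vapply(rec$r_peaks, function(g) min(abs(det - g)), numeric(1))
  expect_true(all(dev <= 2))
  expect_true(all(diff(det) > 0))
  expect_true(all(diff(det) >= 0.2 * rec$fs))
})

test_that("degenerate records raise explicit errors", {
  expect_error(detect_r_peaks(ecg_record(rep(0, 1000), fs = 200)), "flat")
  expect_error(detect_r_peaks(ecg_record(rnorm(100), fs = 200)), "short")
})

test_that("detection stays above 99% under measurement noise", {
  rec <- tiny_record(n_beats = 120, noise_sd = 0.02, jitter = 0.03, seed = 8)
  det <- detect_r_peaks(rec)
  dev <- vapply(rec$r_peaks, function(g) min(abs(det - g)), numeric(1))
  expect_gte(mean(dev <= 0.010 * rec$fs), 0.99)
})

test_that("segmentation drops edge peaks and tiles the record exactly", {
  rec <- tiny_record(n_beats = 5, noise_sd = 0, jitter = 0)
  beats <- segment_beats(rec, rec$r_peaks)
  expect_length(beats, 3)

  # window arithmetic: constant RR 0.5 s at 200 Hz gives 100-sample beats
  peaks <- c(100L, 200L, 300L)
  rec2 <- ecg_record(rnorm(400), fs = 200, r_peaks = peaks)
  b2 <- segment_beats(rec2, peaks)
  expect_length(b2, 1)
  expect_length(b2[[1]]$samples, 100)
  expect_identical(b2[[1]]$rr_prev, 0.5)

  expect_error(segment_beats(rec2, peaks[1:2]), "3 R peaks")

  # lossless round trip between the outermost beat boundaries
  rec3 <- tiny_record(n_beats = 30, noise_sd = 0, jitter = 0)
  beats3 <- segment_beats(rec3, rec3$r_peaks)
  joined <- unlist(lapply(beats3, `[[`, "samples"))
  first <- rec3$r_peaks[1] + round(0.65 * (rec3$r_peaks[2] - rec3$r_peaks[1]))
  expect_identical(joined, rec3$samples[first:(first + length(joined) - 1)])

  # all beats of a noiseless periodic record are identical
  lens <- vapply(beats3, function(b) length(b$samples), integer(1))
  expect_true(all(lens == lens[1]))
  m <- do.call(rbind, lapply(beats3, `[[`, "samples"))
  expect_true(all(apply(m, 2, function(col) max(col) - min(col)) < 1e-12))
})

test_that("RR bookkeeping is consistent with peak positions", {
  rec <- tiny_record(n_beats = 50, noise_sd = 0.01, jitter = 0.03, seed = 3)
  beats <- segment_beats(rec, rec$r_peaks)
  rr <- vapply(beats, `[[`, numeric(1), "rr_prev")
  n <- length(rec$r_peaks)
  # beats cover peaks 2..n-1; their rr_prev are intervals 1..n-2
  expected <- (rec$r_peaks[n - 1] - rec$r_peaks[1]) / (rec$fs * (n - 2))
  expect_equal(mean(rr), expected, tolerance = 1e-12)
})

test_that("beat images are deterministic, connected and mirror-symmetric", {
  rec <- tiny_record(n_beats = 10, noise_sd = 0, jitter = 0)
  beat <- segment_beats(rec, rec$r_peaks)[[2]]

  img1 <- beat_to_image(beat, 64, 64)
  img2 <- beat_to_image(beat, 64, 64)
  expect_identical(img1$pixels, img2$pixels)
  expect_identical(dim(img1$pixels), c(64L, 64L))
  expect_true(all(img1$pixels >= 0 & img1$pixels <= 1))
  # the trace is connected in time: every column is inked
  expect_true(all(colSums(img1$pixels) > 0))
  expect_identical(img1$rr_prev, beat$rr_prev)

  # time reversal mirrors the image about the vertical axis
  rev_beat <- structure(list(samples = rev(beat$samples), rr_prev = beat$rr_prev,
                             r_index = beat$r_index), class = "beat")
  img_rev <- beat_to_image(rev_beat, 64, 64)
  expect_equal(img_rev$pixels, img1$pixels[, 64:1], tolerance = 1e-12)
})

test_that("a constant beat renders as one horizontal line at its voltage row", {
  img <- beat_to_image(rep(0, 80), 128, 64)
  # nonzero ink confined to the rows bracketing the 0 mV level,
  # identical across columns, unit mass per column
  target_row <- 1 + (2.0 - 0) / 3.5 * 127
  inked <- which(rowSums(img$pixels) > 0)
  expect_true(all(inked %in% c(floor(target_row), ceiling(target_row))))
  expect_equal(colSums(img$pixels), rep(1, 64), tolerance = 1e-12)
  expect_error(beat_to_image(numeric(0), 64, 64), "empty")

  # clipping: voltages outside the window land on the edge rows
  img_hi <- beat_to_image(rep(5, 80), 64, 64)
  expect_true(all(which(rowSums(img_hi$pixels) > 0) == 1))
})

test_that("beat window selection anchors at end of exercise", {
  beats <- as.list(seq_len(500))
  expect_identical(unlist(select_beat_window(beats, 180)), 321:500)
  expect_identical(unlist(select_beat_window(beats, 180, anchor = "start")), 1:180)
  expect_identical(unlist(select_beat_window(beats, 1)), 500L)
  expect_warning(short <- select_beat_window(as.list(1:100), 180), "only 100")
  expect_length(short, 100)
  expect_error(select_beat_window(list(), 10), "empty")
})
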