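# Preprocessing chain: window arithmetic, filters, blink suppression,
# normalization, and whole-pipeline properties.

test_that("middle-window extraction uses centered half-open sample windows", {
  rec <- generate_recording(1, 300, seed = 31)
  win <- select_middle_window(rec, 15)
  expect_identical(win$duration_s, 15)
  expect_length(win$channels$O1, 3750)
  # (300 - 15)/2 * 250 = 35625 zero-based -> R indices 35626..39375
  expect_identical(win$channels$O1, rec$channels$O1[35626:39375])
  expect_length(win$channels$ECG, 15 * 120)
  expect_identical(win$channels$ECG, rec$channels$ECG[17101:18900])
  # whole-recording window is the identity
  rec15 <- generate_recording(1, 15, seed = 32)
  expect_identical(select_middle_window(rec15, 15)$channels, rec15$channels)
  rec10 <- generate_recording(1, 10, seed = 33)
  expect_error(select_middle_window(rec10, 15), "shorter")
})

test_that("50 Hz notch attenuates the mains tone and preserves the passband", {
  fs <- 250
  t <- seq_len(15 * fs) / fs
  x50 <- sin(2 * pi * 50 * t)
  y50 <- notch_filter(x50, fs)
  att_db <- 10 * log10(band_power(x50, fs, c(49, 51)) /
                         band_power(y50, fs, c(49, 51)))
  expect_gt(att_db, 20)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- notch_filter(x10, fs)
  ripple_db <- abs(10 * log10(band_power(y10, fs, c(9, 11)) /
                                band_power(x10, fs, c(9, 11))))
  expect_lt(ripple_db, 1)
  expect_equal(notch_filter(numeric(500), fs), numeric(500))
  expect_error(notch_filter(x10, fs = 90), "fs")
})

test_that("first-order Butterworth band-pass matches its analytic response", {
  fs <- 250
  t <- seq_len(15 * fs) / fs
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_butterworth(x10, fs)
  gain_db <- 20 * log10(stats::sd(y10) / stats::sd(x10))
  expect_lt(abs(gain_db), 3)
  y100 <- bandpass_butterworth(sin(2 * pi * 100 * t), fs)
  expect_lt(stats::sd(y100), 0.5 * stats::sd(y10))
  expect_equal(bandpass_butterworth(numeric(500), fs), numeric(500))
  expect_error(bandpass_butterworth(x10, fs, low = 0, high = 60), "band edges")
  expect_error(bandpass_butterworth(x10, fs, low = 1, high = 200), "band edges")
})

test_that("filter stages are linear before normalization", {
  fs <- 250
  withr::with_seed(61, x <- stats::rnorm(3750))
  for (f in list(function(s) notch_filter(s, fs),
                 function(s) bandpass_butterworth(s, fs))) {
    expect_equal(f(3.7 * x), 3.7 * f(x), tolerance = 1e-9)
  }
})

test_that("blink suppression removes transients and spares clean signal", {
  tmpl_len <- length(fatiguenet:::blink_template(250))
  for (sd_ in c(12, 34)) {
    rec <- generate_recording(0, 15, seed = sd_)
    cleaned <- remove_blinks(rec)
    for (o in rec$blink_onsets) {
      idx <- o:(o + tmpl_len - 1L)
      before <- max(abs(rec$channels$Fp1[idx] - rec$clean$Fp1[idx]))
      after <- max(abs(cleaned$channels$Fp1[idx] - rec$clean$Fp1[idx]))
      expect_lt(after, 0.2 * before)   # >= 80% peak reduction
    }
  }
  # blink-free epoch: output equals input within 5% RMS
  cfg <- synth_config(blink_rate_per_min = rep(0, 5))
  rec0 <- generate_recording(0, 15, cfg, seed = 35)
  cl0 <- remove_blinks(rec0)
  rel_rms <- sqrt(mean((cl0$channels$Fp1 - rec0$channels$Fp1)^2)) /
    sqrt(mean(rec0$channels$Fp1^2))
  expect_lt(rel_rms, 0.05)
  # all-zero channels pass through unchanged
  recz <- rec0
  recz$channels$Fp1 <- numeric(3750)
  expect_identical(remove_blinks(recz)$channels$Fp1, numeric(3750))
  # configuration error when no frontal channel exists
  rec_nf <- rec0
  rec_nf$channels$Fp1 <- rec_nf$channels$Fp2 <- NULL
  expect_error(remove_blinks(rec_nf), "frontal")
})

test_that("min-max normalization has exact bounds, convention, idempotence", {
  expect_identical(minmax01(c(-1, 0, 1)), c(0, 0.5, 1))
  withr::with_seed(41, x <- stats::rnorm(100))
  y <- minmax01(x)
  expect_identical(range(y), c(0, 1))
  expect_identical(minmax01(y), y)
  expect_identical(minmax01(rep(3.2, 5)), numeric(5))
  expect_error(minmax01(numeric(0)), "non-empty")
})

test_that("the full pipeline is deterministic, bounded, and ordered", {
  rec <- generate_recording(2, 15, seed = 71)
  ep1 <- preprocess_pipeline(rec)
  ep2 <- preprocess_pipeline(rec)
  expect_identical(ep1, ep2)
  expect_identical(dim(ep1$data), c(4L, 3750L))
  expect_true(all(ep1$data >= 0 & ep1$data <= 1))
  expect_identical(ep1$provenance,
                   c("select_middle_window", "notch", "bandpass",
                     "remove_blinks", "minmax01"))
  expect_identical(ep1$label, 2L)
  short <- generate_recording(2, 10, seed = 72)
  expect_error(preprocess_pipeline(short), "shorter")
})

test_that("preprocess_dataset stacks epochs with labels and provenance", {
  ds <- tiny_epochs()
  expect_s3_class(ds, "epoch_dataset")
  expect_identical(dim(ds$x), c(18L, 4L, 3750L))
  expect_identical(sort(unique(ds$labels)), c(0L, 2L, 4L))
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  expect_false(any(ds$synthetic))
})
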