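# Synthetic-recording generator: determinism, channel geometry, and the
# level-dependent physiological signatures.

test_that("recordings have the declared channel geometry and are seed-deterministic", {
  rec <- generate_recording(level = 2, duration_s = 15, seed = 101)
  expect_s3_class(rec, "fatigue_recording")
  for (nm in c("Fp1", "Fp2", "O1", "O2", "C3", "P4"))
    expect_length(rec$channels[[nm]], 15 * 250)
  for (nm in c("ECG", "EMG", "RESP"))
    expect_length(rec$channels[[nm]], 15 * 120)
  expect_identical(rec$fatigue_level, 2L)
  rec2 <- generate_recording(level = 2, duration_s = 15, seed = 101)
  expect_identical(rec$channels, rec2$channels)
  rec3 <- generate_recording(level = 2, duration_s = 15, seed = 102)
  expect_false(identical(rec$channels, rec3$channels))
})

test_that("invalid level or duration is rejected", {
  expect_error(generate_recording(5, 15), "level")
  expect_error(generate_recording(-1, 15), "level")
  expect_error(generate_recording(2.5, 15), "level")
  expect_error(generate_recording(0, 0), "duration_s")
  expect_error(generate_dataset(3, levels = integer(0)), "non-empty")
  expect_error(generate_dataset(0, levels = 0:4), "n_per_class")
})

test_that("theta/alpha ratio rises with fatigue level at both occipital channels", {
  # averaged over 20 seeded epochs per level
  ratios <- sapply(0:4, function(lv) {
    mean(sapply(1:20, function(i) {
      rec <- generate_recording(lv, 15, seed = 1000 + 20 * lv + i)
      mean(sapply(c("O1", "O2"), function(ch)
        band_power(rec$channels[[ch]], 250, c(4, 8)) /
          band_power(rec$channels[[ch]], 250, c(8, 13))))
    }))
  })
  expect_true(all(diff(ratios) > 0))
  # same seed, extreme levels: strictly greater ratio at full fatigue
  r0 <- generate_recording(0, 15, seed = 7)
  r4 <- generate_recording(4, 15, seed = 7)
  ta <- function(r) band_power(r$channels$O1, 250, c(4, 8)) /
    band_power(r$channels$O1, 250, c(8, 13))
  expect_gt(ta(r4), ta(r0))
})

test_that("blink events become rarer with fatigue level", {
  # independent oracle: count groups of threshold crossings on Fp1
  count_blinks <- function(x) {
    z <- abs(x - stats::median(x)) / stats::mad(x)
    hot <- which(z > 6)
    if (!length(hot)) return(0L)
    sum(diff(c(-1000L, hot)) > 100L)
  }
  counts <- sapply(c(0, 2, 4), function(lv) {
    mean(sapply(1:20, function(i)
      count_blinks(generate_recording(lv, 15,
                                      seed = 3000 + 20 * lv + i)$channels$Fp1)))
  })
  expect_true(all(diff(counts) < 0))
  # and the oracle agrees with the generator's own event count on average
  n_true <- mean(sapply(1:10, function(i)
    length(generate_recording(0, 15, seed = 4000 + i)$blink_onsets)))
  n_det <- mean(sapply(1:10, function(i)
    count_blinks(generate_recording(0, 15, seed = 4000 + i)$channels$Fp1)))
  expect_lt(abs(n_true - n_det), 1)
})

test_that("heart rate, EMG bursts and respiration clipping follow their schedules", {
  r0 <- generate_recording(0, 30, seed = 9)
  r4 <- generate_recording(4, 30, seed = 9)
  count_peaks <- function(x, thr = 0.6) sum(diff(c(0, x > thr)) == 1)
  expect_gt(count_peaks(r0$channels$ECG), count_peaks(r4$channels$ECG))
  # respiration clipping: full-fatigue amplitude is truncated
  expect_lt(max(abs(r4$channels$RESP)), max(abs(r0$channels$RESP)))
  expect_lte(max(abs(r4$channels$RESP)), 1 - 0.6 + 1e-12)
  # EMG burst energy drops with level
  expect_gt(mean(r0$channels$EMG^2), mean(r4$channels$EMG^2))
})

test_that("generate_dataset yields balanced, independently seeded epochs", {
  rset <- generate_dataset(10, levels = 0:4, epoch_len_s = 15, seed = 21)
  expect_length(rset$recordings, 50)
  expect_equal(as.vector(table(rset$labels)), rep(10, 5))
  expect_length(rset$recordings[[1]]$channels$O1, 3750)
  rset2 <- generate_dataset(10, levels = 0:4, epoch_len_s = 15, seed = 22)
  expect_false(identical(rset$recordings[[1]]$channels$O1,
                         rset2$recordings[[1]]$channels$O1))
})

test_that("band_power matches sinusoid closed forms and rejects bad bands", {
  fs <- 250
  t <- seq_len(15 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  expect_equal(band_power(x, fs, c(8, 13)), 0.5, tolerance = 0.05)
  expect_lt(band_power(x, fs, c(20, 30)), 0.01 * 0.5)
  # off-bin frequency still lands in the band within the window tolerance
  x2 <- sin(2 * pi * 10.37 * t)
  expect_equal(band_power(x2, fs, c(8, 13)), 0.5, tolerance = 0.05)
  expect_identical(band_power(numeric(100), fs, c(8, 13)), 0)
  expect_error(band_power(x, fs, c(100, 130)), "band")
  expect_error(band_power(x, fs, c(13, 8)), "band")
})

test_that("schedule monotonicity is enforced at construction", {
  expect_error(synth_config(alpha_amp = c(1, 1.1, 0.6, 0.4, 0.2)), "non-increasing")
  expect_error(synth_config(theta_amp = c(1, 0.8, 0.6, 0.4, 0.2)), "non-decreasing")
  expect_error(synth_config(blink_rate_per_min = rep(1, 4)), "length 5")
  expect_error(synth_config(resp_clip_frac = c(0, 0.1, 0.2, 0.3, 1)), "\\[0, 1\\)")
})
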