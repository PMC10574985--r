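# Synthetic multichannel physiological recordings with a controlled,
# level-dependent class structure:
#   - occipital/parietal EEG: alpha (8-13 Hz) power falls and theta (4-8 Hz)
#     power rises with fatigue level,
#   - frontal EEG: blink transients whose rate falls with level,
#   - ECG: periodic QRS-like template whose rate falls with level,
#   - EMG: random movement bursts whose rate falls with level,
#   - respiration: slow sinusoid that clips progressively with level.
# All randomness is seeded; identical (config, seed) reproduces bit-identical
# arrays.

EEG_CHANNELS  <- c("Fp1", "Fp2", "O1", "O2", "C3", "P4")
AUX_CHANNELS  <- c("ECG", "EMG", "RESP")
EEG_FS <- 250
AUX_FS <- 120

#' Configuration of the synthetic-recording generator
#'
#' Per-level schedules (length 5, fatigue levels 0-4) control the emulated
#' physiological fatigue signatures. Alpha amplitude must be non-increasing
#' and theta amplitude non-decreasing with level; blink, heart and EMG-burst
#' rates non-increasing; respiration clipping non-decreasing.
#'
#' @param alpha_band,theta_band frequency bands in Hz.
#' @param alpha_amp,theta_amp per-level amplitudes (arbitrary units, the
#'   broadband noise floor has SD `noise_sd`).
#' @param blink_rate_per_min per-level frontal blink rates.
#' @param heart_rate_bpm per-level heart rates.
#' @param emg_burst_rate_per_min per-level EMG burst rates.
#' @param resp_clip_frac per-level respiration clipping fraction in `[0, 1)`.
#' @param resp_rate_per_min respiration rate (level-independent).
#' @param noise_sd SD of the broadband EEG noise floor.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(alpha_band = c(8, 13),
                         theta_band = c(4, 8),
                         alpha_amp = c(1.00, 0.80, 0.60, 0.42, 0.25),
                         theta_amp = c(0.25, 0.42, 0.60, 0.80, 1.00),
                         blink_rate_per_min = c(18, 14, 10, 6, 2),
                         heart_rate_bpm = c(75, 70, 64, 57, 50),
                         emg_burst_rate_per_min = c(24, 18, 12, 7, 3),
                         resp_clip_frac = c(0, 0.10, 0.25, 0.40, 0.60),
                         resp_rate_per_min = 14,
                         noise_sd = 0.35) {
  sched <- list(alpha_amp = alpha_amp, theta_amp = theta_amp,
                blink_rate_per_min = blink_rate_per_min,
                heart_rate_bpm = heart_rate_bpm,
                emg_burst_rate_per_min = emg_burst_rate_per_min,
                resp_clip_frac = resp_clip_frac)
  for (nm in names(sched))
    if (length(sched[[nm]]) != 5L)
      stop_arg("schedule `%s` must have length 5 (one value per level)", nm)
  if (any(diff(alpha_amp) > 0)) stop_arg("`alpha_amp` must be non-increasing")
  if (any(diff(theta_amp) < 0)) stop_arg("`theta_amp` must be non-decreasing")
  if (any(diff(blink_rate_per_min) > 0)) stop_arg("`blink_rate_per_min` must be non-increasing")
  if (any(diff(heart_rate_bpm) > 0)) stop_arg("`heart_rate_bpm` must be non-increasing")
  if (any(diff(emg_burst_rate_per_min) > 0)) stop_arg("`emg_burst_rate_per_min` must be non-increasing")
  if (any(diff(resp_clip_frac) < 0)) stop_arg("`resp_clip_frac` must be non-decreasing")
  if (any(resp_clip_frac < 0 | resp_clip_frac >= 1)) stop_arg("`resp_clip_frac` must lie in [0, 1)")
  structure(c(list(alpha_band = alpha_band, theta_band = theta_band),
              sched,
              list(resp_rate_per_min = resp_rate_per_min, noise_sd = noise_sd)),
            class = "synth_config")
}

# Band-limited stochastic oscillator: white noise shaped in the frequency
# domain to the given band, normalized to unit SD.
band_oscillator <- function(n, fs, band) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)          # mirror for negative frequencies
  keep <- freqs >= band[1] & freqs <= band[2]
  Z[!keep] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Smooth biphasic blink transient (positive lobe then smaller negative lobe),
# also used as the matched template by the blink-suppression stage.
blink_template <- function(fs, dur_s = 0.35) {
  n <- round(fs * dur_s)
  t <- seq(0, 1, length.out = n)
  w <- sin(pi * t)^2                         # smooth envelope, zero at ends
  w * (1.3 * exp(-((t - 0.35) / 0.18)^2) - 0.5 * exp(-((t - 0.75) / 0.2)^2))
}

# One QRS-like beat shape sampled at fs
qrs_template <- function(fs) {
  t <- seq(-0.1, 0.1, by = 1 / fs)
  1.2 * exp(-(t / 0.012)^2) - 0.3 * exp(-((t - 0.035) / 0.02)^2) -
    0.2 * exp(-((t + 0.035) / 0.02)^2)
}

place_events <- function(n, fs, rate_per_min, template, amplitude = 1,
                         jitter = TRUE, min_gap = 0L) {
  x <- numeric(n)
  dur_s <- n / fs
  k <- stats::rpois(1, rate_per_min * dur_s / 60)
  if (k == 0) return(list(signal = x, onsets = integer(0)))
  onsets <- sort(sample.int(max(1L, n - length(template)), k, replace = TRUE))
  if (min_gap > 0L && length(onsets) > 1L) {
    keep <- onsets[1L]
    for (o in onsets[-1L]) if (o - keep[length(keep)] >= min_gap) keep <- c(keep, o)
    onsets <- keep
  }
  for (o in onsets) {
    idx <- o:(o + length(template) - 1L)
    amp <- if (jitter) amplitude * stats::runif(1, 0.8, 1.2) else amplitude
    x[idx] <- x[idx] + amp * template
  }
  list(signal = x, onsets = onsets)
}

#' Generate one synthetic multichannel recording
#'
#' @param level fatigue level, integer 0 (alert) to 4 (complete fatigue).
#' @param duration_s recording duration in seconds (positive; integer values
#'   are required for EDF export).
#' @param config a [synth_config()].
#' @param seed integer seed; identical `(level, duration_s, config, seed)`
#'   reproduce bit-identical sample arrays.
#' @param subject_id identifier stored on the recording.
#' @return an object of class `fatigue_recording`: a list with `channels`
#'   (named list of sample vectors), `fs` (per-modality sampling rates),
#'   `duration_s`, `fatigue_level`, `subject_id`, `seed`, and `clean` (the
#'   frontal channels before blink transients were added, kept for
#'   validating blink suppression).
#' @examples
#' rec <- generate_recording(level = 4, duration_s = 15, seed = 1)
#' length(rec$channels$O1)  # 15 s x 250 Hz
#' @export
generate_recording <- function(level, duration_s, config = synth_config(),
                               seed = 1, subject_id = "synthetic") {
  level <- check_level(level)
  check_scalar_num(duration_s, "duration_s", positive = TRUE)
  if (!inherits(config, "synth_config")) stop_arg("`config` must be a synth_config")
  li <- level + 1L
  n_eeg <- round(duration_s * EEG_FS)
  n_aux <- round(duration_s * AUX_FS)
  with_seed(seed, {
    ch <- list()
    clean <- list()
    aA <- config$alpha_amp[li]
    aT <- config$theta_amp[li]
    # occipital carry the full alpha/theta schedule; parietal nearly full,
    # central attenuated toward the schedule midpoint
    contrast <- c(O1 = 1, O2 = 1, P4 = 0.8, C3 = 0.5)
    mid <- (config$alpha_amp[3] + config$theta_amp[3]) / 2
    for (nm in names(contrast)) {
      g <- contrast[[nm]]
      ch[[nm]] <- (g * aA + (1 - g) * mid) * band_oscillator(n_eeg, EEG_FS, config$alpha_band) +
        (g * aT + (1 - g) * mid) * band_oscillator(n_eeg, EEG_FS, config$theta_band) +
        config$noise_sd * stats::rnorm(n_eeg)
    }
    # frontal: weak rhythm + noise + blink transients (same onsets both sides)
    tmpl <- blink_template(EEG_FS)
    base_f1 <- 0.3 * band_oscillator(n_eeg, EEG_FS, config$alpha_band) +
      config$noise_sd * stats::rnorm(n_eeg)
    base_f2 <- 0.3 * band_oscillator(n_eeg, EEG_FS, config$alpha_band) +
      config$noise_sd * stats::rnorm(n_eeg)
    # blinks are discrete events with a physiological refractory gap
    ev <- place_events(n_eeg, EEG_FS, config$blink_rate_per_min[li], tmpl,
                       amplitude = 4, min_gap = 2L * length(tmpl))
    clean$Fp1 <- base_f1
    clean$Fp2 <- base_f2
    ch$Fp1 <- base_f1 + ev$signal
    ch$Fp2 <- base_f2 + 0.9 * ev$signal
    # ECG: strictly periodic beats at the scheduled heart rate
    beat <- qrs_template(AUX_FS)
    period <- round(60 / config$heart_rate_bpm[li] * AUX_FS)
    ecg <- 0.05 * stats::rnorm(n_aux)
    onsets <- seq(1L, max(1L, n_aux - length(beat)), by = period)
    for (o in onsets) {
      idx <- o:(o + length(beat) - 1L)
      ecg[idx] <- ecg[idx] + beat
    }
    ch$ECG <- ecg
    # EMG: noise floor + high-variance movement bursts
    burst <- rep(1, round(0.25 * AUX_FS))
    bev <- place_events(n_aux, AUX_FS, config$emg_burst_rate_per_min[li],
                        burst, amplitude = 1)
    ch$EMG <- 0.05 * stats::rnorm(n_aux) + bev$signal * stats::rnorm(n_aux)
    # respiration: sinusoid with level-dependent amplitude clipping
    tt <- seq_len(n_aux) / AUX_FS
    resp <- sin(2 * pi * config$resp_rate_per_min / 60 * tt +
                  stats::runif(1, 0, 2 * pi))
    lim <- 1 - config$resp_clip_frac[li]
    ch$RESP <- pmin(pmax(resp, -lim), lim)
    ch <- ch[c(EEG_CHANNELS, AUX_CHANNELS)]
    structure(list(channels = ch,
                   fs = c(EEG = EEG_FS, ECG = AUX_FS, EMG = AUX_FS, RESP = AUX_FS),
                   duration_s = duration_s,
                   fatigue_level = level,
                   subject_id = subject_id,
                   seed = as.integer(seed),
                   clean = clean,
                   blink_onsets = ev$onsets),
              class = "fatigue_recording")
  })
}

#' @export
print.fatigue_recording <- function(x, ...) {
  cat(sprintf("<fatigue_recording> subject=%s level=%d duration=%gs\n",
              x$subject_id, x$fatigue_level, x$duration_s))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

channel_fs <- function(rec, name) {
  if (name %in% EEG_CHANNELS) rec$fs[["EEG"]] else rec$fs[[name]]
}

#' Generate a labeled collection of synthetic recordings
#'
#' Produces `n_per_class` recordings of `epoch_len_s` seconds for each
#' requested fatigue level, class-balanced, each independently seeded from
#' `seed`.
#'
#' @param n_per_class recordings per fatigue level (>= 1).
#' @param levels subset of `0:4`.
#' @param epoch_len_s duration of each recording in seconds (default 15, the
#'   analysis window length).
#' @param config a [synth_config()].
#' @param seed integer master seed.
#' @return class `recording_set`: list with `recordings` and integer `labels`.
#' @export
generate_dataset <- function(n_per_class, levels = 0:4, epoch_len_s = 15,
                             config = synth_config(), seed = 1) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop_arg("`n_per_class` must be >= 1")
  if (length(levels) == 0L) stop_arg("`levels` must be a non-empty subset of 0:4")
  levels <- vapply(levels, check_level, integer(1))
  recs <- list(); labels <- integer(0)
  for (lv in levels) {
    for (i in seq_len(n_per_class)) {
      s <- derive_seed(seed, sprintf("rec-%d-%d", lv, i))
      recs[[length(recs) + 1L]] <-
        generate_recording(lv, epoch_len_s, config, seed = s,
                           subject_id = sprintf("S%02d_%03d", lv, i))
      labels <- c(labels, lv)
    }
  }
  structure(list(recordings = recs, labels = labels,
                 epoch_len_s = epoch_len_s, seed = as.integer(seed)),
            class = "recording_set")
}

#' Band power of a signal
#'
#' Integral of the one-sided power spectral density over a frequency band,
#' estimated with a Hann-windowed periodogram. A unit-amplitude sinusoid
#' inside the band yields approximately 0.5 (its mean-square power).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, Hz; must lie within `(0, fs/2)`.
#' @return nonnegative scalar power.
#' @export
band_power <- function(x, fs, band) {
  if (length(band) != 2L || band[1] >= band[2] || band[1] < 0 || band[2] > fs / 2)
    stop_arg("`band` must be an increasing interval within (0, fs/2)")
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))   # Hann
  X <- stats::fft(x * w)
  scale <- sum(w^2)                                        # window power
  half <- floor(n / 2)
  psd <- (Mod(X[seq_len(half + 1)])^2) / (fs * scale)
  last_double <- if (n %% 2 == 0) half else half + 1L   # Nyquist bin not doubled
  psd[2:last_double] <- 2 * psd[2:last_double]
  freqs <- (0:half) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(psd[sel]) * fs / n
}
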