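# EDF (European Data Format) reader/writer for fatigue recordings.
# One file per recording; standard 16-bit EDF with one-second data records,
# so EEG channels store 250 samples per record and the auxiliary channels
# 120. Physical scaling limits are taken from the data range, giving
# round-trip fidelity within the format's 16-bit quantization.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) pad_field(signif(x, 7), width)

#' Write a recording to an EDF file
#'
#' @param rec a `fatigue_recording` with integer `duration_s`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "fatigue_recording")) stop_arg("`rec` must be a fatigue_recording")
  if (rec$duration_s != round(rec$duration_s))
    stop_arg("EDF export requires an integer number of seconds")
  labels <- names(rec$channels)
  ns <- length(labels)
  n_rec <- as.integer(rec$duration_s)
  spr <- vapply(labels, function(nm) as.integer(channel_fs(rec, nm)), integer(1))
  pmin_ <- pmax_ <- numeric(ns)
  digs <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1          # constant channel: avoid zero range
    # round limits to what the 8-char ASCII header can carry, then quantize
    lo <- signif(lo, 7); hi <- signif(hi, 7)
    pmin_[i] <- lo; pmax_[i] <- hi
    digs[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
    digs[[i]] <- pmin(pmax(digs[[i]], -32768L), 32767L)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste("subject", rec$subject_id), 80),
    pad_field(sprintf("fatigue level %d seed %d", rec$fatigue_level, rec$seed), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4),
    paste(vapply(labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, num_field, "", width = 8), collapse = ""),
    paste(vapply(pmax_, num_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(-32768, 8), ns), collapse = ""),
    paste(rep(pad_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(vapply(spr, pad_field, "", width = 8), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(digs[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Reads standard 16-bit EDF. Channel labels matching the package's channel
#' set are mapped back onto a `fatigue_recording`; the fatigue level and
#' seed are recovered from the recording-identification header field when
#' present.
#'
#' @param path EDF file path.
#' @return a `fatigue_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80)
  recinfo <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                      # transducer
  for (i in seq_len(ns)) rd(8)                       # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                      # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  chans <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  names(chans) <- labels
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      phys <- pmin_[i] + (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      chans[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  level <- 0L; seed <- NA_integer_
  m <- regmatches(recinfo, regexec("fatigue level ([0-9]+) seed ([0-9]+)", recinfo))[[1]]
  if (length(m) == 3L) { level <- as.integer(m[2]); seed <- as.integer(m[3]) }
  fs_map <- c(EEG = EEG_FS, ECG = AUX_FS, EMG = AUX_FS, RESP = AUX_FS)
  structure(list(channels = chans, fs = fs_map,
                 duration_s = n_rec * rec_dur, fatigue_level = level,
                 subject_id = "edf", seed = seed,
                 clean = NULL, blink_onsets = NULL),
            class = "fatigue_recording")
}
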