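# Epoch-dataset container: a portable single RDS file holding the epoch
# array (n x channels x samples), labels and attributes (sampling rate,
# epoch length, channel ordering, seed, provenance, synthetic flags), plus a
# JSON sidecar manifest with the same attributes and a content hash so a
# dataset can be identified without loading it.

#' Construct an epoch dataset
#'
#' @param x numeric array `n x channels x samples`.
#' @param labels integer fatigue labels, length `n`.
#' @param channels channel names, length `dim(x)[2]`.
#' @param fs sampling rate in Hz.
#' @param provenance character vector of applied processing steps.
#' @param synthetic logical length-`n` flag marking generated (augmented)
#'   epochs; defaults to all `FALSE`.
#' @return an object of class `epoch_dataset`.
#' @export
epoch_dataset <- function(x, labels, channels, fs = 250,
                          provenance = character(0), synthetic = NULL) {
  if (length(dim(x)) != 3L) stop_arg("`x` must be an n x channels x samples array")
  n <- dim(x)[1L]
  if (length(labels) != n) stop_arg("`labels` must have one entry per epoch")
  if (length(channels) != dim(x)[2L]) stop_arg("`channels` length must match dim(x)[2]")
  synthetic <- synthetic %||% rep(FALSE, n)
  structure(list(x = x, labels = as.integer(labels), channels = channels,
                 fs = fs, provenance = provenance, synthetic = synthetic),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat(sprintf("<epoch_dataset> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$fs))
  cat("  labels:", paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                                 as.integer(table(x$labels))), collapse = " "), "\n")
  if (any(x$synthetic)) cat("  synthetic epochs:", sum(x$synthetic), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.epoch_dataset <- function(x) dim(x$x)[1L]

# subset an epoch dataset by epoch index
ds_subset <- function(ds, idx) {
  epoch_dataset(ds$x[idx, , , drop = FALSE], ds$labels[idx], ds$channels,
                ds$fs, ds$provenance, ds$synthetic[idx])
}

#' Write / read an epoch dataset container
#'
#' `write_epoch_dataset()` stores the dataset as an RDS file and writes a
#' `<path>.json` manifest (dimensions, sampling rate, channels, provenance,
#' md5 of the RDS) alongside it.
#'
#' @param ds an `epoch_dataset`.
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly; `read_epoch_dataset()` returns the dataset.
#' @export
write_epoch_dataset <- function(ds, path) {
  if (!inherits(ds, "epoch_dataset")) stop_arg("`ds` must be an epoch_dataset")
  saveRDS(ds, path, version = 2)
  manifest <- list(
    n_epochs = dim(ds$x)[1L], n_channels = dim(ds$x)[2L],
    n_samples = dim(ds$x)[3L], fs = ds$fs, channels = ds$channels,
    labels_table = as.list(table(ds$labels)),
    n_synthetic = sum(ds$synthetic),
    provenance = ds$provenance,
    md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_epoch_dataset
#' @export
read_epoch_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "epoch_dataset")) stop_arg("`%s` does not contain an epoch_dataset", path)
  ds
}
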