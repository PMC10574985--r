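# Classification metric suite: confusion matrix, accuracy, per-class and
# macro sensitivity/specificity/precision/F-score, Cohen's kappa, and
# one-vs-rest ROC/AUC.

#' Confusion matrix and metric report
#'
#' Computes the confusion matrix (rows = true class, columns = predicted)
#' and the standard multiclass metrics. Per-class rates are one-vs-rest;
#' macro values are their unweighted means.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class labels defining matrix order; defaults to the
#'   sorted union of observed labels.
#' @param train_duration_s optional informational training duration.
#' @return an object of class `metrics_report`.
#' @examples
#' r <- confusion_and_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' r$accuracy; r$kappa
#' @export
confusion_and_metrics <- function(y_true, y_pred, classes = NULL,
                                  train_duration_s = NA_real_) {
  if (length(y_true) == 0L) stop_arg("empty input")
  if (length(y_true) != length(y_pred)) stop_arg("label vectors differ in length")
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  if (!all(y_true %in% classes) || !all(y_pred %in% classes))
    stop_arg("labels outside the declared class set")
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(true = classes, pred = classes))
  for (i in seq_along(y_true))
    cm[match(y_true[i], classes), match(y_pred[i], classes)] <-
      cm[match(y_true[i], classes), match(y_pred[i], classes)] + 1L
  metrics_from_confusion(cm, train_duration_s)
}

# All rates from a confusion matrix (rows true, cols predicted).
metrics_from_confusion <- function(cm, train_duration_s = NA_real_) {
  n <- sum(cm)
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * prec * sens, prec + sens)
  acc <- sum(tp) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2       # chance agreement
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  structure(list(confusion = cm, n = n, accuracy = acc,
                 sensitivity = sens, specificity = spec, precision = prec,
                 f_score = f1, kappa = kappa,
                 macro_sensitivity = mean(sens, na.rm = TRUE),
                 macro_specificity = mean(spec, na.rm = TRUE),
                 macro_precision = mean(prec, na.rm = TRUE),
                 macro_f_score = mean(f1, na.rm = TRUE),
                 train_duration_s = train_duration_s),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d accuracy=%.4f kappa=%.4f\n",
              x$n, x$accuracy, x$kappa))
  cat(sprintf("  macro: sens=%.4f spec=%.4f prec=%.4f F=%.4f\n",
              x$macro_sensitivity, x$macro_specificity, x$macro_precision,
              x$macro_f_score))
  print(x$confusion)
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @export
write_metrics_json <- function(report, path) {
  out <- report
  out$confusion <- unclass(out$confusion)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' One-vs-rest ROC curves and AUC
#'
#' Sweeps the score threshold for each class against the rest; AUC by the
#' trapezoidal rule (equivalently, pairwise concordance with ties counted
#' half).
#'
#' @param y_true label vector.
#' @param scores matrix of class scores, one row per observation, one
#'   column per class (rows should sum to 1).
#' @param classes class labels matching the score columns; defaults to
#'   column names or the sorted unique labels.
#' @return class `roc_ovr`: per-class list with `fpr`, `tpr`, `auc` (AUC is
#'   `NA` with a warning for a class absent from `y_true`).
#' @export
roc_ovr <- function(y_true, scores, classes = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y_true)) stop_arg("scores/labels size mismatch")
  rs <- rowSums(scores)
  if (any(abs(rs - 1) > 1e-6)) stop_arg("score rows must sum to 1")
  classes <- classes %||% (if (!is.null(colnames(scores))) colnames(scores)
                           else as.character(sort(unique(y_true))))
  out <- list()
  for (j in seq_along(classes)) {
    pos <- y_true == classes[j]
    if (all(pos) || !any(pos)) {
      warning(sprintf("class %s is degenerate in y_true; AUC undefined", classes[j]))
      out[[as.character(classes[j])]] <- list(fpr = NA, tpr = NA, auc = NA_real_)
      next
    }
    s <- scores[, j]
    ths <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
    tpr <- vapply(ths, function(t) mean(s[pos] >= t), 0)
    fpr <- vapply(ths, function(t) mean(s[!pos] >= t), 0)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    out[[as.character(classes[j])]] <- list(fpr = fpr, tpr = tpr, auc = auc)
  }
  structure(out, class = "roc_ovr")
}

#' @export
print.roc_ovr <- function(x, ...) {
  cat("<roc_ovr> per-class AUC:\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]]$auc, digits = 4)))
  invisible(x)
}

#' @export
plot.roc_ovr <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, xlab = "FPR",
                 ylab = "TPR", ...)
  i <- 0
  for (nm in names(x)) {
    i <- i + 1
    if (!anyNA(x[[nm]]$fpr)) graphics::lines(x[[nm]]$fpr, x[[nm]]$tpr, col = i)
  }
  graphics::legend("bottomright", names(x), col = seq_along(x), lty = 1, bty = "n")
  invisible(x)
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise power is set so that `10 * log10(P_signal / P_noise)` equals
#' `snr_db`. `snr_db = Inf` returns the signal unchanged.
#'
#' @param x numeric signal with nonzero power.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed integer seed for the noise realization.
#' @return the noisy signal.
#' @export
add_awgn <- function(x, snr_db, seed = 1) {
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  p_sig <- mean(x^2)
  if (p_sig == 0) stop_arg("signal has zero power; SNR undefined")
  p_noise <- p_sig / 10^(snr_db / 10)
  with_seed(seed, x + stats::rnorm(length(x), sd = sqrt(p_noise)))
}

#' Noise-robustness curve of trained classifiers
#'
#' Evaluates each model on the test set after corrupting every epoch channel
#' with white Gaussian noise at each SNR of the grid (with `replicates`
#' independent noise draws), re-normalizing each channel to `[0, 1]` as the
#' preprocessing contract requires. The infinite-SNR entry reproduces the
#' clean test accuracy exactly.
#'
#' @param models named list of trained `fatigue_cnn`s (e.g. one per
#'   activation variant).
#' @param test an `epoch_dataset`.
#' @param snr_grid numeric SNRs in dB, decreasing (may start at `Inf`).
#' @param replicates independent noise draws per grid point.
#' @param seed integer seed.
#' @return class `robustness_curve`: data frame with columns `variant`,
#'   `snr_db`, `replicate`, `accuracy`, plus a `summary` attribute of mean
#'   and SD per (variant, SNR).
#' @export
robustness_curve <- function(models, test, snr_grid, replicates = 3, seed = 1) {
  if (length(snr_grid) == 0L) stop_arg("`snr_grid` is empty")
  if (is.unsorted(rev(snr_grid), strictly = TRUE))
    stop_arg("`snr_grid` must be strictly decreasing")
  rows <- list()
  for (v in names(models)) {
    model <- models[[v]]
    for (snr in snr_grid) {
      for (r in seq_len(replicates)) {
        noisy <- test
        if (is.finite(snr)) {
          s <- derive_seed(seed, sprintf("awgn-%s-%g-%d", v, snr, r))
          for (i in seq_len(dim(test$x)[1L])) for (c in seq_len(dim(test$x)[2L])) {
            noisy$x[i, c, ] <- minmax01(
              add_awgn(test$x[i, c, ], snr, seed = s + i * 131L + c))
          }
        }
        pred <- predict(model, noisy)
        rows[[length(rows) + 1L]] <-
          data.frame(variant = v, snr_db = snr, replicate = r,
                     accuracy = mean(pred == test$labels))
        if (!is.finite(snr)) break   # noiseless entry is deterministic
      }
    }
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ variant + snr_db, df,
                          function(a) c(mean = mean(a), sd = stats::sd(a)))
  summary_df <- data.frame(variant = agg$variant, snr_db = agg$snr_db,
                           mean = agg$accuracy[, "mean"],
                           sd = ifelse(is.na(agg$accuracy[, "sd"]), 0,
                                       agg$accuracy[, "sd"]))
  structure(df, summary = summary_df, class = c("robustness_curve", "data.frame"))
}

#' @export
plot.robustness_curve <- function(x, ...) {
  s <- attr(x, "summary")
  s$snr_plot <- ifelse(is.finite(s$snr_db), s$snr_db,
                       max(s$snr_db[is.finite(s$snr_db)], 0) + 10)
  vs <- unique(s$variant)
  graphics::plot(range(s$snr_plot), c(0, 1), type = "n",
                 xlab = "SNR (dB)", ylab = "accuracy", ...)
  for (i in seq_along(vs)) {
    si <- s[s$variant == vs[i], ]
    si <- si[order(si$snr_plot), ]
    graphics::lines(si$snr_plot, si$mean, col = i, type = "b")
  }
  graphics::legend("bottomright", vs, col = seq_along(vs), lty = 1, bty = "n")
  invisible(x)
}

#' Engineered statistical features of an epoch
#'
#' Per channel, in order: mean, peak coefficient (crest factor,
#' `max(|x|) / RMS`), skewness, variance (population), maximum, minimum,
#' kurtosis (`m4 / m2^2`). A zero-RMS channel yields `NA` crest factor with
#' a warning.
#'
#' @param epoch a `fatigue_epoch`, `epoch_dataset` row matrix (channels x
#'   samples) or numeric vector.
#' @return a `channels x 7` matrix with named columns.
#' @export
engineered_features <- function(epoch) {
  m <- if (inherits(epoch, "fatigue_epoch")) epoch$data
       else if (is.matrix(epoch)) epoch
       else matrix(epoch, nrow = 1)
  if (ncol(m) < 2L) stop_arg("epoch must have at least 2 samples")
  feat <- t(apply(m, 1L, function(x) {
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    rms <- sqrt(mean(x^2))
    crest <- if (rms == 0) { warning("zero-RMS channel: crest factor undefined"); NA_real_ }
             else max(abs(x)) / rms
    skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_
    kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else NA_real_
    c(mean = mu, crest = crest, skewness = skew, variance = m2,
      max = max(x), min = min(x), kurtosis = kurt)
  }))
  if (!is.null(rownames(m))) rownames(feat) <- rownames(m)
  feat
}
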