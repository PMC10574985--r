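# Metric suite: closed forms, brute-force equivalence, ROC concordance,
# AWGN calibration, engineered features.

# brute_metrics() and concordance_auc() oracles come from helper-oracles.R

test_that("hand-worked confusion matrices give the expected metrics", {
  # perfect two-class prediction
  r <- confusion_and_metrics(rep(0:1, each = 50), rep(0:1, each = 50))
  expect_identical(r$accuracy, 1)
  expect_identical(r$kappa, 1)
  expect_identical(unname(r$f_score), c(1, 1))
  # confusion [[40,10],[5,45]]: accuracy 0.85, kappa 0.70
  y_true <- rep(0:1, c(50, 50))
  y_pred <- c(rep(0, 40), rep(1, 10), rep(0, 5), rep(1, 45))
  r2 <- confusion_and_metrics(y_true, y_pred)
  expect_identical(unclass(unname(r2$confusion)),
                   matrix(c(40L, 5L, 10L, 45L), 2))
  expect_equal(r2$accuracy, 0.85)
  expect_equal(r2$kappa, 0.70, tolerance = 1e-12)
  # all-one-class prediction on balanced truth has zero chance-corrected skill
  r3 <- confusion_and_metrics(rep(0:1, each = 20), rep(0, 40), classes = 0:1)
  expect_equal(r3$kappa, 0)
  expect_error(confusion_and_metrics(integer(0), integer(0)), "empty")
  expect_error(confusion_and_metrics(0:1, c(0, 7), classes = 0:1), "outside")
})

test_that("metrics agree with a brute-force implementation on random inputs", {
  withr::with_seed(99, {
    for (rep_i in 1:100) {
      K <- sample(2:5, 1)
      n <- sample(20:60, 1)
      y_true <- sample(0:(K - 1), n, replace = TRUE)
      y_pred <- sample(0:(K - 1), n, replace = TRUE)
      r <- confusion_and_metrics(y_true, y_pred, classes = 0:(K - 1))
      b <- brute_metrics(y_true, y_pred, 0:(K - 1))
      expect_equal(r$accuracy, b$accuracy)
      expect_equal(unname(r$sensitivity), b$sensitivity)
      expect_equal(unname(r$specificity), b$specificity)
      expect_equal(unname(r$precision), b$precision)
      expect_equal(unname(r$f_score), b$f_score)
      expect_equal(r$kappa, b$kappa)
      expect_identical(sum(r$confusion), n)
    }
  })
})

test_that("AUC equals exhaustive pairwise concordance on small inputs", {
  withr::with_seed(17, {
    for (rep_i in 1:30) {
      n <- sample(4:12, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))   # both classes present
      s1 <- round(stats::runif(n), 2)                    # ties likely
      scores <- cbind(1 - s1, s1)
      r <- roc_ovr(y, scores, classes = 0:1)
      expect_equal(r[["1"]]$auc, concordance_auc(y, s1), tolerance = 1e-12)
      # ROC points are monotone
      expect_true(all(diff(r[["1"]]$fpr) >= 0))
      expect_true(all(diff(r[["1"]]$tpr) >= 0))
    }
  })
})

test_that("AUC cross-checks against pROC and handles degenerate classes", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    y <- sample(0:1, 40, replace = TRUE)
    s <- stats::runif(40)
  })
  r <- roc_ovr(y, cbind(1 - s, s), classes = 0:1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(r[["1"]]$auc, ref, tolerance = 1e-12)
  # perfectly separated and uninformative scores
  ysep <- rep(0:1, each = 5)
  expect_identical(roc_ovr(ysep, cbind(1 - ysep, ysep), classes = 0:1)[["1"]]$auc, 1)
  flat <- matrix(0.5, 10, 2)
  expect_identical(roc_ovr(ysep, flat, classes = 0:1)[["1"]]$auc, 0.5)
  y3 <- c(0, 0, 1, 1, 1, 0)                    # class 2 absent
  s3 <- matrix(1 / 3, 6, 3)
  expect_warning(r2 <- roc_ovr(y3, s3, classes = 0:2), "degenerate")
  expect_true(is.na(r2[["2"]]$auc))
  expect_identical(r2[["0"]]$auc, 0.5)
  expect_error(roc_ovr(ysep, matrix(0.4, 10, 2)), "sum to 1")
})

test_that("add_awgn hits the target SNR and respects its contracts", {
  withr::with_seed(3, x <- stats::rnorm(3750))
  for (snr in c(20, 10, 0)) {
    y <- add_awgn(x, snr, seed = 5)
    realized <- 10 * log10(mean(x^2) / mean((y - x)^2))
    expect_lt(abs(realized - snr), 0.5)
  }
  # realized SNR tightens with signal length
  err_at <- function(n) {
    withr::with_seed(4, xs <- stats::rnorm(n))
    abs(10 * log10(mean(xs^2) / mean((add_awgn(xs, 10, seed = 6) - xs)^2)) - 10)
  }
  errs <- vapply(c(500, 5000, 50000), err_at, 0)
  expect_lt(errs[3], errs[1])
  expect_identical(add_awgn(x, Inf), x)
  expect_identical(add_awgn(x, 10, seed = 8), add_awgn(x, 10, seed = 8))
  expect_error(add_awgn(numeric(10), 10), "zero power")
})

test_that("engineered features match closed forms", {
  fs <- 100
  x <- sin(2 * pi * 5 * seq_len(20 * fs) / fs)     # whole periods
  f <- engineered_features(x)
  expect_identical(colnames(f),
                   c("mean", "crest", "skewness", "variance", "max", "min",
                     "kurtosis"))
  expect_equal(unname(f[, "mean"]), 0, tolerance = 1e-10)
  expect_equal(unname(f[, "max"]), 1, tolerance = 1e-6)
  expect_equal(unname(f[, "min"]), -1, tolerance = 1e-6)
  expect_equal(unname(f[, "crest"]), sqrt(2), tolerance = 1e-3)
  expect_equal(unname(f[, "kurtosis"]), 1.5, tolerance = 1e-3)   # sinusoid m4/m2^2
  f2 <- engineered_features(c(1, 2, 3, 4))
  expect_equal(unname(f2[, "mean"]), 2.5)
  expect_equal(unname(f2[, "variance"]), 1.25)                   # population variance
  expect_equal(unname(f2[, "max"]), 4)
  expect_equal(unname(f2[, "min"]), 1)
  fc <- engineered_features(rep(3, 10))
  expect_equal(unname(fc[, "variance"]), 0)
  expect_equal(unname(fc[, "max"]), unname(fc[, "min"]))
  expect_warning(fz <- engineered_features(numeric(10)), "crest")
  expect_true(is.na(unname(fz[, "crest"])))
  expect_error(engineered_features(1), "2 samples")
})

test_that("metrics report serializes to JSON", {
  r <- confusion_and_metrics(rep(0:1, each = 5), rep(0:1, each = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy, 1)
  expect_equal(back$kappa, 1)
})
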