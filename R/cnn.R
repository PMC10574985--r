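# Seven-block 1-D CNN with interval type-2 fuzzy activations.
#
# Block structure: an input dropout layer, then seven blocks of
# [conv1d (same padding) -> activation -> maxpool(2,2) -> batch-norm], with
# an extra dropout after the first block only, then a dense softmax head.
# Filter schedule 16, 32, 64, 64, 64, 64, 64; first kernel 128 with stride
# 20, remaining kernels 3 with stride 1.

#' Architecture specification for the fatigue CNN
#'
#' Defaults encode the reference seven-block architecture. The temporal
#' input length is a free parameter: the default pipeline input is the four
#' selected EEG channels concatenated into one vector (4 x 3750 = 15000
#' samples); the canonical published shape table corresponds to an input of
#' length 47500 whose first-block output length is 2375.
#'
#' @param n_classes number of output classes, one of 2, 3, 5.
#' @param input_len temporal length of the input.
#' @param in_channels number of input channels (1 for concatenated input).
#' @param activation `"t2f"`, `"relu"` or `"leaky_relu"`.
#' @param filters,kernels,strides per-block conv parameters (length 7).
#' @param dropout dropout rate (applied before block 1 and after block 1).
#' @param first_init initialization of the first (wide) convolution:
#'   `"filterbank"` (default) starts its filters as windowed sinusoids
#'   log-spaced over the EEG bands — a learnable spectral prior standard in
#'   EEG convolutional nets — while `"he"` uses plain random init.
#' @param fs sampling rate used by the filterbank initialization.
#' @return an object of class `arch_spec`.
#' @export
arch_spec <- function(n_classes = 5, input_len = 15000, in_channels = 1,
                      activation = c("t2f", "relu", "leaky_relu"),
                      filters = c(16, 32, 64, 64, 64, 64, 64),
                      kernels = c(128, 3, 3, 3, 3, 3, 3),
                      strides = c(20, 1, 1, 1, 1, 1, 1),
                      dropout = 0.3,
                      first_init = c("filterbank", "he"), fs = 250) {
  first_init <- match.arg(first_init)
  activation <- match.arg(activation)
  if (!n_classes %in% c(2, 3, 5))
    stop_arg("`n_classes` must be 2, 3 or 5")
  if (length(filters) != length(kernels) || length(filters) != length(strides))
    stop_arg("`filters`, `kernels`, `strides` must have equal length")
  structure(list(n_classes = as.integer(n_classes),
                 input_len = as.integer(input_len),
                 in_channels = as.integer(in_channels),
                 activation = activation, filters = as.integer(filters),
                 kernels = as.integer(kernels), strides = as.integer(strides),
                 dropout = dropout, first_init = first_init, fs = fs),
            class = "arch_spec")
}

#' Output length of a conv or pool layer
#'
#' Same-padding convolution maps length `L` to `ceiling(L / stride)`;
#' max-pooling maps `L` to `floor(L / pool_stride)`.
#'
#' @param input_len input temporal length (>= 1).
#' @param layer a list with `$type` (`"conv"` or `"pool"`) and `$stride`.
#' @return integer output length.
#' @export
layer_length <- function(input_len, layer) {
  if (input_len < 1) stop_arg("`input_len` must be >= 1")
  switch(layer$type,
    conv = conv_out_len(input_len, layer$stride),
    pool = pool_out_len(input_len, layer$stride),
    stop_arg("layer$type must be 'conv' or 'pool'"))
}

#' Temporal-length chain of an architecture
#'
#' @param arch an [arch_spec()].
#' @param input_len optional input length override.
#' @return integer vector of per-layer lengths, alternating conv and pool
#'   outputs over the seven blocks.
#' @export
cnn_length_chain <- function(arch, input_len = arch$input_len) {
  L <- input_len
  out <- integer(0)
  for (b in seq_along(arch$filters)) {
    L <- layer_length(L, list(type = "conv", stride = arch$strides[b]))
    out <- c(out, L)
    L <- layer_length(L, list(type = "pool", stride = 2L))
    out <- c(out, L)
  }
  out
}

#' Build the CNN
#'
#' @param arch an [arch_spec()].
#' @param seed seed for weight initialization.
#' @return an untrained model object of class `fatigue_cnn`.
#' @export
build_cnn <- function(arch, seed = 1) {
  if (!inherits(arch, "arch_spec")) stop_arg("`arch` must be an arch_spec")
  with_seed(seed, {
    layers <- list(nn_dropout(arch$dropout))
    in_ch <- arch$in_channels
    L <- arch$input_len
    for (b in seq_along(arch$filters)) {
      layers <- c(layers, list(
        nn_conv1d(in_ch, arch$filters[b], arch$kernels[b], arch$strides[b],
                  init = if (b == 1L) arch$first_init else "he", fs = arch$fs),
        nn_activation(arch$activation, arch$filters[b]),
        nn_maxpool(),
        nn_batchnorm(arch$filters[b])))
      if (b == 1L) layers <- c(layers, list(nn_dropout(arch$dropout)))
      in_ch <- arch$filters[b]
      L <- pool_out_len(conv_out_len(L, arch$strides[b]), 2L)
      if (L < 1L) stop_arg("input_len %d collapses before block %d", arch$input_len, b)
    }
    layers <- c(layers, list(nn_dense(in_ch * L, arch$n_classes, "linear")))
    structure(list(layers = layers, arch = arch, flat_len = L,
                   n_classes = arch$n_classes, trained = FALSE,
                   history = NULL, seed = as.integer(seed)),
              class = "fatigue_cnn")
  })
}

# One equal-weight calibration pass for batch-norm inference statistics
# ("precise BN"): forward the training set in minibatches exactly as during
# training (dropout active, batch-norm normalizing by minibatch statistics
# — the distribution the scale/shift parameters were learned against) and
# set each layer's running statistics to the average of those minibatch
# statistics.
bn_recalibrate <- function(model, x, batch_size) {
  layers <- model$layers
  n <- dim(x)[3L]
  idx_bn <- which(vapply(layers, function(l) l$type == "batchnorm", TRUE))
  if (!length(idx_bn) || n == 0L) return(layers)
  acc <- lapply(idx_bn, function(i) list(mu = 0, v = 0))
  names(acc) <- as.character(idx_bn)
  # shuffle before chunking: minibatch statistics must reflect the mixed
  # batch composition seen in training, not the dataset's class grouping
  ord <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    h <- x[, , ord[s:min(s + batch_size - 1L, n)], drop = FALSE]
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (ly$type == "dense") {
        d <- dim(h); dim(h) <- c(d[1L] * d[2L], d[3L])
      }
      fw <- layer_forward(ly, h, training = TRUE)
      if (ly$type == "batchnorm") {
        k <- as.character(i)
        acc[[k]]$mu <- acc[[k]]$mu + fw$batch_mean
        acc[[k]]$v <- acc[[k]]$v + fw$batch_var
      }
      h <- fw$out
    }
  }
  for (i in idx_bn) {
    k <- as.character(i)
    layers[[i]]$running_mean <- acc[[k]]$mu / length(starts)
    layers[[i]]$running_var <- acc[[k]]$v / length(starts)
  }
  layers
}

# forward through all layers; returns logits, caches, and layers (with
# updated batch-norm running statistics when training)
cnn_forward <- function(model, x, training = FALSE) {
  layers <- model$layers
  caches <- vector("list", length(layers))
  h <- x
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      d <- dim(h)
      dim(h) <- c(d[1L] * d[2L], d[3L])
    }
    fw <- layer_forward(ly, h, training)
    if (ly$type == "batchnorm" && training) {
      m <- ly$momentum
      layers[[i]]$running_mean <- m * ly$running_mean + (1 - m) * fw$batch_mean
      layers[[i]]$running_var <- m * ly$running_var + (1 - m) * fw$batch_var
    }
    caches[[i]] <- fw$cache
    h <- fw$out
  }
  list(logits = h, caches = caches, layers = layers)
}

cnn_backward <- function(model, caches, dlogits) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  dh <- dlogits
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], dh, caches[[i]])
    grads[[i]] <- bw$grads
    dh <- bw$dx
    if (layers[[i]]$type == "dense") {
      # restore conv shape below the flatten point
      B <- ncol(dh)
      dim(dh) <- c(nrow(dh) / model$flat_len, model$flat_len, B)
    }
  }
  grads
}

#' Count of learnable activation parameters
#'
#' For the T2F activation this is exactly 3 per activation channel (slope,
#' uncertainty width, blend), i.e. `3 * sum(filters)`; rectifier variants
#' contribute none.
#'
#' @param x a `fatigue_cnn` or an [arch_spec()].
#' @return integer parameter count.
#' @export
n_activation_params <- function(x) {
  arch <- if (inherits(x, "fatigue_cnn")) x$arch else x
  if (!inherits(arch, "arch_spec")) stop_arg("`x` must be a fatigue_cnn or arch_spec")
  if (arch$activation == "t2f") 3L * sum(arch$filters) else 0L
}

#' Training configuration
#'
#' Defaults follow the tuned values of the reference model: Adadelta
#' optimizer, cross-entropy loss, batch size 10, learning rate 0.001,
#' dropout 0.3.
#'
#' @param optimizer one of `"adadelta"`, `"rmsprop"`, `"adam"`, `"sgd"`,
#'   `"adamax"`.
#' @param learning_rate learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epochs.
#' @param patience early-stopping patience on validation accuracy (epochs);
#'   `Inf` disables early stopping.
#' @param lr_decay per-epoch multiplicative learning-rate decay (1 = none).
#' @param restarts maximum automatic restarts (fresh derived seed) when a
#'   run's selection metric never exceeds chance level.
#' @return a list of class `train_config`.
#' @export
train_config <- function(optimizer = "adadelta", learning_rate = 0.001,
                         batch_size = 10, max_epochs = 30, patience = Inf,
                         lr_decay = 1, restarts = 2) {
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 lr_decay = lr_decay, restarts = as.integer(restarts),
                 loss = "cross_entropy"),
            class = "train_config")
}

# epoch_dataset -> (Ci, L, B) input array per the arch input contract
ds_to_input <- function(ds, arch) {
  n <- dim(ds$x)[1L]; C <- dim(ds$x)[2L]; L <- dim(ds$x)[3L]
  if (arch$in_channels == 1L) {
    stopifnot(C * L == arch$input_len)
    x <- aperm(ds$x, c(3L, 2L, 1L))     # samples, channels, epoch
    dim(x) <- c(1L, C * L, n)
  } else {
    stopifnot(C == arch$in_channels, L == arch$input_len)
    x <- aperm(ds$x, c(2L, 3L, 1L))
  }
  x
}

# map fatigue levels to contiguous class indices 1..K
encode_labels <- function(labels) {
  lev <- sort(unique(labels))
  list(y = match(labels, lev), levels = lev)
}

cnn_eval <- function(model, x, y) {
  fw <- cnn_forward(model, x, training = FALSE)
  sx <- softmax_xent(fw$logits, y)
  pred <- max.col(t(sx$probs))
  list(loss = sx$loss, acc = mean(pred == y))
}

#' Train the fatigue classifier
#'
#' Minibatch training with the configured optimizer; tracks per-epoch
#' training and validation loss/accuracy and returns the parameters of the
#' best-validation epoch. Fixed seeds give bit-reproducible histories.
#'
#' If every epoch's selection metric stays at chance level — a run stuck in
#' a degenerate basin (typically one whose features only work relative to
#' minibatch statistics) — training restarts from a fresh derived seed, up
#' to `config$restarts` times, and the best attempt is returned.
#'
#' @param train,validation `epoch_dataset`s (validation may be `NULL`).
#' @param arch an [arch_spec()]; its `n_classes` must match the number of
#'   distinct labels.
#' @param config a [train_config()].
#' @param seed integer seed (weight init, shuffling, dropout).
#' @param verbose print per-epoch progress.
#' @return a trained `fatigue_cnn` with `$history` (data frame),
#'   `$class_levels` (fatigue levels in softmax order) and `$attempt`
#'   (which restart produced it).
#' @export
train_classifier <- function(train, validation = NULL, arch = arch_spec(),
                             config = train_config(), seed = 1,
                             verbose = FALSE) {
  chance <- 1 / arch$n_classes + 0.05
  best_fit <- NULL
  for (attempt in seq_len(1L + max(0L, config$restarts %||% 0L))) {
    s <- if (attempt == 1L) seed else derive_seed(seed, paste0("restart", attempt))
    fit <- train_classifier_once(train, validation, arch, config, s, verbose)
    fit$attempt <- attempt
    if (is.null(best_fit) || isTRUE(fit$best_metric > best_fit$best_metric))
      best_fit <- fit
    if (!fit$trained || is.na(fit$best_metric) || fit$best_metric > chance)
      break
    if (verbose)
      message(sprintf("attempt %d stuck at chance (metric %.3f); restarting",
                      attempt, fit$best_metric))
  }
  best_fit
}

train_classifier_once <- function(train, validation, arch, config, seed,
                                  verbose) {
  if (length(train) == 0L) stop_arg("`train` is empty")
  enc <- encode_labels(train$labels)
  if (length(enc$levels) != arch$n_classes)
    stop_arg("training data has %d classes but arch expects %d",
             length(enc$levels), arch$n_classes)
  model <- build_cnn(arch, seed = derive_seed(seed, "init"))
  model$class_levels <- enc$levels
  if (config$max_epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                                train_acc = numeric(0), val_loss = numeric(0),
                                val_acc = numeric(0))
    return(model)
  }
  x_tr <- ds_to_input(train, arch)
  y_tr <- enc$y
  has_val <- !is.null(validation) && length(validation) > 0L
  if (has_val) {
    x_va <- ds_to_input(validation, arch)
    y_va <- match(validation$labels, enc$levels)
    if (anyNA(y_va)) stop_arg("validation labels outside training classes")
  }
  opt <- make_optimizer(config$optimizer, lr = config$learning_rate)
  n <- length(y_tr)
  bs <- config$batch_size
  hist <- vector("list", config$max_epochs)
  best <- list(metric = -Inf, layers = model$layers, epoch = 0L)
  wait <- 0L
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tl <- 0; tacc <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- x_tr[, , idx, drop = FALSE]
        fw <- cnn_forward(model, xb, training = TRUE)
        model$layers <- fw$layers
        sx <- softmax_xent(fw$logits, y_tr[idx])
        grads <- cnn_backward(model, fw$caches, sx$dZ)
        model$layers <- layers_update(model$layers, grads, opt)
        tl <- tl + sx$loss
        tacc <- tacc + mean(max.col(t(sx$probs)) == y_tr[idx])
        nb <- nb + 1L
      }
      va <- if (has_val) cnn_eval(model, x_va, y_va) else list(loss = NA_real_, acc = NA_real_)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = tl / nb,
                               train_acc = tacc / nb,
                               val_loss = va$loss, val_acc = va$acc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f acc %.3f  val_acc %s", ep,
                        tl / nb, tacc / nb, format(va$acc, digits = 3)))
      metric <- if (has_val) va$acc else tacc / nb
      # ties go to the later epoch: same validation score, more training
      if (!is.na(metric) && metric >= best$metric) {
        best <- list(metric = metric, layers = model$layers, epoch = ep)
        wait <- 0L
      } else wait <- wait + 1L
      if (wait > config$patience) break
      if (!is.finite(tl)) stop("training diverged: non-finite loss (try a lower learning rate)")
      opt$lr <- opt$lr * config$lr_decay
    }
  })
  model$layers <- best$layers
  # refresh batch-norm inference statistics with one equal-weight pass over
  # the training set (the exponential averages of an early best epoch are
  # still dominated by their initialization)
  with_seed(derive_seed(seed, "bn-recal"), {
    model$layers <- bn_recalibrate(model, x_tr, bs)
  })
  model$best_epoch <- best$epoch
  model$best_metric <- best$metric
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$train_config <- config
  model
}

#' Predict from a trained fatigue CNN
#'
#' @param object a `fatigue_cnn`.
#' @param newdata an `epoch_dataset` or an input array shaped like the
#'   training input.
#' @param type `"class"` for fatigue-level labels, `"prob"` for the softmax
#'   matrix (rows = epochs).
#' @param ... unused.
#' @export
predict.fatigue_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "epoch_dataset")) ds_to_input(newdata, object$arch) else newdata
  fw <- cnn_forward(object, x, training = FALSE)
  P <- t(softmax_cols(fw$logits))
  colnames(P) <- as.character(object$class_levels %||% seq_len(object$n_classes) - 1L)
  if (type == "prob") return(P)
  lv <- object$class_levels %||% (seq_len(object$n_classes) - 1L)
  lv[max.col(P)]
}

#' @export
print.fatigue_cnn <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<fatigue_cnn> %d-class, %s activation, input %d x %d\n",
              a$n_classes, a$activation, a$in_channels, a$input_len))
  cat(sprintf("  7-block conv net, filters %s; activation params: %d\n",
              paste(a$filters, collapse = "/"), n_activation_params(x)))
  if (x$trained)
    cat(sprintf("  trained %d epochs (best epoch %d, val metric %.3f)\n",
                nrow(x$history), x$best_epoch,
                max(c(x$history$val_acc, x$history$train_acc), na.rm = TRUE)))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.fatigue_cnn <- function(object, ...) {
  print(object)
  chain <- cnn_length_chain(object$arch)
  cat("  temporal lengths:", paste(chain, collapse = " -> "), "\n")
  if (object$trained && nrow(object$history)) {
    h <- utils::tail(object$history, 1)
    cat(sprintf("  final: train_loss %.4f train_acc %.3f val_acc %s\n",
                h$train_loss, h$train_acc, format(h$val_acc, digits = 3)))
  }
  invisible(object)
}

#' @export
plot.fatigue_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop_arg("no training history to plot")
  graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", ...)
  if (any(!is.na(h$val_acc)))
    graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::legend("bottomright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Extract T2F activation parameters
#'
#' @param object a `fatigue_cnn` with T2F activations.
#' @param ... unused.
#' @return a data frame with one row per activation channel: block, channel,
#'   and the constrained-scale slope `a`, uncertainty width `delta` and
#'   blend `alpha`.
#' @export
coef.fatigue_cnn <- function(object, ...) {
  if (object$arch$activation != "t2f")
    stop_arg("activation '%s' has no learnable parameters", object$arch$activation)
  rows <- list(); b <- 0L
  for (ly in object$layers) {
    if (ly$type != "activation") next
    b <- b + 1L
    rows[[b]] <- data.frame(block = b, channel = seq_len(ly$channels),
                            a = exp(ly$params$a_raw),
                            delta = 0.99 * sigmoid(ly$params$d_raw),
                            alpha = sigmoid(ly$params$b_raw))
  }
  do.call(rbind, rows)
}

#' Save / load classifier checkpoints
#'
#' Single-file RDS checkpoint; the architecture is additionally embedded
#' as a JSON string (`$arch_json`) so a checkpoint can be inspected
#' without package-specific knowledge.
#'
#' @param model a `fatigue_cnn`.
#' @param path file path.
#' @export
save_cnn <- function(model, path) {
  model$arch_json <- as.character(
    jsonlite::toJSON(unclass(model$arch), auto_unbox = TRUE))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "fatigue_cnn")) stop_arg("not a fatigue_cnn checkpoint")
  m
}

#' Split an epoch dataset into train/validation/test
#'
#' @param ds an `epoch_dataset`.
#' @param fractions length-3 positive fractions summing to 1 (default
#'   70/10/20).
#' @param seed integer seed.
#' @param stratified stratify the split by label (default `TRUE`).
#' @return named list of `epoch_dataset`s: `train`, `validation`, `test`.
#' @export
split_dataset <- function(ds, fractions = c(0.70, 0.10, 0.20), seed = 1,
                          stratified = TRUE) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_arg("`fractions` must be 3 positive numbers summing to 1")
  n <- length(ds)
  assign_split <- function(m) {
    n_tr <- round(m * fractions[1])
    n_va <- round(m * fractions[2])
    c(rep(1L, n_tr), rep(2L, n_va), rep(3L, m - n_tr - n_va))
  }
  with_seed(seed, {
    grp <- integer(n)
    if (stratified) {
      for (lv in unique(ds$labels)) {
        idx <- which(ds$labels == lv)
        grp[idx] <- sample(assign_split(length(idx)))
      }
    } else grp <- sample(assign_split(n))
    list(train = ds_subset(ds, grp == 1L),
         validation = ds_subset(ds, grp == 2L),
         test = ds_subset(ds, grp == 3L))
  })
}

#' k-fold cross-validation of the classifier
#'
#' Splits the dataset into `k` disjoint stratified folds; each fold serves
#' once as the test set while the rest trains a fresh model.
#'
#' @param ds an `epoch_dataset`.
#' @param k number of folds (default 5).
#' @param arch an [arch_spec()].
#' @param config a [train_config()].
#' @param seed integer seed.
#' @return class `fatigue_cv`: per-fold metric reports plus mean and SD of
#'   fold accuracy.
#' @export
kfold_cv <- function(ds, k = 5, arch = arch_spec(), config = train_config(),
                     seed = 1) {
  if (k < 2) stop_arg("`k` must be >= 2")
  n <- length(ds)
  if (n < k) stop_arg("dataset smaller than k")
  folds <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    for (lv in unique(ds$labels)) {
      idx <- which(ds$labels == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  reports <- vector("list", k)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- ds_subset(ds, folds != f)
    te <- ds_subset(ds, folds == f)
    fit <- train_classifier(tr, NULL, arch, config, seed = derive_seed(seed, paste0("fold", f)))
    pred <- predict(fit, te)
    reports[[f]] <- confusion_and_metrics(te$labels, pred, classes = fit$class_levels)
    accs[f] <- reports[[f]]$accuracy
  }
  structure(list(folds = folds, reports = reports, fold_accuracy = accs,
                 mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs)),
            class = "fatigue_cv")
}

#' @export
print.fatigue_cv <- function(x, ...) {
  cat(sprintf("<fatigue_cv> %d folds: accuracy %.3f +/- %.3f\n",
              length(x$fold_accuracy), x$mean_accuracy, x$sd_accuracy))
  cat("  per fold:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}
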