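# Generative adversarial augmentation of epoch datasets.
#
# Generator: fully connected blocks of widths 128, 256, 512, 1024, 3750
# (leaky-rectifier hidden activations, sigmoid output so samples live in
# the normalized [0,1] epoch range) mapping a 100-d uniform latent vector
# to a length-3750 signal. Discriminator: five fully connected layers with
# dropout after layers 1 and 3 and a sigmoid squashing to (0,1). Both train
# under the minimax objective with stochastic gradient descent, alternating
# k discriminator steps per generator step.

GAN_EPS <- 1e-7

#' GAN specification
#'
#' Defaults encode the reference augmentation network: 100-d uniform latent,
#' generator widths 128/256/512/1024/3750, five-layer discriminator with
#' dropout at positions 1 and 3, batch size 10, learning rate 1e-5, 200
#' training epochs, SGD for the discriminator.
#'
#' @param latent_dim latent dimension.
#' @param generator_dims hidden-to-output layer widths; the last entry is
#'   the generated signal length.
#' @param discriminator_dims widths of the five discriminator layers (last
#'   must be 1).
#' @param dropout_positions indices of discriminator layers followed by
#'   dropout.
#' @param dropout_rate discriminator dropout rate.
#' @param batch_size minibatch size.
#' @param learning_rate SGD learning rate.
#' @param epochs training epochs.
#' @param k_disc discriminator updates per generator update.
#' @param generator_loss `"non_saturating"` (default) or `"saturating"`
#'   (the plain minimax form).
#' @return an object of class `gan_spec`.
#' @export
gan_spec <- function(latent_dim = 100,
                     generator_dims = c(128, 256, 512, 1024, 3750),
                     discriminator_dims = c(1024, 512, 256, 128, 1),
                     dropout_positions = c(1, 3),
                     dropout_rate = 0.3,
                     batch_size = 10,
                     learning_rate = 1e-5,
                     epochs = 200,
                     k_disc = 1,
                     generator_loss = c("non_saturating", "saturating")) {
  generator_loss <- match.arg(generator_loss)
  if (length(generator_dims) < 2L) stop_arg("`generator_dims` needs >= 2 layers")
  if (utils::tail(discriminator_dims, 1) != 1L)
    stop_arg("last discriminator layer must have width 1")
  structure(list(latent_dim = as.integer(latent_dim),
                 generator_dims = as.integer(generator_dims),
                 discriminator_dims = as.integer(discriminator_dims),
                 dropout_positions = as.integer(dropout_positions),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 k_disc = as.integer(k_disc),
                 generator_loss = generator_loss),
            class = "gan_spec")
}

#' Build the generator network
#'
#' @param spec a [gan_spec()].
#' @param seed seed for weight initialization.
#' @return class `gan_generator`; maps latent vectors of length
#'   `spec$latent_dim` to signals of length `tail(spec$generator_dims, 1)`.
#' @export
build_generator <- function(spec = gan_spec(), seed = 1) {
  if (!inherits(spec, "gan_spec")) stop_arg("`spec` must be a gan_spec")
  with_seed(seed, {
    dims <- c(spec$latent_dim, spec$generator_dims)
    layers <- list()
    for (i in seq_len(length(dims) - 1L)) {
      act <- if (i < length(dims) - 1L) "leaky_relu" else "sigmoid"
      layers[[i]] <- nn_dense(dims[i], dims[i + 1L], act)
    }
    structure(list(layers = layers, spec = spec, out_len = dims[length(dims)]),
              class = "gan_generator")
  })
}

#' Build the discriminator network
#'
#' @param spec a [gan_spec()].
#' @param input_len length of the signals to judge (defaults to the
#'   generator output length).
#' @param seed seed for weight initialization.
#' @return class `gan_discriminator`; maps signals to a probability in
#'   (0,1). Five fully connected layers; dropout after layers 1 and 3.
#' @export
build_discriminator <- function(spec = gan_spec(),
                                input_len = utils::tail(spec$generator_dims, 1),
                                seed = 1) {
  if (!inherits(spec, "gan_spec")) stop_arg("`spec` must be a gan_spec")
  with_seed(seed, {
    dims <- c(input_len, spec$discriminator_dims)
    layers <- list()
    for (i in seq_len(length(dims) - 1L)) {
      act <- if (i < length(dims) - 1L) "leaky_relu" else "sigmoid"
      layers[[i]] <- list(dense = nn_dense(dims[i], dims[i + 1L], act),
                          dropout = if (i %in% spec$dropout_positions)
                            nn_dropout(spec$dropout_rate) else NULL)
    }
    structure(list(layers = layers, spec = spec, input_len = input_len),
              class = "gan_discriminator")
  })
}

# forward helpers; z and x are (features x batch) matrices
generator_forward <- function(gen, z) {
  caches <- vector("list", length(gen$layers))
  h <- z
  for (i in seq_along(gen$layers)) {
    fw <- dense_forward(gen$layers[[i]], h)
    caches[[i]] <- fw$cache
    h <- fw$out
  }
  list(out = h, caches = caches)
}

discriminator_forward <- function(disc, x, training = FALSE) {
  caches <- vector("list", length(disc$layers))
  h <- x
  for (i in seq_along(disc$layers)) {
    fw <- dense_forward(disc$layers[[i]]$dense, h)
    dcache <- NULL
    out <- fw$out
    if (!is.null(disc$layers[[i]]$dropout)) {
      dfw <- dropout_forward(disc$layers[[i]]$dropout, out, training)
      dcache <- dfw$cache
      out <- dfw$out
    }
    caches[[i]] <- list(dense = fw$cache, dropout = dcache)
    h <- out
  }
  p <- pmin(pmax(h, GAN_EPS), 1 - GAN_EPS)
  list(p = as.numeric(p), pre_clamp = as.numeric(h), caches = caches)
}

discriminator_backward <- function(disc, dp, caches) {
  grads <- vector("list", length(disc$layers))
  dh <- matrix(dp, 1L)
  for (i in rev(seq_along(disc$layers))) {
    if (!is.null(caches[[i]]$dropout)) {
      dh <- dropout_backward(disc$layers[[i]]$dropout, dh, caches[[i]]$dropout)$dx
    }
    bw <- dense_backward(disc$layers[[i]]$dense, dh, caches[[i]]$dense)
    grads[[i]] <- bw$grads
    dh <- bw$dx
  }
  list(grads = grads, dx = dh)
}

generator_backward <- function(gen, dout, caches) {
  grads <- vector("list", length(gen$layers))
  dh <- dout
  for (i in rev(seq_along(gen$layers))) {
    bw <- dense_backward(gen$layers[[i]], dh, caches[[i]])
    grads[[i]] <- bw$grads
    dh <- bw$dx
  }
  grads
}

#' Adversarial losses from discriminator outputs
#'
#' Discriminator loss is the negative log-likelihood of correct real/fake
#' discrimination, `-mean(log d_real) - mean(log(1 - d_fake))`; at
#' `d_real = d_fake = 0.5` it equals `2 log 2`. The generator loss is
#' either the non-saturating form `-mean(log d_fake)` (default) or the
#' saturating minimax form `mean(log(1 - d_fake))`.
#'
#' @param d_real,d_fake discriminator probabilities on real and generated
#'   batches; values at exactly 0 or 1 are clamped to `[1e-7, 1 - 1e-7]`.
#' @param generator_loss `"non_saturating"` or `"saturating"`.
#' @return list with `d_loss` and `g_loss`.
#' @export
gan_losses <- function(d_real, d_fake,
                       generator_loss = c("non_saturating", "saturating")) {
  generator_loss <- match.arg(generator_loss)
  if (any(d_real < 0 | d_real > 1) || any(d_fake < 0 | d_fake > 1))
    stop_arg("discriminator outputs must be probabilities")
  d_real <- pmin(pmax(d_real, GAN_EPS), 1 - GAN_EPS)
  d_fake <- pmin(pmax(d_fake, GAN_EPS), 1 - GAN_EPS)
  d_loss <- -mean(log(d_real)) - mean(log(1 - d_fake))
  g_loss <- if (generator_loss == "non_saturating") -mean(log(d_fake))
            else mean(log(1 - d_fake))
  list(d_loss = d_loss, g_loss = g_loss)
}

#' Draw generator samples
#'
#' @param object a `gan_generator` (or `fatigue_gan`).
#' @param nsim number of samples.
#' @param seed integer seed.
#' @param ... unused.
#' @return matrix `nsim x out_len`.
#' @export
simulate.gan_generator <- function(object, nsim = 1, seed = 1, ...) {
  with_seed(seed, {
    z <- matrix(stats::runif(object$spec$latent_dim * nsim, -1, 1),
                object$spec$latent_dim, nsim)
    t(generator_forward(object, z)$out)
  })
}

#' @export
simulate.fatigue_gan <- function(object, nsim = 1, seed = 1, ...) {
  simulate.gan_generator(object$generator, nsim, seed, ...)
}

#' Train the GAN
#'
#' Alternating optimization: `k_disc` stochastic-gradient discriminator
#' steps per generator step, minibatches of `spec$batch_size`, for
#' `spec$epochs` passes over the real data. With `epochs = 0` the untrained
#' networks are returned with an empty history.
#'
#' @param real matrix of real epochs (rows = epochs) whose column count
#'   matches the generator output length, or an `epoch_dataset` with a
#'   single channel.
#' @param spec a [gan_spec()].
#' @param seed integer seed.
#' @param holdout_frac fraction of real rows held out to report final
#'   discriminator accuracy on a real/fake mix.
#' @param verbose print progress every 10 epochs.
#' @return class `fatigue_gan`: `generator`, `discriminator`, `history`
#'   (per-epoch mean `d_loss`/`g_loss`), `disc_accuracy`.
#' @export
train_gan <- function(real, spec = gan_spec(), seed = 1, holdout_frac = 0.1,
                      verbose = FALSE) {
  if (inherits(real, "epoch_dataset")) {
    n <- dim(real$x)[1L]
    real <- matrix(real$x, n, dim(real$x)[2L] * dim(real$x)[3L])
  }
  if (!is.matrix(real)) real <- matrix(real, nrow = 1)
  out_len <- utils::tail(spec$generator_dims, 1)
  if (ncol(real) != out_len)
    stop_arg("real epochs have length %d but the generator emits %d",
             ncol(real), out_len)
  if (nrow(real) < spec$batch_size && spec$epochs > 0L)
    stop_arg("need at least batch_size (%d) real epochs, got %d",
             spec$batch_size, nrow(real))
  gen <- build_generator(spec, seed = derive_seed(seed, "gen-init"))
  disc <- build_discriminator(spec, out_len, seed = derive_seed(seed, "disc-init"))
  n_hold <- floor(nrow(real) * holdout_frac)
  hist <- NULL
  with_seed(derive_seed(seed, "gan-train"), {
    hold_idx <- if (n_hold > 0) sample.int(nrow(real), n_hold) else integer(0)
    train_real <- if (n_hold > 0) real[-hold_idx, , drop = FALSE] else real
    opt_d <- make_optimizer("sgd", lr = spec$learning_rate)
    opt_g <- make_optimizer("sgd", lr = spec$learning_rate)
    n <- nrow(train_real)
    bs <- spec$batch_size
    if (spec$epochs > 0L) {
      hist <- data.frame(epoch = seq_len(spec$epochs), d_loss = NA_real_,
                         g_loss = NA_real_)
      step <- 0L
      for (ep in seq_len(spec$epochs)) {
        ord <- sample.int(n)
        dl <- gl <- 0; nb <- 0L
        for (start in seq(1L, n - bs + 1L, by = bs)) {
          idx <- ord[start:(start + bs - 1L)]
          xb <- t(train_real[idx, , drop = FALSE])
          # --- discriminator step ---
          z <- matrix(stats::runif(spec$latent_dim * bs, -1, 1), spec$latent_dim, bs)
          gfw <- generator_forward(gen, z)
          dfr <- discriminator_forward(disc, xb, training = TRUE)
          dff <- discriminator_forward(disc, gfw$out, training = TRUE)
          losses <- gan_losses(dfr$p, dff$p, spec$generator_loss)
          # d_loss = -mean log p_real - mean log(1-p_fake)
          dp_real <- -1 / (dfr$p * bs)
          dp_fake <- 1 / ((1 - dff$p) * bs)
          gr <- discriminator_backward(disc, dp_real, dfr$caches)$grads
          gf <- discriminator_backward(disc, dp_fake, dff$caches)$grads
          dgrads <- mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                           gr, gf, SIMPLIFY = FALSE)
          dl_layers <- lapply(seq_along(disc$layers), function(i) disc$layers[[i]]$dense)
          dl_layers <- layers_update(dl_layers, dgrads, opt_d, prefix = "d")
          for (i in seq_along(disc$layers)) disc$layers[[i]]$dense <- dl_layers[[i]]
          step <- step + 1L
          # --- generator step every k_disc discriminator steps ---
          if (step %% spec$k_disc == 0L) {
            z <- matrix(stats::runif(spec$latent_dim * bs, -1, 1), spec$latent_dim, bs)
            gfw <- generator_forward(gen, z)
            dff <- discriminator_forward(disc, gfw$out, training = TRUE)
            dp <- if (spec$generator_loss == "non_saturating")
              -1 / (dff$p * bs) else -1 / ((1 - dff$p) * bs)
            dx <- discriminator_backward(disc, dp, dff$caches)$dx
            ggrads <- generator_backward(gen, dx, gfw$caches)
            gen$layers <- layers_update(gen$layers, ggrads, opt_g, prefix = "g")
          }
          dl <- dl + losses$d_loss; gl <- gl + losses$g_loss; nb <- nb + 1L
        }
        hist$d_loss[ep] <- dl / max(nb, 1L)
        hist$g_loss[ep] <- gl / max(nb, 1L)
        if (verbose && ep %% 10L == 0L)
          message(sprintf("gan epoch %3d  d_loss %.4f g_loss %.4f",
                          ep, hist$d_loss[ep], hist$g_loss[ep]))
      }
    }
    # held-out real/fake discrimination accuracy
    disc_acc <- NA_real_
    if (n_hold > 0) {
      xh <- t(real[hold_idx, , drop = FALSE])
      fake <- t(simulate.gan_generator(gen, n_hold, seed = derive_seed(seed, "holdout")))
      ph <- discriminator_forward(disc, xh)$p
      pf <- discriminator_forward(disc, fake)$p
      disc_acc <- mean(c(ph >= 0.5, pf < 0.5))
    }
    structure(list(generator = gen, discriminator = disc,
                   history = hist %||% data.frame(epoch = integer(0),
                                                  d_loss = numeric(0),
                                                  g_loss = numeric(0)),
                   disc_accuracy = disc_acc, spec = spec,
                   seed = as.integer(seed)),
              class = "fatigue_gan")
  })
}

#' @export
print.fatigue_gan <- function(x, ...) {
  cat(sprintf("<fatigue_gan> latent %d -> signal %d; %d training epochs\n",
              x$spec$latent_dim, x$generator$out_len, nrow(x$history)))
  if (nrow(x$history))
    cat(sprintf("  final d_loss %.4f g_loss %.4f; held-out disc accuracy %s\n",
                utils::tail(x$history$d_loss, 1), utils::tail(x$history$g_loss, 1),
                format(x$disc_accuracy, digits = 3)))
  invisible(x)
}

#' @export
plot.fatigue_gan <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop_arg("no training history to plot")
  graphics::plot(h$epoch, h$d_loss, type = "l", xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$d_loss, h$g_loss), finite = TRUE), ...)
  graphics::lines(h$epoch, h$g_loss, lty = 2)
  graphics::legend("topright", c("discriminator", "generator"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Augment an epoch dataset with generated epochs
#'
#' Grows the dataset to `target_total` epochs by sampling class-conditional
#' generators, preserving class proportions; generated epochs are flagged
#' `synthetic` and real epochs are never modified.
#'
#' @param ds an `epoch_dataset`.
#' @param generators named list mapping class label (as character) to a
#'   `gan_generator`/`fatigue_gan` whose output length equals
#'   `channels * samples` of `ds`.
#' @param target_total desired total epoch count (>= current size).
#' @param seed integer seed.
#' @return the augmented `epoch_dataset`.
#' @export
augment_dataset <- function(ds, generators, target_total, seed = 1) {
  if (!inherits(ds, "epoch_dataset")) stop_arg("`ds` must be an epoch_dataset")
  n <- length(ds)
  if (target_total < n)
    stop_arg("target_total (%d) is smaller than the dataset (%d)", target_total, n)
  if (target_total == n) return(ds)
  C <- dim(ds$x)[2L]; L <- dim(ds$x)[3L]
  extra <- target_total - n
  classes <- sort(unique(ds$labels))
  # proportional allocation, largest remainders first
  prop <- as.numeric(table(factor(ds$labels, classes))) / n
  alloc <- floor(prop * extra)
  rem <- extra - sum(alloc)
  if (rem > 0) {
    o <- order(prop * extra - alloc, decreasing = TRUE)
    alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1L
  }
  new_x <- array(0, c(extra, C, L))
  new_lab <- integer(extra)
  pos <- 0L
  for (j in seq_along(classes)) {
    if (alloc[j] == 0L) next
    g <- generators[[as.character(classes[j])]]
    if (is.null(g)) stop_arg("no generator supplied for class %s", classes[j])
    if (inherits(g, "fatigue_gan")) g <- g$generator
    if (g$out_len != C * L)
      stop_arg("generator for class %s emits length %d, need %d",
               classes[j], g$out_len, C * L)
    sm <- simulate.gan_generator(g, alloc[j],
                                 seed = derive_seed(seed, paste0("aug", classes[j])))
    for (i in seq_len(alloc[j])) {
      new_x[pos + i, , ] <- matrix(sm[i, ], C, L)
    }
    new_lab[pos + seq_len(alloc[j])] <- classes[j]
    pos <- pos + alloc[j]
  }
  epoch_dataset(
    x = abind_first(ds$x, new_x),
    labels = c(ds$labels, new_lab),
    channels = ds$channels, fs = ds$fs,
    provenance = c(ds$provenance, "gan_augment"),
    synthetic = c(ds$synthetic, rep(TRUE, extra)))
}

# bind two (n, C, L) arrays along the first margin
abind_first <- function(a, b) {
  out <- array(0, c(dim(a)[1L] + dim(b)[1L], dim(a)[2L], dim(a)[3L]))
  out[seq_len(dim(a)[1L]), , ] <- a
  out[dim(a)[1L] + seq_len(dim(b)[1L]), , ] <- b
  out
}

#' Save / load GAN checkpoints
#'
#' Single-file RDS checkpoint embedding the `gan_spec`.
#'
#' @param gan a `fatigue_gan`.
#' @param path file path.
#' @export
save_gan <- function(gan, path) { saveRDS(gan, path, version = 2); invisible(path) }

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "fatigue_gan")) stop_arg("not a fatigue_gan checkpoint")
  g
}
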