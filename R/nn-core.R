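# Minimal 1-D neural-network core used by both the GAN and the CNN.
#
# Tensors flow through conv layers as 3-D arrays dim = (channels, length,
# batch); dense layers see (features, batch) matrices. All heavy lifting is
# BLAS matrix products (conv via im2col). Every layer is a plain list with a
# $type, learnable $params, and a matching $grads slot filled by backward().

# ---- layer constructors ----------------------------------------------------

nn_conv1d <- function(in_ch, out_ch, kernel, stride,
                      init = c("he", "filterbank"), fs = 250) {
  init <- match.arg(init)
  fan_in <- in_ch * kernel
  if (init == "filterbank") {
    # windowed-sinusoid atoms log-spaced over the EEG range (1.5-45 Hz),
    # alternating cosine/sine phase; learnable like any other weights
    freqs <- exp(seq(log(1.5), log(45), length.out = out_ch))
    t <- (seq_len(kernel) - (kernel + 1) / 2) / fs
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = kernel))
    W <- matrix(0, out_ch, fan_in)
    for (i in seq_len(out_ch)) {
      atom <- w * cos(2 * pi * freqs[i] * t + (i %% 2) * pi / 2)
      atom <- atom / sqrt(sum(atom^2))
      # replicate the temporal atom across input channels (scaled down)
      W[i, ] <- rep(atom, each = in_ch) / sqrt(in_ch)
    }
    W <- W + matrix(stats::rnorm(out_ch * fan_in, sd = 0.01), out_ch, fan_in)
  } else {
    W <- matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)), out_ch, fan_in)
  }
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = stride, params = list(W = W, b = numeric(out_ch)))
}

nn_dense <- function(in_dim, out_dim, act = c("linear", "leaky_relu", "sigmoid")) {
  act <- match.arg(act)
  sdv <- if (act == "leaky_relu") sqrt(2 / in_dim) else sqrt(1 / in_dim)
  W <- matrix(stats::rnorm(out_dim * in_dim, sd = sdv), out_dim, in_dim)
  list(type = "dense", act = act, in_dim = in_dim, out_dim = out_dim,
       params = list(W = W, b = numeric(out_dim)))
}

nn_activation <- function(kind = c("t2f", "relu", "leaky_relu"), channels,
                          leaky_slope = 0.01) {
  kind <- match.arg(kind)
  params <- list()
  if (kind == "t2f") {
    # raw scale: a = exp(0) = 1, delta = 0.99*sigma(-2) ~ 0.118, alpha = 0.5
    params <- list(a_raw = numeric(channels),
                   d_raw = rep(-2, channels),
                   b_raw = numeric(channels))
  }
  list(type = "activation", kind = kind, channels = channels,
       leaky_slope = leaky_slope, params = params)
}

nn_maxpool <- function(size = 2L, stride = 2L) {
  stopifnot(size == 2L, stride == 2L)
  list(type = "maxpool", size = 2L, stride = 2L, params = list())
}

nn_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", channels = channels, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       running_mean = numeric(channels), running_var = rep(1, channels))
}

nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate, params = list())
}

# ---- shape arithmetic ------------------------------------------------------

conv_out_len <- function(input_len, stride) as.integer(ceiling(input_len / stride))
pool_out_len <- function(input_len, stride) as.integer(floor(input_len / stride))

# ---- forward / backward ----------------------------------------------------

# x: (Ci, Lin, B) -> (Co, Lout, B)
conv1d_forward <- function(layer, x) {
  d <- dim(x); Ci <- d[1L]; Lin <- d[2L]; B <- d[3L]
  k <- layer$kernel; s <- layer$stride
  Lout <- conv_out_len(Lin, s)
  pad_total <- max(0L, (Lout - 1L) * s + k - Lin)
  pl <- pad_total %/% 2L
  Lp <- Lin + pad_total
  xpad <- array(0, c(Ci, Lp, B))
  xpad[, (pl + 1L):(pl + Lin), ] <- x
  base <- (0:(Lout - 1L)) * s
  Xcol <- array(0, c(Ci, k, Lout, B))
  for (j in seq_len(k)) Xcol[, j, , ] <- xpad[, base + j, , drop = FALSE]
  dim(Xcol) <- c(Ci * k, Lout * B)
  Y <- layer$params$W %*% Xcol + layer$params$b
  dim(Y) <- c(layer$out_ch, Lout, B)
  list(out = Y, cache = list(Xcol = Xcol, dims = d, Lout = Lout, Lp = Lp,
                             pl = pl, base = base))
}

conv1d_backward <- function(layer, dout, cache) {
  d <- cache$dims; Ci <- d[1L]; Lin <- d[2L]; B <- d[3L]
  k <- layer$kernel
  Lout <- cache$Lout
  dim(dout) <- c(layer$out_ch, Lout * B)
  dW <- dout %*% t(cache$Xcol)
  db <- rowSums(dout)
  dXcol <- crossprod(layer$params$W, dout)      # (Ci*k) x (Lout*B)
  dim(dXcol) <- c(Ci, k, Lout, B)
  dxpad <- array(0, c(Ci, cache$Lp, B))
  base <- cache$base
  for (j in seq_len(k)) {
    sl <- dXcol[, j, , , drop = FALSE]
    dim(sl) <- c(Ci, Lout, B)
    dxpad[, base + j, ] <- dxpad[, base + j, , drop = FALSE] + sl
  }
  dx <- dxpad[, (cache$pl + 1L):(cache$pl + Lin), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

dense_forward <- function(layer, x) {
  Z <- layer$params$W %*% x + layer$params$b
  out <- switch(layer$act,
    linear = Z,
    leaky_relu = ifelse(Z > 0, Z, 0.01 * Z),
    sigmoid = sigmoid(Z))
  list(out = out, cache = list(x = x, Z = Z, out = out))
}

dense_backward <- function(layer, dout, cache) {
  dZ <- switch(layer$act,
    linear = dout,
    leaky_relu = dout * ifelse(cache$Z > 0, 1, 0.01),
    sigmoid = dout * cache$out * (1 - cache$out))
  list(dx = crossprod(layer$params$W, dZ),
       grads = list(W = dZ %*% t(cache$x), b = rowSums(dZ)))
}

activation_forward <- function(layer, x) {
  d <- dim(x)
  if (layer$kind == "t2f") {
    xm <- matrix(x, d[1L])
    r <- t2f_forward_raw(xm, layer$params$a_raw, layer$params$d_raw,
                         layer$params$b_raw)
    out <- r$out; dim(out) <- d
    return(list(out = out, cache = c(r["cache"], list(dims = d))))
  }
  if (layer$kind == "relu") {
    return(list(out = pmax(x, 0), cache = list(x = x)))
  }
  list(out = ifelse(x > 0, x, layer$leaky_slope * x), cache = list(x = x))
}

activation_backward <- function(layer, dout, cache) {
  if (layer$kind == "t2f") {
    d <- cache$dims
    dm <- matrix(dout, d[1L])
    r <- t2f_backward_raw(dm, cache$cache)
    dx <- r$dx; dim(dx) <- d
    return(list(dx = dx,
                grads = list(a_raw = r$ga, d_raw = r$gd, b_raw = r$gb)))
  }
  if (layer$kind == "relu") {
    return(list(dx = dout * (cache$x > 0), grads = list()))
  }
  list(dx = dout * ifelse(cache$x > 0, 1, layer$leaky_slope), grads = list())
}

maxpool_forward <- function(layer, x) {
  d <- dim(x); L <- d[2L]
  Lout <- pool_out_len(L, 2L)
  i1 <- seq.int(1L, 2L * Lout, 2L)
  x1 <- x[, i1, , drop = FALSE]
  x2 <- x[, i1 + 1L, , drop = FALSE]
  m1 <- x1 >= x2
  list(out = pmax(x1, x2), cache = list(m1 = m1, dims = d, Lout = Lout, i1 = i1))
}

maxpool_backward <- function(layer, dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  dx[, cache$i1, ] <- dout * cache$m1
  dx[, cache$i1 + 1L, ] <- dout * !cache$m1
  list(dx = dx, grads = list())
}

batchnorm_forward <- function(layer, x, training) {
  d <- dim(x); C <- d[1L]
  xm <- matrix(x, C)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    xc <- xm - mu
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- xc * inv
  out <- layer$params$gamma * xhat + layer$params$beta
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, xc = xc, inv = inv, dims = d,
                    training = training),
       batch_mean = if (training) mu else NULL,
       batch_var = if (training) v else NULL)
}

batchnorm_backward <- function(layer, dout, cache) {
  d <- cache$dims; C <- d[1L]
  dm <- matrix(dout, C)
  N <- ncol(dm)
  dgamma <- rowSums(dm * cache$xhat)
  dbeta <- rowSums(dm)
  dxhat <- dm * layer$params$gamma
  if (cache$training) {
    # standard batch-norm backward, per channel over the (length x batch) axis
    dx <- (cache$inv / N) *
      (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dxhat * cache$inv
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

dropout_forward <- function(layer, x, training) {
  if (!training || layer$rate == 0) return(list(out = x, cache = list(mask = NULL)))
  keep <- 1 - layer$rate
  mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim(x) %||% length(x))
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, dout, cache) {
  if (is.null(cache$mask)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache$mask, grads = list())
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv1d = conv1d_forward(layer, x),
    dense = dense_forward(layer, x),
    activation = activation_forward(layer, x),
    maxpool = maxpool_forward(layer, x),
    batchnorm = batchnorm_forward(layer, x, training),
    dropout = dropout_forward(layer, x, training),
    stop_arg("unknown layer type '%s'", layer$type))
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv1d = conv1d_backward(layer, dout, cache),
    dense = dense_backward(layer, dout, cache),
    activation = activation_backward(layer, dout, cache),
    maxpool = maxpool_backward(layer, dout, cache),
    batchnorm = batchnorm_backward(layer, dout, cache),
    dropout = dropout_backward(layer, dout, cache),
    stop_arg("unknown layer type '%s'", layer$type))
}

# softmax over columns of a (K, B) matrix, numerically stabilized
softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2L, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(E), ncol(E), byrow = TRUE)
}

# cross-entropy loss and gradient for one-hot labels y (integer in 1..K)
softmax_xent <- function(Z, y) {
  P <- softmax_cols(Z)
  B <- ncol(Z)
  idx <- cbind(y, seq_len(B))
  eps <- 1e-12
  loss <- -mean(log(pmax(P[idx], eps)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, probs = P, dZ = dZ / B)
}

# ---- optimizers ------------------------------------------------------------

#' @noRd
make_optimizer <- function(name = c("adadelta", "rmsprop", "sgd", "adam", "adamax"),
                           lr = 0.001, momentum = 0, rho = NULL, eps = NULL) {
  name <- match.arg(name)
  rho <- rho %||% switch(name, adadelta = 0.95, rmsprop = 0.9, 0.9)
  eps <- eps %||% switch(name, adadelta = 1e-6, 1e-8)
  e <- new.env(parent = emptyenv())
  list(name = name, lr = lr, momentum = momentum, rho = rho, eps = eps,
       beta1 = 0.9, beta2 = 0.999, state = e, t = 0)
}

opt_step <- function(opt, key, param, grad) {
  st <- opt$state[[key]]
  upd <- switch(opt$name,
    sgd = {
      if (opt$momentum > 0) {
        v <- if (is.null(st)) grad * 0 else st$v
        v <- opt$momentum * v - opt$lr * grad
        opt$state[[key]] <- list(v = v)
        v
      } else -opt$lr * grad
    },
    rmsprop = {
      Eg <- if (is.null(st)) grad * 0 else st$Eg
      Eg <- opt$rho * Eg + (1 - opt$rho) * grad^2
      opt$state[[key]] <- list(Eg = Eg)
      -opt$lr * grad / (sqrt(Eg) + opt$eps)
    },
    adadelta = {
      if (is.null(st)) st <- list(Eg = grad * 0, Ed = grad * 0)
      Eg <- opt$rho * st$Eg + (1 - opt$rho) * grad^2
      dx <- -sqrt(st$Ed + opt$eps) / sqrt(Eg + opt$eps) * grad
      Ed <- opt$rho * st$Ed + (1 - opt$rho) * dx^2
      opt$state[[key]] <- list(Eg = Eg, Ed = Ed)
      opt$lr * dx
    },
    adam = , adamax = {
      if (is.null(st)) st <- list(m = grad * 0, v = grad * 0, t = 0)
      t <- st$t + 1
      m <- opt$beta1 * st$m + (1 - opt$beta1) * grad
      if (opt$name == "adam") {
        v <- opt$beta2 * st$v + (1 - opt$beta2) * grad^2
        mhat <- m / (1 - opt$beta1^t)
        vhat <- v / (1 - opt$beta2^t)
        opt$state[[key]] <- list(m = m, v = v, t = t)
        -opt$lr * mhat / (sqrt(vhat) + opt$eps)
      } else {
        v <- pmax(opt$beta2 * st$v, abs(grad))
        opt$state[[key]] <- list(m = m, v = v, t = t)
        -opt$lr * (m / (1 - opt$beta1^t)) / (v + opt$eps)
      }
    })
  param + upd
}

# Apply one optimizer step to every learnable parameter of a layer list.
layers_update <- function(layers, grads_list, opt, prefix = "") {
  for (i in seq_along(layers)) {
    g <- grads_list[[i]]
    if (length(g) == 0L) next
    for (nm in names(g)) {
      key <- paste0(prefix, i, ".", nm)
      layers[[i]]$params[[nm]] <-
        opt_step(opt, key, layers[[i]]$params[[nm]], g[[nm]])
    }
  }
  layers
}
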