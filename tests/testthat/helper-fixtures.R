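# Shared fixtures, built in code and memoized within a test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small labeled recording set + preprocessed epochs (3 levels, 6 per level)
tiny_recording_set <- function() memo("tiny_rset",
  generate_dataset(6, levels = c(0, 2, 4), epoch_len_s = 15, seed = 401))

tiny_epochs <- function() memo("tiny_epochs",
  preprocess_dataset(tiny_recording_set()))

# random epoch dataset with short signals, for unit tests of the network
# machinery where realistic EEG content is irrelevant
toy_dataset <- function(n_per_class = 10, n_classes = 2, C = 2, L = 64,
                        seed = 77, sep = 3) {
  withr::with_seed(seed, {
    n <- n_per_class * n_classes
    x <- array(stats::rnorm(n * C * L), c(n, C, L))
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    # shift class means so the toy problem is separable
    for (k in seq_len(n_classes)) x[labels == k - 1L, , ] <-
      x[labels == k - 1L, , ] + (k - 1L) * sep
    epoch_dataset(x, labels, paste0("ch", seq_len(C)), fs = 250)
  })
}

# a small architecture (2 blocks) for fast network unit tests
toy_arch <- function(n_classes = 2, activation = "relu", C = 2, L = 64,
                     dropout = 0) {
  arch_spec(n_classes = n_classes, input_len = L, in_channels = C,
            activation = activation, filters = c(4, 6), kernels = c(16, 3),
            strides = c(4, 1), dropout = dropout, first_init = "he")
}

# sinusoid-family epochs used by the GAN distribution test
sine_family <- function(n = 64, L = 128, fs = 64, seed = 1) {
  withr::with_seed(seed, {
    t(replicate(n, minmax01(
      stats::runif(1, 0.8, 1.2) * sin(2 * pi * 8 * seq_len(L) / fs +
                                        stats::runif(1, 0, 2 * pi)) +
        0.1 * stats::rnorm(L))))
  })
}
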