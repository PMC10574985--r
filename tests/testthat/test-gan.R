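# GAN module: structural contracts, closed-form losses, scaled-down
# training behaviour, and dataset augmentation.

test_that("default generator maps a 100-d latent to a 3750-sample signal", {
  gen <- build_generator(gan_spec(), seed = 1)
  z <- matrix(stats::runif(100 * 2, -1, 1), 100, 2)
  out <- fatiguenet:::generator_forward(gen, z)$out
  expect_identical(dim(out), c(3750L, 2L))
  expect_true(all(out > 0 & out < 1))
  # wrong latent length is a shape error
  expect_error(fatiguenet:::generator_forward(gen, matrix(0, 99, 1)))
  # same latent, same weights: identical output
  out2 <- fatiguenet:::generator_forward(gen, z)$out
  expect_identical(out, out2)
  # sampled draws are seed-deterministic
  expect_identical(simulate(gen, 2, seed = 4), simulate(gen, 2, seed = 4))
})

test_that("discriminator has five dense layers with dropout at 1 and 3", {
  disc <- build_discriminator(gan_spec(), seed = 2)
  expect_length(disc$layers, 5L)
  has_drop <- vapply(disc$layers, function(l) !is.null(l$dropout), TRUE)
  expect_identical(which(has_drop), c(1L, 3L))
  x <- matrix(stats::runif(3750 * 3), 3750, 3)
  p <- fatiguenet:::discriminator_forward(disc, x)$p
  expect_length(p, 3L)
  expect_true(all(p > 0 & p < 1))
  expect_error(fatiguenet:::discriminator_forward(disc, matrix(0, 100, 1)))
})

test_that("adversarial losses match their closed forms", {
  l <- gan_losses(0.5, 0.5)
  expect_equal(l$d_loss, 2 * log(2), tolerance = 1e-9)
  expect_equal(l$g_loss, log(2), tolerance = 1e-9)           # non-saturating at 1/2
  expect_equal(gan_losses(0.5, 0.5, "saturating")$g_loss, -log(2), tolerance = 1e-9)
  # perfect-discrimination limit drives the loss to zero
  eps <- 1e-6
  expect_lt(gan_losses(1 - eps, eps)$d_loss, 1e-5)
  # values at exactly 0/1 are clamped, not an error
  expect_true(is.finite(gan_losses(1, 0)$d_loss))
  expect_error(gan_losses(1.2, 0.5), "probabilities")
  # batch means: vectorized inputs
  expect_equal(gan_losses(c(0.5, 0.5), c(0.25, 0.75))$d_loss,
               2 * log(2) - mean(log(c(0.75, 0.25))) - log(2), tolerance = 1e-9)
})

test_that("scaled-down GAN training pulls generated band power toward the real distribution", {
  fs <- 64; L <- 128
  real <- sine_family(n = 64, L = L, fs = fs, seed = 1)
  sp <- gan_spec(latent_dim = 16, generator_dims = c(32, 64, L),
                 discriminator_dims = c(64, 32, 16, 8, 1),
                 batch_size = 8, learning_rate = 0.1, epochs = 600)
  bp <- function(m) apply(m, 1, function(x) band_power(x, fs, c(6, 10)))
  # untrained baseline: generated and real band powers are far apart
  g0 <- train_gan(real, gan_spec(latent_dim = 16, generator_dims = c(32, 64, L),
                                 discriminator_dims = c(64, 32, 16, 8, 1),
                                 epochs = 0), seed = 5)
  ks0 <- suppressWarnings(stats::ks.test(bp(real), bp(simulate(g0, 64, seed = 6)))$statistic)
  gan <- train_gan(real, sp, seed = 5)
  ks1 <- suppressWarnings(stats::ks.test(bp(real), bp(simulate(gan, 64, seed = 6)))$statistic)
  expect_lt(ks1, 0.7)
  expect_lt(ks1, ks0)
  # loss history covers every epoch and is finite
  expect_identical(nrow(gan$history), 600L)
  expect_true(all(is.finite(gan$history$d_loss)))
  # seeded determinism of the full loss history
  gan2 <- train_gan(real, sp, seed = 5)
  expect_identical(gan$history, gan2$history)
})

test_that("training refuses datasets smaller than one batch", {
  sp <- gan_spec(latent_dim = 4, generator_dims = c(8, 16), batch_size = 10,
                 epochs = 1)
  expect_error(train_gan(matrix(0.5, 4, 16), sp), "batch_size")
})

test_that("augmentation reaches the target size without touching real epochs", {
  withr::with_seed(8, {
    x <- array(stats::runif(3750 * 1 * 40), c(3750, 1, 40))
  })
  ds <- epoch_dataset(x, rep(0:4, each = 750), "ch")
  tiny_gen <- function(seed) build_generator(
    gan_spec(latent_dim = 4, generator_dims = c(8, 40)), seed = seed)
  gens <- setNames(lapply(1:5, tiny_gen), as.character(0:4))
  before <- ds$x
  aug <- augment_dataset(ds, gens, 6000, seed = 3)
  expect_identical(length(aug), 6000L)
  expect_identical(sum(aug$synthetic), 2250L)            # 6000 - 3750
  expect_identical(aug$x[1:3750, , , drop = FALSE], before)
  # class proportions preserved (balanced in, balanced out)
  expect_identical(as.vector(table(aug$labels)), rep(1200L, 5L))
  expect_true("gan_augment" %in% aug$provenance)
  # boundary cases
  expect_identical(augment_dataset(ds, gens, 3750), ds)
  expect_error(augment_dataset(ds, gens, 1000), "smaller")
  expect_error(augment_dataset(ds, gens["0"], 3800), "no generator")
})

test_that("GAN checkpoints round-trip", {
  sp <- gan_spec(latent_dim = 4, generator_dims = c(8, 16),
                 discriminator_dims = c(8, 4, 3, 2, 1), batch_size = 4,
                 epochs = 2, learning_rate = 0.01)
  gan <- train_gan(matrix(stats::runif(8 * 16), 8, 16), sp, seed = 1,
                   holdout_frac = 0)
  path <- withr::local_tempfile(fileext = ".rds")
  save_gan(gan, path)
  back <- load_gan(path)
  expect_identical(back$generator$layers, gan$generator$layers)
  expect_identical(simulate(back, 3, seed = 2), simulate(gan, 3, seed = 2))
})
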