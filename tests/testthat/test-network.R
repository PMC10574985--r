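# Network module: shape arithmetic, construction, training behaviour,
# splitting and cross-validation.

test_that("layer_length implements same-padding conv and floor pooling", {
  expect_identical(layer_length(2375, list(type = "pool", stride = 2)), 1187L)
  expect_identical(layer_length(1187, list(type = "conv", stride = 1)), 1187L)
  expect_identical(layer_length(37, list(type = "pool", stride = 2)), 18L)
  expect_identical(layer_length(47500, list(type = "conv", stride = 20)), 2375L)
  expect_error(layer_length(0, list(type = "conv", stride = 1)), "input_len")
  expect_error(layer_length(10, list(type = "dense")), "conv")
})

test_that("built models expose the expected shapes and parameter counts", {
  arch <- toy_arch()
  m <- build_cnn(arch, seed = 1)
  expect_s3_class(m, "fatigue_cnn")
  # forward pass shape
  x <- array(stats::rnorm(2 * 64 * 3), c(2, 64, 3))
  fw <- fatiguenet:::cnn_forward(m, x)
  expect_identical(dim(fw$logits), c(2L, 3L))
  # softmax normalization
  P <- fatiguenet:::softmax_cols(fw$logits)
  expect_equal(colSums(P), rep(1, 3), tolerance = 1e-6)
  # activation parameter accounting
  expect_identical(n_activation_params(arch_spec(activation = "t2f")), 1104L)
  expect_identical(n_activation_params(arch_spec(activation = "relu")), 0L)
  expect_identical(n_activation_params(toy_arch(activation = "t2f")), 3L * (4L + 6L))
  expect_error(arch_spec(n_classes = 4), "n_classes")
})

test_that("weight initialization is seed-deterministic", {
  m1 <- build_cnn(toy_arch(), seed = 5)
  m2 <- build_cnn(toy_arch(), seed = 5)
  m3 <- build_cnn(toy_arch(), seed = 6)
  expect_identical(m1$layers, m2$layers)
  expect_false(identical(m1$layers, m3$layers))
})

test_that("training fits separable toy data and is reproducible", {
  ds <- toy_dataset(n_per_class = 20, n_classes = 2)
  sp <- split_dataset(ds, seed = 3)
  cfg <- train_config(optimizer = "adam", learning_rate = 0.01,
                      max_epochs = 10)
  fit <- train_classifier(sp$train, sp$validation, toy_arch(dropout = 0.1),
                          cfg, seed = 11)
  expect_gte(utils::tail(fit$history$train_acc, 1), 0.95)
  expect_identical(nrow(fit$history), 10L)
  pred <- predict(fit, sp$test)
  expect_gte(mean(pred == sp$test$labels), 0.9)
  # reproducibility of the whole history
  fit2 <- train_classifier(sp$train, sp$validation, toy_arch(dropout = 0.1),
                           cfg, seed = 11)
  expect_identical(fit$history, fit2$history)
  # probability predictions are normalized rows
  P <- predict(fit, sp$test, type = "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("zero-epoch training returns an untrained model with empty history", {
  ds <- toy_dataset(n_per_class = 5)
  fit <- train_classifier(ds, NULL, toy_arch(),
                          train_config(max_epochs = 0), seed = 1)
  expect_false(fit$trained)
  expect_identical(nrow(fit$history), 0L)
  expect_error(train_classifier(fatiguenet:::ds_subset(ds, integer(0)), NULL, toy_arch(),
                                train_config(max_epochs = 1)), "empty")
})

test_that("coef extracts one constrained triple per activation channel", {
  fit <- build_cnn(toy_arch(activation = "t2f"), seed = 2)
  co <- coef(fit)
  expect_identical(nrow(co), 10L)            # 4 + 6 channels
  expect_true(all(co$a > 0))
  expect_true(all(co$delta >= 0 & co$delta < 1))
  expect_true(all(co$alpha >= 0 & co$alpha <= 1))
  expect_error(coef(build_cnn(toy_arch(activation = "relu"))), "no learnable")
})

test_that("split_dataset partitions exhaustively, disjointly, stratified", {
  ds <- toy_dataset(n_per_class = 30, n_classes = 2)
  sp <- split_dataset(ds, seed = 9)
  expect_identical(length(sp$train), 42L)     # 70% of 60
  expect_identical(length(sp$validation), 6L)
  expect_identical(length(sp$test), 12L)
  # stratification: each split balanced
  for (part in sp) expect_identical(as.vector(table(part$labels)),
                                    rep(as.integer(length(part) / 2), 2L))
  expect_error(split_dataset(ds, fractions = c(0.7, 0.2, 0.2)), "summing to 1")
  # 6000-epoch arithmetic of the 70/10/20 split
  big <- epoch_dataset(array(0, c(6000, 1, 2)), rep(0:4, 1200), "ch")
  spb <- split_dataset(big, seed = 1)
  expect_identical(vapply(spb, length, 0L),
                   c(train = 4200L, validation = 600L, test = 1200L))
})

test_that("k-fold folds are disjoint, exhaustive, and above chance on easy data", {
  ds <- toy_dataset(n_per_class = 25, n_classes = 2)
  cv <- kfold_cv(ds, k = 5, toy_arch(dropout = 0),
                 train_config(optimizer = "adam", learning_rate = 0.01,
                              max_epochs = 5), seed = 13)
  expect_identical(as.vector(table(cv$folds)), rep(10L, 5L))
  expect_identical(sort(unlist(lapply(1:5, function(f) which(cv$folds == f)))),
                   1:50)
  expect_true(all(cv$fold_accuracy > 0.5))
  expect_identical(sum(vapply(cv$reports, function(r) r$n, 0)), 50)
  expect_error(kfold_cv(ds, k = 1), "k")
})

test_that("non-finite training loss raises a diagnostic error", {
  ds <- toy_dataset(n_per_class = 6)
  ds$x[1, 1, 1] <- NaN
  cfg <- train_config(optimizer = "sgd", learning_rate = 0.01, max_epochs = 2)
  expect_error(train_classifier(ds, NULL, toy_arch(), cfg, seed = 2),
               "diverged")
})
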