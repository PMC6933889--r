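test_that("closed-form parameter count matches the actual weight count", {
  expect_equal(count_parameters(model_spec(L = 400L)), 2002253L)
  expect_equal(count_parameters(model_spec(L = 4L, kernels = 1L,
                                           kernel_size = 1L, fc_units = 1L,
                                           n_classes = 2L)), 14L)
  # 2-class variant differs only in the output layer: 303 -> 202
  expect_equal(count_parameters(model_spec(L = 400L)) -
                 count_parameters(model_spec(L = 400L, n_classes = 2L)),
               303L - 202L)
  # property: closed form equals the built model's element count
  set.seed(7)
  for (i in 1:8) {
    spec <- model_spec(L = 2L * sample(5:40, 1), kernels = sample(1:8, 1),
                       kernel_size = sample(1:7, 1),
                       fc_units = sample(1:30, 1),
                       n_classes = sample(2:3, 1))
    m <- build_model(spec, seed = i)
    expect_equal(count_parameters(spec),
                 sum(vapply(m$params, length, integer(1))))
  }
})

test_that("invalid specifications are rejected", {
  expect_error(model_spec(L = 8, kernel_size = 9), "kernel_size")
  expect_error(model_spec(stride = 2), "stride")
  expect_error(model_spec(dropout_rate = 1), "dropout_rate")
  expect_error(model_spec(L = 21), "even")
})

test_that("probabilities are softmax-normalized and deterministic", {
  m <- build_model(tiny_spec(), seed = 3)
  seqs <- c(random_seqs(10, 20, seed = 1), random_seqs(1, 20, seed = 1)[1])
  p <- predict_proba(m, seqs)
  expect_equal(rowSums(p), rep(1, 11), tolerance = 1e-10)
  expect_equal(dim(p), c(11L, 3L))
  expect_identical(colnames(p), c("acceptor", "donor", "non_splice"))
  # duplicated input row -> equal output rows (up to BLAS summation order);
  # repeated calls are bitwise identical
  expect_equal(p[11, ], p[1, ], tolerance = 1e-12)
  expect_identical(predict_proba(m, seqs), p)
})

test_that("training history has one row per epoch and the loss decreases", {
  ds <- learnable_dataset(n_per_class = 25, L = 20, seed = 2)
  cfg1 <- train_config(epochs = 1L, batch_size = 10L, seed = 5,
                       learning_rate = 2e-3)
  m1 <- train_model(build_model(tiny_spec(), seed = 5), ds, NULL, cfg1)
  expect_equal(nrow(m1$history), 1L)
  cfg <- train_config(epochs = 25L, batch_size = 10L, seed = 5,
                      learning_rate = 2e-3)
  m <- train_model(build_model(tiny_spec(), seed = 5), ds, NULL, cfg)
  expect_equal(nrow(m$history), 25L)
  # same seed: epoch 1 of the long run matches the 1-epoch run
  expect_equal(m$history$train_loss[1], m1$history$train_loss[1])
  # learnable signal: final loss below epoch-1 loss
  expect_lt(m$history$train_loss[25], m$history$train_loss[1])
  expect_gt(m$history$train_acc[25], 0.95)
})

test_that("shuffled labels give chance-level validation accuracy", {
  set.seed(11)
  n <- 360
  w <- fake_windows(random_seqs(n, 20, seed = 11),
                    sample(rep(c("acceptor", "donor", "non_splice"),
                               n / 3)))
  ds <- splicescan:::.new_dataset(w, 20L)
  wv <- fake_windows(random_seqs(450, 20, seed = 12),
                     sample(rep(c("acceptor", "donor", "non_splice"), 150)))
  val <- splicescan:::.new_dataset(wv, 20L)
  cfg <- train_config(epochs = 4L, batch_size = 20L, seed = 11,
                      learning_rate = 1e-3)
  m <- train_model(build_model(tiny_spec(), seed = 11), ds, val, cfg)
  expect_equal(m$history$val_acc[4], 1 / 3, tolerance = 0.05 * 3)
})

test_that("training labels outside the model's label order error", {
  w <- fake_windows(random_seqs(4, 20), rep("weird", 4))
  ds <- splicescan:::.new_dataset(w, 20L)
  m <- build_model(tiny_spec(), seed = 1)
  expect_error(train_model(m, ds, NULL, train_config(epochs = 1)),
               "data error")
})

test_that("window length mismatches are shape errors", {
  m <- build_model(tiny_spec(L = 20), seed = 1)
  expect_error(predict_proba(m, random_seqs(2, 18)), "shape error")
})

test_that("dropout masks ~30% of hidden units in training, none at inference", {
  m <- build_model(tiny_spec(L = 20), seed = 2)  # dropout_rate 0.30
  f <- splicescan:::.forward_debug(m, random_seqs(2000, 20, seed = 2),
                                   training = TRUE, seed = 7)
  expect_equal(f$n_masked / f$n_units, 0.30, tolerance = 0.05)
  f0 <- splicescan:::.forward_debug(m, random_seqs(50, 20, seed = 2),
                                    training = FALSE)
  expect_identical(f0$n_masked, 0L)
})

test_that("models round-trip through save/load with identical predictions", {
  ds <- learnable_dataset(n_per_class = 10, L = 20, seed = 3)
  cfg <- train_config(epochs = 2L, batch_size = 10L, seed = 3,
                      learning_rate = 1e-3)
  m <- train_model(build_model(tiny_spec(), seed = 3), ds, NULL, cfg)
  dir <- withr::local_tempdir()
  save_model(m, file.path(dir, "m"))
  back <- load_model(file.path(dir, "m"))
  probe <- random_seqs(8, 20, seed = 9)
  expect_identical(predict_proba(back, probe), predict_proba(m, probe))
  expect_equal(back$spec, m$spec)
  # class-count guard and missing-file error
  expect_error(load_model(file.path(dir, "m"), expect_classes = 2L),
               "class-count")
  expect_error(load_model(file.path(dir, "absent")), "not found")
})
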