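test_that("conv1d matches its definition on hand cases", {
  expect_equal(as.vector(conv1d(c(1, 2, 3, 4), c(1, 0, 0),
                                activation = "identity")),
               c(1, 2))
  # ReLU saturation: a hugely negative bias zeroes everything
  set.seed(1)
  y <- conv1d(rnorm(30L), matrix(rnorm(10L), 2L), bias = -1e6)
  expect_true(all(y == 0))
  expect_error(conv1d(1:2, c(1, 1, 1)), "shorter")
})

test_that("conv1d agrees with the nested-loop oracle on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    len <- sample(5:30, 1L)
    m <- sample(1:min(5L, len), 1L)
    nk <- sample(1:3, 1L)
    x <- rnorm(len)
    W <- matrix(rnorm(nk * m), nk, m)
    b <- rnorm(nk)
    got <- conv1d(x, W, bias = b, activation = "identity")
    expect_lt(max(abs(got - oracle_conv1d(x, W, b))), 1e-10)
  }
})

test_that("conv2d agrees with the quadruple-loop oracle and hand cases", {
  expect_equal(conv2d(matrix(1, 3, 3), matrix(1, 2, 2),
                      activation = "identity")[1:2, 1:2],
               matrix(4, 2, 2))
  set.seed(102)
  x <- matrix(rnorm(64L), 8L)
  expect_equal(conv2d(x, matrix(1), activation = "identity"), x,
               ignore_attr = TRUE)
  for (rep in 1:60) {
    h <- sample(3:9, 1L); w <- sample(3:9, 1L)
    kh <- sample(1:3, 1L); kw <- sample(1:3, 1L)
    x <- matrix(rnorm(h * w), h)
    kerns <- list(matrix(rnorm(kh * kw), kh), matrix(rnorm(kh * kw), kh))
    b <- rnorm(2L)
    got <- conv2d(x, kerns, bias = b, activation = "identity")
    for (i in 1:2) {
      expect_lt(max(abs(got[[i]] - oracle_conv2d(x, kerns[[i]], b[i]))),
                1e-10)
    }
  }
  expect_error(conv2d(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
})

test_that("multi-channel batched convolution engines match a direct sum", {
  set.seed(103)
  C <- 3L; L <- 12L; m <- 4L; M <- 2L; B <- 3L
  x <- array(rnorm(C * L * B), c(C, L, B))
  W <- matrix(rnorm(M * C * m), M, C * m)    # channel-fastest layout
  b <- rnorm(M)
  idx <- specnet:::conv1d_index(C, L, m)
  got <- specnet:::conv1d_forward(x, W, b, idx, L - m + 1L)$out
  for (bb in seq_len(B)) for (i in seq_len(M)) {
    Wk <- matrix(W[i, ], C, m)
    for (t in seq_len(L - m + 1L)) {
      expect_equal(got[i, t, bb],
                   sum(x[, t:(t + m - 1L), bb] * Wk) + b[i],
                   tolerance = 1e-10)
    }
  }
})

test_that("pooling agrees with the windowed oracle and handles w = 1", {
  expect_equal(pool(c(1, 3, 2, 8), 2L), c(3, 8))
  set.seed(104)
  v <- rnorm(17L)
  expect_equal(pool(v, 1L), v)                       # identity configuration
  for (rep in 1:40) {
    len <- sample(4:24, 1L)
    w <- sample(1:4, 1L)
    x <- rnorm(len)
    for (mode in c("max", "avg")) {
      expect_equal(pool(x, w, mode), oracle_pool(x, w, mode),
                   tolerance = 1e-12)
    }
  }
  # 2-D square pooling
  m <- matrix(c(1, 5, 2, 6, 3, 7, 4, 8, 9, 13, 10, 14, 11, 15, 12, 16), 4L)
  expect_equal(pool(m, 2L), matrix(c(7, 8, 15, 16), 2L))
  expect_error(pool(1:4, 0L), ">= 1")
})

test_that("relu is non-negative and idempotent", {
  set.seed(105)
  x <- rnorm(100L)
  expect_true(all(relu(x) >= 0))
  expect_equal(relu(relu(x)), relu(x))
})

test_that("softmax is a shift-invariant probability distribution", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  v <- c(1, 2, 3)
  expect_equal(softmax(v), exp(v) / sum(exp(v)))
  expect_equal(which.max(softmax(v)), 3L)
  set.seed(106)
  for (rep in 1:50) {
    v <- rnorm(sample(2:20, 1L), sd = 10)
    s <- softmax(v)
    expect_true(all(s > 0 & s < 1))
    expect_lt(abs(sum(s) - 1), 1e-12)
    expect_lt(max(abs(s - softmax(v + 100))), 1e-12)
    expect_equal(which.max(s), which.max(v))
  }
  expect_error(softmax(numeric(0L)), "non-empty")
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("backprop matches finite differences on tiny 1-D and 2-D models", {
  cfg <- cnn1d_config(n_stages = 1L, conv_width = 5L, pool_width = 2L,
                      feature_maps = 3L, n_classes = 3L, input_length = 30L)
  model <- build_cnn1d(cfg, seed = 2L)
  set.seed(3)
  x <- array(rnorm(30L * 4L), c(1L, 30L, 4L))
  y <- c(1L, 2L, 3L, 1L)
  chk <- specnet:::nn_gradient_check(model, x, y, n_params = 20L, seed = 4L)
  expect_lt(max(chk$rel_error), 1e-4)

  lmodel <- build_lenet(lenet_config(input_side = 18L, n_classes = 3L),
                        seed = 5L)
  set.seed(6)
  x2 <- array(rnorm(18L * 18L * 3L), c(1L, 18L, 18L, 3L))
  chk2 <- specnet:::nn_gradient_check(lmodel, x2, 1:3, n_params = 20L,
                                      seed = 7L)
  expect_lt(max(chk2$rel_error), 1e-4)
})

test_that("eval-mode forward is deterministic and outputs a distribution", {
  cfg <- cnn1d_config(n_stages = 1L, conv_width = 5L, pool_width = 2L,
                      feature_maps = 4L, n_classes = 13L, input_length = 60L)
  model <- build_cnn1d(cfg, seed = 1L)
  set.seed(2)
  x <- array(rnorm(60L * 5L), c(1L, 60L, 5L))
  p1 <- nn_predict_probs(model, x)
  p2 <- nn_predict_probs(model, x)
  expect_identical(p1, p2)                  # dropout off at inference
  expect_equal(dim(p1), c(5L, 13L))
  expect_equal(rowSums(p1), rep(1, 5L), tolerance = 1e-12)
})

test_that("shape mismatches name the offending layer", {
  cfg <- cnn1d_config(n_stages = 1L, conv_width = 5L, pool_width = 2L,
                      feature_maps = 2L, n_classes = 3L, input_length = 40L)
  model <- build_cnn1d(cfg, seed = 1L)
  expect_error(nn_forward(model, array(0, c(1L, 39L, 2L))), "conv1d")
})

test_that("a softmax-only model trains to separate linear classes", {
  set.seed(10)
  n <- 60L
  x <- cbind(matrix(rnorm(n, -2), 1L), matrix(rnorm(n, 2), 1L))
  x <- rbind(x, rnorm(2L * n, 0, 0.1))
  y <- rep(1:2, each = n)
  model <- specnet:::new_nn_model(
    list(specnet:::make_dense_layer(2L, 2L)), c(2L), 2L, arch = "softmax")
  st <- nn_train(model, x, y, x, y,
                 train_spec(batch_size = 10L, max_epochs = 30L,
                            dropout_p = 0, seed = 3L))
  acc <- mean(nn_predict(st$model, x) == y)
  expect_gt(acc, 0.95)
  # optimization made progress
  expect_lt(st$history$train_loss[nrow(st$history)], st$history$train_loss[1L])
})

test_that("early stopping returns the minimum-validation-error epoch", {
  ds <- generate_dataset(tiny_cfg(samples_per_class = 16L,
                                  train_per_class = 12L))
  dp <- preprocess_dataset(ds)
  fit <- train_cnn1d(dp, cnn1d_config(n_stages = 1L, conv_width = 5L,
                                      pool_width = 2L, feature_maps = 4L),
                     spec = train_spec(batch_size = 8L, max_epochs = 12L,
                                       patience = 3L, seed = 9L))
  h <- fit$state$history
  expect_lte(nrow(h), 12L)
  expect_equal(fit$state$best_epoch, which.min(h$val_error)[1L])
  expect_equal(fit$state$best_val_error, min(h$val_error))
  # stopped no later than patience epochs after the best epoch
  expect_lte(fit$state$epochs_run, fit$state$best_epoch + 3L)
})

test_that("training on uninformative labels stays at chance", {
  ds <- generate_dataset(tiny_cfg(separability = 0,
                                  samples_per_class = 20L,
                                  train_per_class = 15L))
  dp <- preprocess_dataset(ds)
  fit <- train_cnn1d(dp, cnn1d_config(n_stages = 1L, conv_width = 5L,
                                      pool_width = 2L, feature_maps = 4L),
                     spec = train_spec(batch_size = 8L, max_epochs = 5L,
                                       seed = 2L))
  # 3 balanced classes: chance is 1/3; anything near it passes
  expect_lt(abs(fit$report$accuracy - 100 / 3), 25)
})

test_that("a non-finite loss aborts with a diagnostic", {
  set.seed(11)
  x <- matrix(rnorm(2L * 20L), 2L)
  y <- rep(1:2, 10L)
  model <- specnet:::new_nn_model(
    list(specnet:::make_dense_layer(2L, 2L)), c(2L), 2L, arch = "softmax")
  theta <- specnet:::nn_get_params(model)
  theta[1L] <- NaN
  model <- specnet:::nn_set_params(model, theta)
  expect_error(
    nn_train(model, x, y, x, y,
             train_spec(batch_size = 5L, max_epochs = 5L,
                        dropout_p = 0, seed = 1L)),
    "non-finite")
})
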