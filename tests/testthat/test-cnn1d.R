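test_that("the depth convention counts 2 * stages + 3 layers", {
  for (s in 1:5) {
    expect_equal(cnn_depth(cnn1d_config(n_stages = s)), 2L * s + 3L)
  }
  expect_equal(cnn_depth(cnn1d_config(n_stages = 2L)), 7L)
  expect_error(cnn1d_config(n_stages = 0L), "1\\.\\.5")
  expect_error(cnn1d_config(n_stages = 6L), "1\\.\\.5")
})

test_that("shape_trace reproduces the valid-conv / floor-pool arithmetic", {
  tr <- suppressWarnings(
    shape_trace(cnn1d_config(n_stages = 1L, conv_width = 5L,
                             pool_width = 2L, feature_maps = 12L)))
  expect_equal(tr$length[tr$layer == "C1"], 1605L)
  expect_equal(tr$length[tr$layer == "S1"], 802L)     # remainder dropped
  expect_equal(tr$units[tr$layer == "FC1"], 802L * 12L)

  # default architecture: 4 stages of conv 1*15 + pool 1*2, M = 24
  tr6 <- suppressWarnings(shape_trace(cnn1d_config()))
  expect_equal(tr6$length[tr6$type == "conv"], c(1595L, 783L, 377L, 174L))
  expect_equal(tr6$length[tr6$type == "pool"], c(797L, 391L, 188L, 87L))
  expect_equal(tr6$units[tr6$layer == "FC1"], 87L * 24L)
  expect_equal(tr6$units[tr6$layer == "FC2"], 87L * 24L)
  expect_equal(tr6$units[tr6$layer == "output"], 13L)

  # boundary: kernel as wide as the input leaves one point
  tr1 <- shape_trace(cnn1d_config(n_stages = 1L, conv_width = 100L,
                                  pool_width = 1L, input_length = 100L))
  expect_equal(tr1$length[tr1$layer == "C1"], 1L)

  # non-divisible pooling warns about truncation
  expect_warning(shape_trace(cnn1d_config(n_stages = 1L, conv_width = 11L,
                                          pool_width = 2L)), "dropped")
})

test_that("FC1 size scales linearly in the number of feature maps", {
  sizes <- vapply(c(6L, 12L, 24L), function(m) {
    tr <- suppressWarnings(shape_trace(cnn1d_config(feature_maps = m)))
    tr$units[tr$layer == "FC1"]
  }, integer(1L))
  expect_equal(sizes / c(6L, 12L, 24L), rep(87, 3L))
})

test_that("trace lengths are positive and weakly decreasing across pooling", {
  for (cfg in list(cnn1d_config(), cnn1d_config(n_stages = 5L, conv_width = 5L,
                                                pool_width = 2L))) {
    tr <- suppressWarnings(shape_trace(cfg))
    len <- tr$length[!is.na(tr$length)]
    expect_true(all(len >= 1L))
    pools <- tr$length[tr$type == "pool"]
    convs <- tr$length[tr$type == "conv"]
    expect_true(all(pools <= convs))
  }
})

test_that("built models have the specified layer sequence", {
  model <- build_cnn1d(cnn1d_config(n_stages = 2L, conv_width = 5L,
                                    pool_width = 2L, feature_maps = 6L,
                                    input_length = 200L))
  types <- vapply(model$layers, function(l) l$type, character(1L))
  expect_equal(types,
               c("conv1d", "relu", "pool1d", "conv1d", "relu", "pool1d",
                 "flatten", "dense", "relu", "dropout",
                 "dense", "relu", "dropout", "dense"))
  # depth counts conv+pool+2 FC+output
  structural <- sum(types %in% c("conv1d", "pool1d", "dense"))
  expect_equal(structural, cnn_depth(model$config))
  expect_equal(nrow(model$layers[[14L]]$W), 13L)      # 13-way softmax head
  expect_error(build_cnn1d(cnn1d_config(n_stages = 5L, conv_width = 15L,
                                        pool_width = 5L)), "shorter|no output")
})

test_that("the parameter count matches the closed form", {
  cfg <- cnn1d_config(n_stages = 2L, conv_width = 7L, pool_width = 2L,
                      feature_maps = 5L, n_classes = 4L, input_length = 150L)
  model <- build_cnn1d(cfg)
  tr <- suppressWarnings(shape_trace(cfg))
  f0 <- tr$units[tr$layer == "FC1"]
  m <- cfg$conv_width; M <- cfg$feature_maps
  expected <- (M * (1L * m) + M) +          # stage 1 conv (1 input channel)
    (M * (M * m) + M) +                     # stage 2 conv
    2L * (f0 * f0 + f0) +                   # two FC layers
    (cfg$n_classes * f0 + cfg$n_classes)    # softmax head
  expect_equal(n_parameters(model), expected)
})

test_that("identical seeds give identical initial weights", {
  cfg <- cnn1d_config(n_stages = 1L, conv_width = 5L, feature_maps = 3L,
                      input_length = 50L)
  m1 <- build_cnn1d(cfg, seed = 4L)
  m2 <- build_cnn1d(cfg, seed = 4L)
  m3 <- build_cnn1d(cfg, seed = 5L)
  expect_identical(specnet:::nn_get_params(m1), specnet:::nn_get_params(m2))
  expect_false(identical(specnet:::nn_get_params(m1),
                         specnet:::nn_get_params(m3)))
})

test_that("architecture sweeps tabulate one row per value", {
  ds <- preprocess_dataset(generate_dataset(tiny_cfg(
    n_points = 64L, samples_per_class = 12L, train_per_class = 9L)))
  spec <- train_spec(batch_size = 9L, max_epochs = 2L, seed = 5L)
  base <- cnn1d_config(n_stages = 1L, conv_width = 5L, pool_width = 2L,
                       feature_maps = 4L)

  depths <- sweep_depth(ds, depths = c(5L, 7L), base_cfg = base, spec = spec)
  expect_equal(nrow(depths), 2L)
  expect_equal(depths$depth, c(5L, 7L))
  expect_equal(depths$model, c("1D_CNN_5", "1D_CNN_7"))
  expect_true(all(depths$test_accuracy >= 0 & depths$test_accuracy <= 100))
  expect_true(all(depths$train_accuracy >= 0 & depths$train_accuracy <= 100))
  expect_error(sweep_depth(ds, depths = c(6L), base_cfg = base, spec = spec),
               "2 \\* n_stages")

  kernels <- sweep_kernel(ds, values = c(3L, 15L), base_cfg = base,
                          spec = spec)
  expect_equal(kernels$conv_width, c(3L, 15L))
  expect_true(all(is.finite(kernels$test_accuracy)))

  # the identity pooling width w = 1 is a legal configuration
  pools <- sweep_pool(ds, values = c(1L, 2L), base_cfg = base, spec = spec)
  expect_equal(pools$pool_width, c(1L, 2L))

  maps <- sweep_maps(ds, values = c(2L, 4L, 6L), base_cfg = base, spec = spec)
  expect_equal(nrow(maps), 3L)
})

test_that("training is reproducible under a fixed seed", {
  ds <- preprocess_dataset(generate_dataset(tiny_cfg(
    n_points = 64L, samples_per_class = 12L, train_per_class = 9L)))
  cfg <- cnn1d_config(n_stages = 1L, conv_width = 5L, pool_width = 2L,
                      feature_maps = 4L)
  spec <- train_spec(batch_size = 9L, max_epochs = 3L, seed = 8L)
  f1 <- train_cnn1d(ds, cfg, spec = spec)
  f2 <- train_cnn1d(ds, cfg, spec = spec)
  expect_identical(f1$state$history, f2$state$history)
  expect_identical(f1$report$confusion, f2$report$confusion)
})
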