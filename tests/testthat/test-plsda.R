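test_that("perfectly separable constant classes are fit with one component", {
  x <- rbind(matrix(0, 10L, 20L), matrix(5, 10L, 20L))
  y <- rep(1:2, each = 10L)
  fit <- fit_plsda(x, y, n_components = 1L)
  expect_equal(predict_plsda(fit, x), y)
})

test_that("component counts are validated", {
  x <- matrix(rnorm(60L), 12L)
  y <- rep(1:2, 6L)
  expect_error(fit_plsda(x, y, n_components = 0L), ">= 1")
  expect_error(fit_plsda(x, y, n_components = 12L), "exceeds")
  expect_error(fit_plsda(x, rep(1L, 12L)), "2 classes")
})

test_that("the first latent weight is the dominant singular direction of X'Y", {
  set.seed(30)
  x <- matrix(rnorm(200L), 20L)
  y <- rep(1:4, each = 5L)
  fit <- fit_plsda(x, y, n_components = 2L)
  w1 <- fit$model$loadings$X[, 1L]
  Y <- stats::model.matrix(~ factor(y) - 1)
  xc <- scale(x, scale = FALSE); yc <- scale(Y, scale = FALSE)
  u1 <- svd(crossprod(xc, yc))$u[, 1L]
  expect_gt(abs(sum(w1 * u1)) / sqrt(sum(w1^2) * sum(u1^2)), 1 - 1e-8)
})

test_that("predictions are row-wise independent and shape-checked", {
  set.seed(31)
  x <- rbind(matrix(rnorm(100L, 0), 10L), matrix(rnorm(100L, 4), 10L))
  y <- rep(1:2, each = 10L)
  fit <- fit_plsda(x, y, n_components = 2L)
  pred <- predict_plsda(fit, x)
  perm <- sample(nrow(x))
  expect_equal(predict_plsda(fit, x[perm, ]), pred[perm])
  single <- predict_plsda(fit, x[3L, , drop = FALSE])
  expect_length(single, 1L)
  expect_true(single %in% 1:2)
  expect_error(predict_plsda(fit, x[, 1:5]), "features")
})

test_that("noiseless separable K-class data reach 100% with K-1 components", {
  cfg <- clean_cfg(n_classes = 4L, samples_per_class = 8L,
                   train_per_class = 6L, separability = 2)
  ds <- preprocess_dataset(generate_dataset(cfg))
  tr <- ds$split == "train"
  # zero-variance grid points make mixOmics' internal cor() warn; harmless
  fit <- suppressWarnings(
    fit_plsda(ds$absorbance[tr, ], ds$labels[tr], n_components = 3L))
  expect_equal(predict_plsda(fit, ds$absorbance[tr, ]), ds$labels[tr])
})

test_that("PCA embeddings report centered scores and variance fractions", {
  set.seed(32)
  # rank-2 data: every point a combination of two basis spectra
  basis <- matrix(rnorm(2L * 50L), 2L)
  x <- matrix(rnorm(40L), 20L) %*% basis
  emb <- embed_2d(x, "pca")
  ev <- attr(emb, "explained_variance")
  expect_equal(sum(ev), 1, tolerance = 1e-10)     # PC1+PC2 carry everything
  expect_equal(mean(emb$dim1), 0, tolerance = 1e-10)
  expect_equal(mean(emb$dim2), 0, tolerance = 1e-10)
  expect_gte(ev[1L], ev[2L])
  expect_error(embed_2d(matrix(1, 5L, 4L), "pca"), "Constant")
})

test_that("t-SNE embeddings are deterministic under a fixed seed", {
  set.seed(33)
  x <- rbind(matrix(rnorm(60L, 0), 10L), matrix(rnorm(60L, 6), 10L))
  e1 <- embed_2d(x, "tsne", seed = 5L, max_iter = 120L)
  e2 <- embed_2d(x, "tsne", seed = 5L, max_iter = 120L)
  expect_identical(e1$dim1, e2$dim1)
  expect_identical(e1$dim2, e2$dim2)
  # well-separated clusters stay separated in the embedding
  d_within <- max(dist(cbind(e1$dim1, e1$dim2)[1:10, ]))
  centroid1 <- colMeans(cbind(e1$dim1, e1$dim2)[1:10, ])
  centroid2 <- colMeans(cbind(e1$dim1, e1$dim2)[11:20, ])
  expect_gt(sqrt(sum((centroid1 - centroid2)^2)), 0)
})
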