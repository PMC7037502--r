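test_that("generated datasets honour the configured design exactly", {
  cfg <- tiny_cfg()
  ds <- generate_dataset(cfg)
  expect_s3_class(ds, "spectra_dataset")
  expect_equal(dim(ds), c(30L, 120L))
  counts <- table(ds$labels, ds$split)
  expect_true(all(counts[, "train"] == cfg$train_per_class))
  expect_true(all(counts[, "test"] ==
                    cfg$samples_per_class - cfg$train_per_class))
  expect_true(all(is.finite(ds$absorbance)))
  expect_equal(length(ds$grid), 120L)
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  a <- generate_dataset(tiny_cfg(seed = 7L))
  b <- generate_dataset(tiny_cfg(seed = 7L))
  expect_identical(a$absorbance, b$absorbance)
  expect_identical(a$labels, b$labels)
  c <- generate_dataset(tiny_cfg(seed = 8L))
  expect_false(identical(a$absorbance, c$absorbance))
})

test_that("with all stochastic components off, samples equal their template", {
  cfg <- clean_cfg()
  ds <- generate_dataset(cfg)
  for (k in 1:3) {
    tmpl <- class_template(k, cfg, ds$grid)
    rows <- ds$absorbance[ds$labels == k, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2L, tmpl))), 0)
    expect_equal(max(apply(rows, 2L, var)), 0)
  }
})

test_that("class templates follow the band + baseline construction", {
  cfg <- clean_cfg(bands_per_class = 1L, shared_band_count = 0L)
  g <- wavenumber_grid(cfg$n_points)
  x <- as.numeric(g)
  pars <- specnet:::template_params(cfg)
  for (k in 1:3) {
    b <- pars$classes[[k]][[1L]]
    expected <- specnet:::baseline_curve(x) +
      b$amplitude * exp(-(x - b$center)^2 / (2 * b$sigma^2))
    expect_equal(class_template(k, cfg, g), expected, tolerance = 1e-12)
  }
})

test_that("zero separability collapses all class templates to one", {
  cfg <- tiny_cfg(separability = 0)
  g <- wavenumber_grid(cfg$n_points)
  t1 <- class_template(1L, cfg, g)
  t3 <- class_template(3L, cfg, g)
  expect_identical(t1, t3)
})

test_that("between-class template distance grows with separability", {
  dist_at <- function(sep) {
    cfg <- tiny_cfg(separability = sep)
    g <- wavenumber_grid(cfg$n_points)
    tm <- sapply(1:3, class_template, cfg = cfg, grid = g)
    mean(dist(t(tm)))
  }
  d <- vapply(c(0.5, 1, 2), dist_at, numeric(1L))
  expect_true(all(diff(d) > 0))
})

test_that("band parameters differ between seeds but not within one", {
  p1 <- specnet:::template_params(tiny_cfg(seed = 1L))
  p2 <- specnet:::template_params(tiny_cfg(seed = 2L))
  expect_false(identical(p1$classes[[1L]][[1L]]$center,
                         p2$classes[[1L]][[1L]]$center))
  expect_identical(p1, specnet:::template_params(tiny_cfg(seed = 1L)))
})

test_that("adding classes does not perturb earlier classes' bands", {
  p3 <- specnet:::template_params(tiny_cfg(n_classes = 3L))
  p5 <- specnet:::template_params(tiny_cfg(
    n_classes = 5L, samples_per_class = 10L, train_per_class = 8L))
  expect_identical(p3$classes[[2L]], p5$classes[[2L]])
  expect_identical(p3$shared, p5$shared)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_classes = 0), "positive")
  expect_error(synth_config(samples_per_class = 5, train_per_class = 5),
               "train")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(class_template(9L, tiny_cfg()), "1\\.\\.3")
})

test_that("the wavenumber grid spans 4000-10000 and is strictly increasing", {
  g <- wavenumber_grid()
  expect_equal(length(g), 1609L)
  expect_equal(g[1L], 4000)
  expect_equal(g[length(g)], 10000)
  expect_true(all(diff(g) > 0))
  expect_error(wavenumber_grid(1), ">= 2")
})
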