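# The 1-D CNN family: n_stages stacked (convolution + max-pooling) blocks
# followed by two equally sized fully connected layers (the first merges
# all feature maps) and a 13-way softmax output. The reported network
# depth counts hidden and output layers only: depth = 2 * n_stages + 3.

#' 1-D CNN architecture configuration
#'
#' Each stage is one convolution layer (ReLU) followed by one
#' non-overlapping max-pooling layer. All stages share the same kernel
#' width, pool width and number of feature maps. The first fully
#' connected layer has as many units as the flattened feature length,
#' the second the same again, and the output layer is a K-way softmax.
#'
#' @param n_stages Number of convolution + pooling stages (1-5). The
#'   reported depth is `2 * n_stages + 3`.
#' @param conv_width Convolution kernel width (points).
#' @param pool_width Pooling (sampling kernel) width; 1 is the identity.
#' @param feature_maps Feature maps (convolution kernels) per stage, M.
#' @param n_classes Output classes K.
#' @param input_length Spectrum length fed to the network.
#' @param pool_mode `"max"` or `"avg"`.
#' @param dropout_p Dropout probability on the fully connected layers.
#' @return A `cnn1d_config`.
#' @examples
#' cnn1d_config(n_stages = 2)
#' @export
cnn1d_config <- function(n_stages = 4L, conv_width = 15L, pool_width = 2L,
                         feature_maps = 24L, n_classes = 13L,
                         input_length = 1609L, pool_mode = c("max", "avg"),
                         dropout_p = 0.5) {
  pool_mode <- match.arg(pool_mode)
  n_stages <- as.integer(n_stages)
  if (is.na(n_stages) || n_stages < 1L || n_stages > 5L) {
    abort("`n_stages` must be an integer in 1..5.")
  }
  if (conv_width < 1L) abort("`conv_width` must be >= 1.")
  if (pool_width < 1L) abort("`pool_width` must be >= 1.")
  if (feature_maps < 1L) abort("`feature_maps` must be >= 1.")
  if (n_classes < 2L) abort("`n_classes` must be >= 2.")
  structure(list(n_stages = n_stages, conv_width = as.integer(conv_width),
                 pool_width = as.integer(pool_width),
                 feature_maps = as.integer(feature_maps),
                 n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 pool_mode = pool_mode, dropout_p = dropout_p),
            class = "cnn1d_config")
}

#' @export
print.cnn1d_config <- function(x, ...) {
  cat(sprintf(
    "<cnn1d_config> depth %d: %d stage(s) of conv 1*%d + pool 1*%d, M = %d, input 1*%d, K = %d\n",
    cnn_depth(x), x$n_stages, x$conv_width, x$pool_width, x$feature_maps,
    x$input_length, x$n_classes))
  invisible(x)
}

#' Reported depth of a 1-D CNN configuration
#'
#' Counts the hidden layers plus the output layer (not the input layer):
#' each stage contributes a convolution and a pooling layer, and on top
#' sit two fully connected layers and one output layer, so
#' `depth = 2 * n_stages + 3`.
#'
#' @param cfg A [cnn1d_config()].
#' @return Integer depth.
#' @export
cnn_depth <- function(cfg) 2L * cfg$n_stages + 3L

#' Per-layer shape propagation of a 1-D CNN
#'
#' Traces output lengths through the stack: a valid convolution of width
#' `m` maps length `L` to `L - m + 1`; a pooling layer of width `w` maps
#' `L` to `floor(L / w)` (a remainder is dropped, with a warning since
#' the sampling kernel should divide the post-convolution length). The
#' first fully connected layer has `final_length * feature_maps` units.
#'
#' @param cfg A [cnn1d_config()].
#' @return Tibble with one row per layer: `layer`, `type`, `channels`,
#'   `length`, `units`.
#' @examples
#' shape_trace(cnn1d_config())
#' @export
shape_trace <- function(cfg) {
  L <- cfg$input_length
  rows <- list(tibble(layer = "input", type = "input", channels = 1L,
                      length = L, units = L))
  truncated <- FALSE
  for (s in seq_len(cfg$n_stages)) {
    if (L < cfg$conv_width) {
      abort(sprintf(
        "Stage %d: input length %d is shorter than the conv kernel (%d).",
        s, L, cfg$conv_width))
    }
    L <- L - cfg$conv_width + 1L
    rows <- c(rows, list(tibble(layer = sprintf("C%d", s), type = "conv",
                                channels = cfg$feature_maps, length = L,
                                units = L * cfg$feature_maps)))
    if (L %% cfg$pool_width != 0L) truncated <- TRUE
    L <- L %/% cfg$pool_width
    if (L < 1L) {
      abort(sprintf("Stage %d: pooling width %d leaves no output.",
                    s, cfg$pool_width))
    }
    rows <- c(rows, list(tibble(layer = sprintf("S%d", s), type = "pool",
                                channels = cfg$feature_maps, length = L,
                                units = L * cfg$feature_maps)))
  }
  if (truncated) {
    warn(paste("Pooling width does not divide a post-convolution length;",
               "trailing points are dropped."))
  }
  f0 <- L * cfg$feature_maps
  rows <- c(rows, list(
    tibble(layer = "FC1", type = "dense", channels = NA_integer_,
           length = NA_integer_, units = f0),
    tibble(layer = "FC2", type = "dense", channels = NA_integer_,
           length = NA_integer_, units = f0),
    tibble(layer = "output", type = "softmax", channels = NA_integer_,
           length = NA_integer_, units = cfg$n_classes)))
  dplyr::bind_rows(rows)
}

#' Build a 1-D CNN model from a configuration
#'
#' @param cfg A [cnn1d_config()].
#' @param seed Integer seed for the small-uniform weight initialization
#'   (zero-mean, scaled by `1 / sqrt(fan_in)`; biases start at zero).
#' @return An `nn_model`.
#' @export
build_cnn1d <- function(cfg, seed = 1L) {
  trace <- suppressWarnings(shape_trace(cfg))
  set.seed(derive_seed(seed, 1L))
  layers <- list()
  in_c <- 1L
  L <- cfg$input_length
  for (s in seq_len(cfg$n_stages)) {
    layers <- c(layers, list(
      make_conv1d_layer(in_c, L, cfg$conv_width, cfg$feature_maps),
      make_relu_layer(),
      make_pool1d_layer(cfg$pool_width, cfg$pool_mode)))
    L <- (L - cfg$conv_width + 1L) %/% cfg$pool_width
    in_c <- cfg$feature_maps
  }
  f0 <- L * cfg$feature_maps
  layers <- c(layers, list(
    make_flatten_layer(),
    make_dense_layer(f0, f0), make_relu_layer(),
    make_dropout_layer(cfg$dropout_p),
    make_dense_layer(f0, f0), make_relu_layer(),
    make_dropout_layer(cfg$dropout_p),
    make_dense_layer(f0, cfg$n_classes)))
  model <- new_nn_model(layers, input_shape = c(1L, cfg$input_length),
                        n_classes = cfg$n_classes,
                        arch = sprintf("1D_CNN_%d", cnn_depth(cfg)))
  model$config <- cfg
  model$trace <- trace
  model
}

# Dataset rows (samples x points) -> channel-first (1, L, B) batch.
as_batch_1d <- function(x) {
  array(t(x), c(1L, ncol(x), nrow(x)))
}

# Stratified carve-out of a validation subset from the training split.
carve_validation <- function(labels, fraction, seed) {
  set.seed(seed)
  val <- logical(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    n_val <- max(1L, round(fraction * length(idx)))
    val[sample(idx, n_val)] <- TRUE
  }
  val
}

#' Train a 1-D CNN on a spectra dataset
#'
#' Trains on the dataset's training split with the mini-batch SGD
#' protocol of [nn_train()] and evaluates on the test split. Spectra are
#' standardized (global mean/sd of the training split) before entering
#' the network, and the same affine map is applied at prediction time.
#'
#' Early stopping monitors, by default, a class-stratified validation
#' subset carved out of the training split (`monitor = "validation"`);
#' `monitor = "test"` instead monitors the test split itself, matching
#' protocols that watch the test error directly, at the price of
#' information leaking from the test set into the stopping rule.
#'
#' @param ds A (preprocessed) [spectra_dataset] with a train/test split.
#' @param cfg A [cnn1d_config()]; its input length and class count are
#'   aligned to the dataset.
#' @param spec A [train_spec()].
#' @param monitor `"validation"` (default) or `"test"`.
#' @param val_fraction Fraction of the training split carved out for
#'   monitoring when `monitor = "validation"`.
#' @return A `cnn1d_fit`: list with the `train_state`, the test-set
#'   `eval_report`, the config and the standardization constants.
#' @export
train_cnn1d <- function(ds, cfg = cnn1d_config(), spec = train_spec(),
                        monitor = c("validation", "test"),
                        val_fraction = 0.2) {
  monitor <- match.arg(monitor)
  cfg$input_length <- n_points(ds)
  cfg$n_classes <- n_classes(ds)
  tr <- ds$split == "train"
  x_tr <- ds$absorbance[tr, , drop = FALSE]
  y_tr <- ds$labels[tr]
  x_te <- ds$absorbance[!tr, , drop = FALSE]
  y_te <- ds$labels[!tr]
  mu <- mean(x_tr); sg <- sd(as.vector(x_tr))
  if (sg == 0) sg <- 1
  x_tr <- (x_tr - mu) / sg
  x_te <- (x_te - mu) / sg
  if (monitor == "validation") {
    val <- carve_validation(y_tr, val_fraction,
                            seed = derive_seed(spec$seed, 11L))
    x_val <- as_batch_1d(x_tr[val, , drop = FALSE]); y_val <- y_tr[val]
    x_fit <- as_batch_1d(x_tr[!val, , drop = FALSE]); y_fit <- y_tr[!val]
  } else {
    x_val <- as_batch_1d(x_te); y_val <- y_te
    x_fit <- as_batch_1d(x_tr); y_fit <- y_tr
  }
  model <- build_cnn1d(cfg, seed = derive_seed(spec$seed, 2L))
  state <- nn_train(model, x_fit, y_fit, x_val, y_val, spec)
  pred <- nn_predict(state$model, as_batch_1d(x_te))
  report <- evaluate(y_te, pred, cfg$n_classes, ds$class_names)
  pred_tr <- nn_predict(state$model, as_batch_1d(x_tr))
  report_train <- evaluate(y_tr, pred_tr, cfg$n_classes, ds$class_names)
  structure(list(state = state, report = report, report_train = report_train,
                 config = cfg, center = mu, scale = sg, monitor = monitor),
            class = "cnn1d_fit")
}

#' @export
print.cnn1d_fit <- function(x, ...) {
  cat(sprintf(
    "<cnn1d_fit> depth %d; train accuracy %.2f%%, test accuracy %.2f%%\n",
    cnn_depth(x$config), x$report_train$accuracy, x$report$accuracy))
  invisible(x)
}

#' @export
predict.cnn1d_fit <- function(object, newdata, ...) {
  x <- (as.matrix(newdata) - object$center) / object$scale
  nn_predict(object$state$model, as_batch_1d(x))
}

#' @rdname train_cnn1d
#' @param x A `cnn1d_fit`.
#' @param ... Unused.
#' @export
glance.cnn1d_fit <- function(x, ...) {
  tibble(depth = cnn_depth(x$config),
         conv_width = x$config$conv_width,
         pool_width = x$config$pool_width,
         feature_maps = x$config$feature_maps,
         epochs_run = x$state$epochs_run,
         best_epoch = x$state$best_epoch,
         train_accuracy = x$report_train$accuracy,
         test_accuracy = x$report$accuracy)
}

# ---- architecture sweeps ---------------------------------------------------

run_cnn1d_once <- function(ds, cfg, spec, monitor) {
  fit <- train_cnn1d(ds, cfg, spec = spec, monitor = monitor)
  tibble(depth = cnn_depth(fit$config),
         conv_width = fit$config$conv_width,
         pool_width = fit$config$pool_width,
         feature_maps = fit$config$feature_maps,
         train_accuracy = fit$report_train$accuracy,
         test_accuracy = fit$report$accuracy)
}

sweep_engine <- function(ds, values, base_cfg, field, spec, monitor) {
  purrr::map_dfr(seq_along(values), function(i) {
    cfg <- base_cfg
    cfg[[field]] <- values[[i]]
    run_spec <- spec
    run_spec$seed <- derive_seed(spec$seed, 1000L + i)
    row <- run_cnn1d_once(ds, cfg, run_spec, monitor)
    dplyr::mutate(row, model = sprintf("1D_CNN_%d", row$depth), .before = 1L)
  })
}

#' Architecture sweeps for the 1-D CNN family
#'
#' Each sweep varies one structural hyperparameter while holding the
#' others at `base_cfg`, trains a model per value with a deterministic
#' sub-seed, and tabulates train/test accuracy:
#' `sweep_depth()` varies the number of stages through the reported
#' depths; `sweep_kernel()` the convolution kernel width;
#' `sweep_pool()` the sampling (pooling) kernel width, including the
#' identity width 1; `sweep_maps()` the number of feature maps.
#'
#' @param ds A preprocessed [spectra_dataset].
#' @param depths Reported depths to test (each must be `2 * stages + 3`).
#' @param values Hyperparameter values to test.
#' @param base_cfg Baseline [cnn1d_config()] for the non-swept fields.
#' @param spec A [train_spec()]; each run derives its own sub-seed.
#' @param monitor Early-stopping monitor, see [train_cnn1d()].
#' @return Tibble with one row per value: model, architecture fields,
#'   `train_accuracy`, `test_accuracy` (percent).
#' @export
sweep_depth <- function(ds, depths = c(5L, 7L, 9L, 11L, 13L),
                        base_cfg = cnn1d_config(conv_width = 5L,
                                                pool_width = 2L,
                                                feature_maps = 12L),
                        spec = train_spec(),
                        monitor = c("validation", "test")) {
  monitor <- match.arg(monitor)
  if (any((depths - 3L) %% 2L != 0L | depths < 5L)) {
    abort("Each depth must equal 2 * n_stages + 3 with n_stages >= 1.")
  }
  sweep_engine(ds, as.integer((depths - 3L) / 2L), base_cfg, "n_stages",
               spec, monitor)
}

#' @rdname sweep_depth
#' @export
sweep_kernel <- function(ds, values = seq(3L, 15L, by = 2L),
                         base_cfg = cnn1d_config(feature_maps = 12L),
                         spec = train_spec(),
                         monitor = c("validation", "test")) {
  monitor <- match.arg(monitor)
  sweep_engine(ds, as.integer(values), base_cfg, "conv_width", spec, monitor)
}

#' @rdname sweep_depth
#' @export
sweep_pool <- function(ds, values = 1:5,
                       base_cfg = cnn1d_config(feature_maps = 12L),
                       spec = train_spec(),
                       monitor = c("validation", "test")) {
  monitor <- match.arg(monitor)
  sweep_engine(ds, as.integer(values), base_cfg, "pool_width", spec, monitor)
}

#' @rdname sweep_depth
#' @export
sweep_maps <- function(ds, values = seq(6L, 36L, by = 6L),
                       base_cfg = cnn1d_config(),
                       spec = train_spec(),
                       monitor = c("validation", "test")) {
  monitor <- match.arg(monitor)
  sweep_engine(ds, as.integer(values), base_cfg, "feature_maps", spec, monitor)
}

#' @rdname sweep_depth
#' @param object A sweep result tibble is plotted with
#'   [autoplot.tbl_df()]-style helpers; see `plot_sweep()`.
#' @param x_var Column to place on the x axis.
#' @export
plot_sweep <- function(object, x_var) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x_var]],
                                       y = .data$test_accuracy)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(color = "#2c7fb8") +
    ggplot2::labs(y = "Test set accuracy (%)") +
    ggplot2::theme_minimal()
}
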