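# LeNet-5-style 2-D CNN for spectral images: two (5x5 convolution +
# 2x2 max-pooling) stages with 6 and 16 feature maps, fully connected
# layers of 120 and 84 units (ReLU + dropout), and a K-way softmax head
# replacing the original output layer. Any image side >= 18 is supported;
# the flatten size is recomputed from the valid-convolution arithmetic.

#' LeNet-5-style architecture configuration
#'
#' @param input_side Image side length n (the interception series uses
#'   the even sides 26..40; any n >= 16 leaves positive spatial dims in
#'   the default stack).
#' @param conv1_maps,conv2_maps Feature maps of the two convolution
#'   layers (classically 6 and 16).
#' @param kernel Convolution kernel side (classically 5).
#' @param pool Pooling window side (classically 2).
#' @param fc1,fc2 Units of the two fully connected layers (120, 84).
#' @param n_classes Output classes K.
#' @param pool_mode `"max"` or `"avg"`.
#' @param dropout_p Dropout probability on the fully connected layers.
#' @return A `lenet_config`.
#' @export
lenet_config <- function(input_side = 32L, conv1_maps = 6L, conv2_maps = 16L,
                         kernel = 5L, pool = 2L, fc1 = 120L, fc2 = 84L,
                         n_classes = 13L, pool_mode = c("max", "avg"),
                         dropout_p = 0.5) {
  pool_mode <- match.arg(pool_mode)
  input_side <- as.integer(input_side)
  if (n_classes < 2L) abort("`n_classes` must be >= 2.")
  cfg <- structure(list(input_side = input_side,
                        conv1_maps = as.integer(conv1_maps),
                        conv2_maps = as.integer(conv2_maps),
                        kernel = as.integer(kernel), pool = as.integer(pool),
                        fc1 = as.integer(fc1), fc2 = as.integer(fc2),
                        n_classes = as.integer(n_classes),
                        pool_mode = pool_mode, dropout_p = dropout_p),
                   class = "lenet_config")
  lenet_shape_trace(cfg)   # validates that both stages leave positive dims
  cfg
}

#' @export
print.lenet_config <- function(x, ...) {
  tr <- lenet_shape_trace(x)
  cat(sprintf(
    "<lenet_config> input %d x %d -> %s -> flatten %d -> FC %d -> FC %d -> K = %d\n",
    x$input_side, x$input_side,
    paste(tr$side[tr$type %in% c("conv", "pool")], collapse = " -> "),
    tr$units[tr$layer == "flatten"], x$fc1, x$fc2, x$n_classes))
  invisible(x)
}

#' Spatial shape propagation of the LeNet-style stack
#'
#' Valid convolutions shrink the side by `kernel - 1`; pooling divides
#' it by `pool` (floor). The flatten size is
#' `conv2_maps * final_side^2`; for the classic 32x32 input the trace is
#' 32 -> 28 -> 14 -> 10 -> 5 and the flatten size 16 * 5 * 5 = 400.
#'
#' @param cfg A [lenet_config()].
#' @return Tibble with `layer`, `type`, `channels`, `side`, `units`.
#' @export
lenet_shape_trace <- function(cfg) {
  s <- cfg$input_side
  rows <- list(tibble(layer = "input", type = "input", channels = 1L,
                      side = s, units = s^2))
  chans <- c(cfg$conv1_maps, cfg$conv2_maps)
  for (st in 1:2) {
    if (s < cfg$kernel) {
      abort(sprintf(
        "Input side %d is too small for stage %d (kernel %d); need >= %d.",
        cfg$input_side, st, cfg$kernel,
        min_lenet_side(cfg$kernel, cfg$pool)))
    }
    s <- s - cfg$kernel + 1L
    rows <- c(rows, list(tibble(layer = sprintf("C%d", st), type = "conv",
                                channels = chans[st], side = s,
                                units = chans[st] * s^2)))
    s <- s %/% cfg$pool
    if (s < 1L) {
      abort(sprintf("Stage %d pooling leaves no output.", st))
    }
    rows <- c(rows, list(tibble(layer = sprintf("S%d", st), type = "pool",
                                channels = chans[st], side = s,
                                units = chans[st] * s^2)))
  }
  rows <- c(rows, list(
    tibble(layer = "flatten", type = "flatten", channels = NA_integer_,
           side = NA_integer_, units = cfg$conv2_maps * s^2),
    tibble(layer = "FC1", type = "dense", channels = NA_integer_,
           side = NA_integer_, units = cfg$fc1),
    tibble(layer = "FC2", type = "dense", channels = NA_integer_,
           side = NA_integer_, units = cfg$fc2),
    tibble(layer = "output", type = "softmax", channels = NA_integer_,
           side = NA_integer_, units = cfg$n_classes)))
  dplyr::bind_rows(rows)
}

min_lenet_side <- function(kernel, pool) {
  # smallest n with positive dims after conv-pool-conv-pool:
  # floor((floor((n-k+1)/p) - k + 1)/p) >= 1
  pool * (kernel + pool - 1L) + kernel - 1L
}

#' Build a LeNet-style 2-D CNN
#'
#' Weights are initialized from the seeded small-uniform scheme
#' (zero-mean, scaled by `1 / sqrt(fan_in)`); biases start at zero.
#'
#' @param cfg A [lenet_config()].
#' @param seed Integer seed; identical seeds give identical initial
#'   weights.
#' @return An `nn_model`.
#' @export
build_lenet <- function(cfg, seed = 1L) {
  trace <- lenet_shape_trace(cfg)
  set.seed(derive_seed(seed, 3L))
  s <- cfg$input_side
  layers <- list(
    make_conv2d_layer(1L, s, s, cfg$kernel, cfg$kernel, cfg$conv1_maps),
    make_relu_layer(),
    make_pool2d_layer(cfg$pool, cfg$pool_mode))
  s1 <- (s - cfg$kernel + 1L) %/% cfg$pool
  layers <- c(layers, list(
    make_conv2d_layer(cfg$conv1_maps, s1, s1, cfg$kernel, cfg$kernel,
                      cfg$conv2_maps),
    make_relu_layer(),
    make_pool2d_layer(cfg$pool, cfg$pool_mode)))
  s2 <- (s1 - cfg$kernel + 1L) %/% cfg$pool
  flat <- cfg$conv2_maps * s2^2
  layers <- c(layers, list(
    make_flatten_layer(),
    make_dense_layer(flat, cfg$fc1), make_relu_layer(),
    make_dropout_layer(cfg$dropout_p),
    make_dense_layer(cfg$fc1, cfg$fc2), make_relu_layer(),
    make_dropout_layer(cfg$dropout_p),
    make_dense_layer(cfg$fc2, cfg$n_classes)))
  model <- new_nn_model(layers, input_shape = c(1L, s, s),
                        n_classes = cfg$n_classes, arch = "2D_LeNet5")
  model$config <- cfg
  model$trace <- trace
  model
}

# (n, n, B) pixel array -> channel-first (1, n, n, B) batch.
as_batch_2d <- function(pixels) {
  d <- dim(pixels)
  array(pixels, c(1L, d[1L], d[2L], d[3L]))
}

#' Train the LeNet-style 2-D CNN on spectral images
#'
#' Converts the dataset into `input_side x input_side` images
#' ([image_dataset()], min-max scaled), trains with the shared SGD
#' protocol, optionally re-fits a brand-new softmax head on the frozen
#' convolutional trunk (`refit = TRUE`, the default), and evaluates on
#' the test split.
#'
#' @param ds A preprocessed [spectra_dataset].
#' @param cfg A [lenet_config()].
#' @param spec A [train_spec()].
#' @param monitor Early-stopping monitor, see [train_cnn1d()].
#' @param val_fraction Carved-out validation fraction.
#' @param refit Re-initialize and re-fit the output layer with the trunk
#'   frozen after the main training run.
#' @return A `lenet_fit`: `state`, test `report`, training-set report,
#'   config and image metadata.
#' @export
train_lenet <- function(ds, cfg = lenet_config(), spec = train_spec(),
                        monitor = c("validation", "test"),
                        val_fraction = 0.2, refit = TRUE) {
  monitor <- match.arg(monitor)
  cfg$n_classes <- n_classes(ds)
  imgs <- image_dataset(ds, cfg$input_side, scale = TRUE)
  tr <- imgs$split == "train"
  # standardize intensities (training-split mean/sd): the min-max image
  # values carry a large constant offset and little contrast, which stalls
  # SGD at the fixed learning rate
  mu <- mean(imgs$pixels[, , tr]); sg <- sd(as.vector(imgs$pixels[, , tr]))
  if (sg == 0) sg <- 1
  imgs$pixels <- (imgs$pixels - mu) / sg
  x_tr <- imgs$pixels[, , tr, drop = FALSE]
  y_tr <- imgs$labels[tr]
  x_te <- as_batch_2d(imgs$pixels[, , !tr, drop = FALSE])
  y_te <- imgs$labels[!tr]
  if (monitor == "validation") {
    val <- carve_validation(y_tr, val_fraction,
                            seed = derive_seed(spec$seed, 12L))
    x_val <- as_batch_2d(x_tr[, , val, drop = FALSE]); y_val <- y_tr[val]
    x_fit <- as_batch_2d(x_tr[, , !val, drop = FALSE]); y_fit <- y_tr[!val]
  } else {
    x_val <- x_te; y_val <- y_te
    x_fit <- as_batch_2d(x_tr); y_fit <- y_tr
  }
  model <- build_lenet(cfg, seed = derive_seed(spec$seed, 4L))
  state <- nn_train(model, x_fit, y_fit, x_val, y_val, spec)
  if (refit) {
    state <- refit_head(state$model, x_fit, y_fit, x_val, y_val, spec)
  }
  pred <- nn_predict(state$model, x_te)
  report <- evaluate(y_te, pred, cfg$n_classes, ds$class_names)
  x_tr_all <- as_batch_2d(x_tr)
  report_train <- evaluate(y_tr, nn_predict(state$model, x_tr_all),
                           cfg$n_classes, ds$class_names)
  structure(list(state = state, report = report, report_train = report_train,
                 config = cfg, monitor = monitor, refit = refit,
                 wavenumber_range = imgs$wavenumber_range),
            class = "lenet_fit")
}

#' @export
print.lenet_fit <- function(x, ...) {
  cat(sprintf(
    "<lenet_fit> input %d x %d; train accuracy %.2f%%, test accuracy %.2f%%\n",
    x$config$input_side, x$config$input_side,
    x$report_train$accuracy, x$report$accuracy))
  invisible(x)
}

#' @rdname train_lenet
#' @param x A `lenet_fit`.
#' @param ... Unused.
#' @export
glance.lenet_fit <- function(x, ...) {
  tibble(input_side = x$config$input_side,
         epochs_run = x$state$epochs_run,
         best_epoch = x$state$best_epoch,
         train_accuracy = x$report_train$accuracy,
         test_accuracy = x$report$accuracy)
}

#' Image-size (interception window) sweep for the 2-D CNN
#'
#' For every side n, reshapes the first n^2 spectral points into images,
#' trains the LeNet-style model with a deterministic sub-seed, and
#' records the test accuracy together with the approximate retained
#' wavenumber range.
#'
#' @param ds A preprocessed [spectra_dataset].
#' @param sides Image sides, largest first (default `40, 38, ..., 26`).
#' @param base_cfg A [lenet_config()] for the non-swept fields.
#' @param spec A [train_spec()].
#' @param monitor Early-stopping monitor.
#' @param refit Refit the softmax head after training (see
#'   [train_lenet()]).
#' @return Tibble: `model`, `input_side`, `wn_min`, `wn_max`,
#'   `train_accuracy`, `test_accuracy`.
#' @export
sweep_image_size <- function(ds, sides = seq(40L, 26L, by = -2L),
                             base_cfg = lenet_config(), spec = train_spec(),
                             monitor = c("validation", "test"),
                             refit = TRUE) {
  monitor <- match.arg(monitor)
  purrr::map_dfr(seq_along(sides), function(i) {
    cfg <- base_cfg
    cfg$input_side <- as.integer(sides[i])
    run_spec <- spec
    run_spec$seed <- derive_seed(spec$seed, 2000L + i)
    fit <- train_lenet(ds, cfg, spec = run_spec, monitor = monitor,
                       refit = refit)
    tibble(model = "2D_LeNet5", input_side = cfg$input_side,
           wn_min = fit$wavenumber_range[1L],
           wn_max = fit$wavenumber_range[2L],
           train_accuracy = fit$report_train$accuracy,
           test_accuracy = fit$report$accuracy)
  })
}
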