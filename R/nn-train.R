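# Mini-batch SGD with early stopping. The protocol follows the study
# settings: learning rate 0.01, batch size 40, at most 50 epochs, dropout
# 0.5 on the fully connected layers, training stopped when the monitored
# error has not improved for `patience` epochs, returning the best-epoch
# weights.

#' Training protocol specification
#'
#' @param learning_rate SGD step size (plain gradient descent, no momentum).
#' @param batch_size Samples per mini-batch.
#' @param max_epochs Maximum number of passes over the training set.
#' @param dropout_p Dropout probability on fully connected layers during
#'   training (`0 <= p < 1`).
#' @param patience Early stopping: epochs without improvement of the
#'   monitored error before training halts.
#' @param seed Integer seed controlling shuffling, dropout and weight
#'   initialization in the drivers that consume this spec.
#' @return A `train_spec` list.
#' @export
train_spec <- function(learning_rate = 0.01, batch_size = 40L,
                       max_epochs = 50L, dropout_p = 0.5,
                       patience = 5L, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (batch_size < 1L) abort("`batch_size` must be >= 1.")
  if (max_epochs < 1L) abort("`max_epochs` must be >= 1.")
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1).")
  if (patience < 1L) abort("`patience` must be >= 1.")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 dropout_p = dropout_p, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_spec")
}

sgd_update <- function(model, grads, lr, l2 = 0) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    ly <- model$layers[[i]]
    if (is.null(g) || is.null(ly$W) || !isTRUE(ly$trainable)) next
    if (l2 > 0) g$dW <- g$dW + l2 * ly$W
    model$layers[[i]]$W <- ly$W - lr * g$dW
    model$layers[[i]]$b <- ly$b - lr * g$db
  }
  model
}

error_rate <- function(model, x, y) {
  mean(nn_predict(model, x) != y)
}

#' Train a network with mini-batch SGD and early stopping
#'
#' Minimizes the softmax cross-entropy by plain stochastic gradient
#' descent. After every epoch the classification error on `x_val` is
#' recorded; training stops early once that error has failed to improve
#' for `spec$patience` consecutive epochs, and the weights from the
#' best-validation epoch are returned (not the last ones).
#'
#' @param model An `nn_model` (freshly built or to be fine-tuned).
#' @param x_train,y_train Channel-first training batch and integer labels
#'   in `1..K`.
#' @param x_val,y_val Monitoring set used for early stopping.
#' @param spec A [train_spec()].
#' @param verbose Emit one line per epoch to stderr.
#' @return A `train_state`: list with the best-epoch `model`, a `history`
#'   tibble (epoch, train_loss, train_error, val_error), `best_epoch`,
#'   `epochs_run` and the `spec`.
#' @export
nn_train <- function(model, x_train, y_train, x_val, y_val, spec = train_spec(),
                     verbose = FALSE) {
  n <- batch_size_of(x_train)
  if (n == 0L || batch_size_of(x_val) == 0L) {
    abort("Training and validation sets must be non-empty.")
  }
  if (length(y_train) != n) abort("`y_train` length must match the batch.")
  if (any(y_train < 1L | y_train > model$n_classes)) {
    abort("Labels must lie in 1..K.")
  }
  set.seed(spec$seed)
  best_err <- Inf
  best_model <- model
  best_epoch <- 0L
  bad <- 0L
  hist <- vector("list", spec$max_epochs)
  for (epoch in seq_len(spec$max_epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (s in seq(1L, n, by = spec$batch_size)) {
      idx <- perm[s:min(s + spec$batch_size - 1L, n)]
      xb <- batch_slice(x_train, idx)
      fw <- nn_forward(model, xb, training = TRUE)
      ls <- softmax_xent(fw$out, y_train[idx])
      if (!is.finite(ls$loss)) {
        abort(sprintf(
          "Loss became non-finite at epoch %d (batch starting %d); lower the learning rate.",
          epoch, s))
      }
      losses <- c(losses, ls$loss)
      grads <- nn_backward(model, fw$caches, ls$dlogits)
      model <- sgd_update(model, grads, spec$learning_rate)
    }
    tr_err <- error_rate(model, x_train, y_train)
    va_err <- error_rate(model, x_val, y_val)
    hist[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                            train_error = tr_err, val_error = va_err)
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  train_err %.4f  val_err %.4f",
                      epoch, mean(losses), tr_err, va_err))
    }
    if (va_err < best_err) {
      best_err <- va_err
      best_model <- model
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= spec$patience) break
    }
  }
  structure(list(model = best_model, history = dplyr::bind_rows(hist),
                 best_epoch = best_epoch, best_val_error = best_err,
                 epochs_run = epoch, spec = spec),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf(
    "<train_state> %d epoch(s) run, best epoch %d (val error %.4f)\n",
    x$epochs_run, x$best_epoch, x$best_val_error))
  invisible(x)
}

#' @rdname nn_train
#' @param x A `train_state`.
#' @param ... Unused.
#' @export
tidy.train_state <- function(x, ...) x$history

#' @rdname nn_train
#' @export
glance.train_state <- function(x, ...) {
  tibble(epochs_run = x$epochs_run, best_epoch = x$best_epoch,
         best_val_error = x$best_val_error,
         final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' Re-fit the classification head on frozen features
#'
#' Re-initializes the final (softmax output) layer and trains it alone,
#' with every layer below frozen — i.e. fits a brand-new single-layer
#' classifier on the features extracted by the trained trunk.
#'
#' @param model A trained `nn_model`.
#' @inheritParams nn_train
#' @return A `train_state` for the head-refit model.
#' @export
refit_head <- function(model, x_train, y_train, x_val, y_val,
                       spec = train_spec()) {
  n_layers <- length(model$layers)
  last_dense <- max(which(vapply(model$layers,
                                 function(ly) ly$type == "dense",
                                 logical(1L))))
  for (i in seq_len(n_layers)) {
    if (!is.null(model$layers[[i]]$W)) model$layers[[i]]$trainable <- FALSE
  }
  set.seed(derive_seed(spec$seed, 97L))
  ly <- model$layers[[last_dense]]
  model$layers[[last_dense]]$W <-
    matrix(uniform_init(length(ly$W), ncol(ly$W)), nrow(ly$W), ncol(ly$W))
  model$layers[[last_dense]]$b <- numeric(nrow(ly$W))
  model$layers[[last_dense]]$trainable <- TRUE
  nn_train(model, x_train, y_train, x_val, y_val, spec)
}

# Finite-difference gradient check used by the test-suite: compares the
# backprop gradient of the mean cross-entropy with central differences on
# a random subset of parameters.
nn_gradient_check <- function(model, x, y, n_params = 10L, eps = 1e-5,
                              seed = 1L) {
  # dropout is stochastic; drop it so the two gradient routes see the same
  # deterministic function
  model$layers <- Filter(function(ly) ly$type != "dropout", model$layers)
  fw <- nn_forward(model, x, training = TRUE)
  ls <- softmax_xent(fw$out, y)
  grads <- nn_backward(model, fw$caches, ls$dlogits)
  g_flat <- nn_get_grads_flat(model, grads)
  theta <- nn_get_params(model)
  set.seed(seed)
  pick <- sample.int(length(theta), min(n_params, length(theta)))
  num <- vapply(pick, function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    lp <- softmax_xent(nn_forward(nn_set_params(model, tp), x)$out, y)$loss
    tm <- theta; tm[j] <- tm[j] - eps
    lm <- softmax_xent(nn_forward(nn_set_params(model, tm), x)$out, y)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1L))
  ana <- g_flat[pick]
  rel <- abs(num - ana) / pmax(abs(num) + abs(ana), 1e-8)
  tibble(param = pick, numeric = num, analytic = ana, rel_error = rel)
}
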