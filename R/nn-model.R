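# Network container and the forward/backward machinery shared by the 1-D
# CNN family and the LeNet-style 2-D CNN. A model is an ordered list of
# layer descriptors; shapes (and im2col index vectors for the convolutions)
# are resolved once at build time because spectra have a fixed length.

# Zero-mean uniform init scaled by 1/sqrt(fan_in); the bound sqrt(6/fan_in)
# keeps activation variance roughly constant through the ReLU stack
# (He-style uniform), which matters for the deeper members of the family.
uniform_init <- function(n, fan_in) {
  s <- sqrt(6 / fan_in)
  runif(n, -s, s)
}

make_conv1d_layer <- function(in_c, in_l, m, n_kernels) {
  if (in_l < m) {
    abort(sprintf(
      "Conv layer kernel width %d exceeds its input length %d.", m, in_l))
  }
  fan_in <- in_c * m
  list(type = "conv1d",
       W = matrix(uniform_init(n_kernels * fan_in, fan_in), n_kernels, fan_in),
       b = numeric(n_kernels),
       m = m, in_shape = c(in_c, in_l), out_len = in_l - m + 1L,
       idx = conv1d_index(in_c, in_l, m), trainable = TRUE)
}

make_conv2d_layer <- function(in_c, in_h, in_w, kh, kw, n_kernels) {
  if (in_h < kh || in_w < kw) {
    abort(sprintf("Conv kernel %dx%d exceeds its input %dx%d.",
                  kh, kw, in_h, in_w))
  }
  fan_in <- in_c * kh * kw
  list(type = "conv2d",
       W = matrix(uniform_init(n_kernels * fan_in, fan_in), n_kernels, fan_in),
       b = numeric(n_kernels),
       kh = kh, kw = kw, in_shape = c(in_c, in_h, in_w),
       oh = in_h - kh + 1L, ow = in_w - kw + 1L,
       idx = conv2d_index(in_c, in_h, in_w, kh, kw), trainable = TRUE)
}

make_dense_layer <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(uniform_init(n_out * n_in, n_in), n_out, n_in),
       b = numeric(n_out), trainable = TRUE)
}

make_pool1d_layer <- function(w, mode = "max") {
  list(type = "pool1d", w = as.integer(w), mode = mode)
}

make_pool2d_layer <- function(w, mode = "max") {
  list(type = "pool2d", w = as.integer(w), mode = mode)
}

make_relu_layer <- function() list(type = "relu")
make_flatten_layer <- function() list(type = "flatten")
make_dropout_layer <- function(p) list(type = "dropout", p = p)

new_nn_model <- function(layers, input_shape, n_classes, arch = "cnn") {
  structure(list(layers = layers, input_shape = input_shape,
                 n_classes = n_classes, arch = arch),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model: %s>  input (%s) -> %d classes, %s parameters\n",
              x$arch, paste(x$input_shape, collapse = " x "),
              x$n_classes, format(n_parameters(x), big.mark = ",")))
  for (ly in x$layers) {
    extra <- switch(ly$type,
      conv1d = sprintf(" %d kernels, width %d", nrow(ly$W), ly$m),
      conv2d = sprintf(" %d kernels, %dx%d", nrow(ly$W), ly$kh, ly$kw),
      dense = sprintf(" %d -> %d", ncol(ly$W), nrow(ly$W)),
      pool1d = sprintf(" width %d (%s)", ly$w, ly$mode),
      pool2d = sprintf(" %dx%d (%s)", ly$w, ly$w, ly$mode),
      dropout = sprintf(" p = %.2f", ly$p),
      "")
    cat(sprintf("  %-8s%s\n", ly$type, extra))
  }
  invisible(x)
}

#' Number of trainable parameters in a network
#'
#' @param model An `nn_model`.
#' @return Integer count of weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (is.null(ly$W)) 0L else length(ly$W) + length(ly$b)
  }, integer(1L)))
}

# ---- forward / backward ---------------------------------------------------

# Runs the network on a channel-first batch; in training mode every layer's
# cache (im2col matrices, ReLU masks, dropout masks, pooling argmaxes) is
# kept for the backward pass. Dropout draws from the current RNG stream and
# is inactive in eval mode (inverted dropout, so no rescaling here).
nn_forward <- function(model, x, training = FALSE) {
  layers <- model$layers
  caches <- if (training) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    x <- switch(ly$type,
      conv1d = {
        if (!identical(dim(x)[1:2], as.integer(ly$in_shape))) {
          abort(sprintf(
            "Layer %d (conv1d) expected input %s but received %s.",
            i, paste(ly$in_shape, collapse = "x"),
            paste(dim(x)[-length(dim(x))], collapse = "x")))
        }
        fw <- conv1d_forward(x, ly$W, ly$b, ly$idx, ly$out_len)
        if (training) caches[[i]] <- list(xcol = fw$xcol, in_dim = dim(x))
        fw$out
      },
      conv2d = {
        if (!identical(dim(x)[1:3], as.integer(ly$in_shape))) {
          abort(sprintf(
            "Layer %d (conv2d) expected input %s but received %s.",
            i, paste(ly$in_shape, collapse = "x"),
            paste(dim(x)[-length(dim(x))], collapse = "x")))
        }
        fw <- conv2d_forward(x, ly$W, ly$b, ly$idx, ly$oh, ly$ow)
        if (training) caches[[i]] <- list(xcol = fw$xcol, in_dim = dim(x))
        fw$out
      },
      pool1d = {
        fw <- pool1d_forward(x, ly$w, ly$mode)
        if (training) caches[[i]] <- fw[c("argmax", "in_dim")]
        fw$out
      },
      pool2d = {
        fw <- pool2d_forward(x, ly$w, ly$mode)
        if (training) caches[[i]] <- fw[c("argmax", "in_dim")]
        fw$out
      },
      relu = {
        out <- relu(x)
        if (training) caches[[i]] <- list(mask = x > 0)
        out
      },
      flatten = {
        d <- dim(x)
        if (training) caches[[i]] <- list(in_dim = d)
        matrix(x, prod(d[-length(d)]), d[length(d)])
      },
      dense = {
        if (nrow(x) != ncol(ly$W)) {
          abort(sprintf("Layer %d (dense) expected %d inputs, received %d.",
                        i, ncol(ly$W), nrow(x)))
        }
        if (training) caches[[i]] <- list(x = x)
        ly$W %*% x + ly$b
      },
      dropout = {
        if (training) {
          mask <- (runif(length(x)) >= ly$p) / (1 - ly$p)
          dim(mask) <- dim(x)
          caches[[i]] <- list(mask = mask)
          x * mask
        } else {
          x
        }
      },
      abort(sprintf("Unknown layer type '%s'.", ly$type)))
  }
  list(out = x, caches = caches)
}

# dlogits: gradient of the loss w.r.t. the network output (K, B).
# Returns per-layer parameter gradients; input gradients are not propagated
# past the first parametric layer.
nn_backward <- function(model, caches, dlogits) {
  layers <- model$layers
  n <- length(layers)
  grads <- vector("list", n)
  need_dx_below <- logical(n)
  seen <- FALSE   # scanning from the bottom: does any layer below need dx?
  for (i in seq_len(n)) {
    need_dx_below[i] <- seen
    if (!is.null(layers[[i]]$W)) seen <- TRUE
  }
  d <- dlogits
  for (i in rev(seq_len(n))) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    d <- switch(ly$type,
      dense = {
        grads[[i]] <- list(dW = tcrossprod(d, ca$x), db = rowSums(d))
        if (need_dx_below[i]) crossprod(ly$W, d) else NULL
      },
      conv1d = {
        bk <- conv1d_backward(d, ca$xcol, ly$W, ly$idx, ca$in_dim,
                              need_dx = need_dx_below[i])
        grads[[i]] <- list(dW = bk$dW, db = bk$db)
        bk$dx
      },
      conv2d = {
        bk <- conv2d_backward(d, ca$xcol, ly$W, ly$idx, ca$in_dim,
                              need_dx = need_dx_below[i])
        grads[[i]] <- list(dW = bk$dW, db = bk$db)
        bk$dx
      },
      pool1d = pool1d_backward(d, ly$w, ly$mode, ca$argmax, ca$in_dim),
      pool2d = pool2d_backward(d, ly$w, ly$mode, ca$argmax, ca$in_dim),
      relu = d * ca$mask,
      flatten = array(d, ca$in_dim),
      dropout = d * ca$mask,
      abort(sprintf("Unknown layer type '%s'.", ly$type)))
    if (is.null(d) && i > 1L) {
      # no parametric layer below: stop propagating
      break
    }
  }
  grads
}

# Cross-entropy of a softmax head. y: integer labels 1..K. Returns the mean
# loss over the batch and the gradient w.r.t. the logits.
softmax_xent <- function(logits, y) {
  B <- ncol(logits)
  p <- softmax_mat(logits)
  iy <- cbind(y, seq_len(B))    # (class, sample) pairs; logits are (K, B)
  py <- p[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(py, 1e-300)))
  dl <- p
  dl[cbind(y, seq_len(B))] <- dl[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dl / B)
}

# Slice a channel-first batch along its last (batch) dimension.
batch_slice <- function(x, idx) {
  nd <- length(dim(x))
  if (nd == 3L) x[, , idx, drop = FALSE]
  else if (nd == 4L) x[, , , idx, drop = FALSE]
  else x[, idx, drop = FALSE]
}

batch_size_of <- function(x) dim(x)[length(dim(x))]

#' Class probabilities from a trained network
#'
#' Runs the network in evaluation mode (dropout disabled) and returns
#' softmax probabilities. Inputs are processed in chunks to bound memory.
#'
#' @param model An `nn_model`.
#' @param x Channel-first input batch: `(1, length, n)` for 1-D models,
#'   `(1, side, side, n)` for 2-D models.
#' @param chunk Samples per forward chunk.
#' @return Matrix `n x K` of class probabilities (rows sum to 1).
#' @export
nn_predict_probs <- function(model, x, chunk = 200L) {
  n <- batch_size_of(x)
  out <- matrix(NA_real_, n, model$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    logits <- nn_forward(model, batch_slice(x, idx), training = FALSE)$out
    out[idx, ] <- t(softmax_mat(logits))
  }
  out
}

#' Predicted class labels from a trained network
#'
#' @inheritParams nn_predict_probs
#' @return Integer labels in `1..K`; ties resolve to the lower class index.
#' @export
nn_predict <- function(model, x, chunk = 200L) {
  max.col(nn_predict_probs(model, x, chunk), ties.method = "first")
}

# ---- flat parameter access (used by the finite-difference gradient check) --

nn_get_params <- function(model) {
  unlist(lapply(model$layers, function(ly) {
    if (is.null(ly$W)) NULL else c(as.vector(ly$W), ly$b)
  }))
}

nn_set_params <- function(model, theta) {
  pos <- 0L
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (is.null(ly$W)) next
    nw <- length(ly$W); nb <- length(ly$b)
    model$layers[[i]]$W[] <- theta[pos + seq_len(nw)]
    model$layers[[i]]$b <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  stopifnot(pos == length(theta))
  model
}

nn_get_grads_flat <- function(model, grads) {
  unlist(lapply(seq_along(model$layers), function(i) {
    g <- grads[[i]]
    if (is.null(g)) NULL else c(as.vector(g$dW), g$db)
  }))
}
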