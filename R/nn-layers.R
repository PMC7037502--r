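# Mathematical core of the networks: convolution, ReLU, pooling, softmax,
# dense layers and dropout, each with an explicit backward pass. Batched
# activations are stored channel-first: 1-D data as (channels, length, batch)
# arrays, 2-D data as (channels, height, width, batch). Convolutions are
# cross-correlations (no kernel flip) with stride 1 and no padding; the
# heavy lifting goes through im2col + BLAS matrix products.

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`, the activation used throughout the networks.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries replaced by zero.
#' @examples
#' relu(c(-2, 0, 3))
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Softmax normalization
#'
#' Maps a vector of real scores to a probability distribution
#' `exp(v_i) / sum_j exp(v_j)`, computed with the max-shift trick so
#' arbitrarily large scores do not overflow.
#'
#' @param v Finite numeric vector (length >= 1).
#' @return Probability vector of the same length: entries in (0, 1),
#'   summing to 1, with the argmax preserved.
#' @examples
#' softmax(c(1, 2, 3))
#' @export
softmax <- function(v) {
  if (length(v) == 0L) abort("`v` must be a non-empty numeric vector.")
  if (!all(is.finite(v))) abort("`v` must be finite.")
  e <- exp(v - max(v))
  e / sum(e)
}

# Column-wise softmax of a (K, B) score matrix.
softmax_mat <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' One-dimensional valid convolution
#'
#' Slides each kernel over the input with stride 1 and no padding, producing
#' one feature map per kernel: `y_i(t) = f(sum_x a[t + x - 1] w_i[x] + b_i)`.
#'
#' @param x Numeric input vector.
#' @param kernels Numeric vector (one kernel) or matrix with one kernel per
#'   row, each of width `m <= length(x)`.
#' @param bias Per-kernel bias, recycled to the number of kernels.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return Matrix of feature maps, `n_kernels` rows by `length(x) - m + 1`
#'   columns.
#' @examples
#' conv1d(c(1, 2, 3, 4), c(1, 0, 0), activation = "identity")
#' @export
conv1d <- function(x, kernels, bias = 0, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (is.vector(kernels)) kernels <- matrix(kernels, nrow = 1L)
  m <- ncol(kernels)
  if (m < 1L) abort("Kernel width must be >= 1.")
  if (length(x) < m) {
    abort(sprintf("Input (length %d) is shorter than the kernel (width %d).",
                  length(x), m))
  }
  idx <- conv1d_index(1L, length(x), m)
  xcol <- matrix(x[idx], nrow = m)          # (m, out_len)
  y <- kernels %*% xcol + rep(bias, length.out = nrow(kernels))
  if (activation == "relu") y <- relu(y)
  y
}

#' Two-dimensional valid convolution
#'
#' `y_i(r, c) = f(sum_{x,y} a[r + x - 1, c + y - 1] w_i[x, y] + b_i)` with
#' stride 1 and no padding.
#'
#' @param x Numeric input matrix.
#' @param kernels A single kernel matrix, or a list of kernel matrices of a
#'   common size.
#' @param bias Per-kernel bias, recycled.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return For one kernel, the output matrix of size
#'   `(nrow(x) - m + 1) x (ncol(x) - n + 1)`; for several, a list of them.
#' @examples
#' conv2d(matrix(1, 3, 3), matrix(1, 2, 2), activation = "identity")
#' @export
conv2d <- function(x, kernels, bias = 0, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  single <- !is.list(kernels)
  if (single) kernels <- list(kernels)
  kh <- nrow(kernels[[1L]]); kw <- ncol(kernels[[1L]])
  if (any(!vapply(kernels, function(k) all(dim(k) == c(kh, kw)), logical(1L)))) {
    abort("All kernels must share the same dimensions.")
  }
  if (nrow(x) < kh || ncol(x) < kw) {
    abort(sprintf("Kernel (%d x %d) is larger than the input (%d x %d).",
                  kh, kw, nrow(x), ncol(x)))
  }
  oh <- nrow(x) - kh + 1L
  ow <- ncol(x) - kw + 1L
  idx <- conv2d_index(1L, nrow(x), ncol(x), kh, kw)
  xcol <- matrix(x[idx], nrow = kh * kw)    # (kh*kw, oh*ow)
  W <- do.call(rbind, lapply(kernels, as.vector))   # rows: kernels, ch-major
  y <- W %*% xcol + rep(bias, length.out = length(kernels))
  if (activation == "relu") y <- relu(y)
  out <- lapply(seq_len(nrow(y)), function(i) matrix(y[i, ], oh, ow))
  if (single) out[[1L]] else out
}

#' Non-overlapping pooling
#'
#' Downsamples by taking the maximum or mean over consecutive windows of
#' width `w` (stride equal to `w`). A trailing remainder shorter than `w`
#' is dropped with a warning. Applied along a vector, or over `w x w`
#' blocks of a matrix.
#'
#' @param x Numeric vector (1-D feature map) or matrix (2-D feature map).
#' @param w Window width, integer >= 1. `w = 1` is the identity.
#' @param mode `"max"` (default) or `"avg"`.
#' @return The downsampled vector or matrix.
#' @examples
#' pool(c(1, 3, 2, 8), 2)
#' @export
pool <- function(x, w, mode = c("max", "avg")) {
  mode <- match.arg(mode)
  w <- as.integer(w)
  if (is.na(w) || w < 1L) abort("Pool width `w` must be an integer >= 1.")
  if (is.matrix(x)) {
    arr <- array(x, c(1L, nrow(x), ncol(x), 1L))
    out <- pool2d_forward(arr, w, mode)$out
    return(matrix(out, dim(out)[2L], dim(out)[3L]))
  }
  arr <- array(x, c(1L, length(x), 1L))
  as.vector(pool1d_forward(arr, w, mode)$out)
}

# ---- im2col index construction -------------------------------------------

# Linear indices into a (C, L) activation block selecting, for every output
# position, the (channel, offset) window entries in the order matching the
# weight layout (channel fastest, then kernel offset).
conv1d_index <- function(C, L, m) {
  out_len <- L - m + 1L
  offs <- as.vector(outer(seq_len(C), (seq_len(m) - 1L) * C, "+"))
  as.vector(outer(offs, (seq_len(out_len) - 1L) * C, "+"))
}

# Same for a (C, H, W) block with a (kh, kw) kernel; weight layout is
# channel fastest, then kernel row, then kernel column.
conv2d_index <- function(C, H, W, kh, kw) {
  oh <- H - kh + 1L
  ow <- W - kw + 1L
  offs <- as.vector(outer(
    as.vector(outer(seq_len(C), (seq_len(kh) - 1L) * C, "+")),
    (seq_len(kw) - 1L) * C * H, "+"))
  shifts <- as.vector(outer((seq_len(oh) - 1L) * C,
                            (seq_len(ow) - 1L) * C * H, "+"))
  as.vector(outer(offs, shifts, "+"))
}

# ---- batched layer engines -----------------------------------------------

# x: (C, L, B); W: (M, C*m); b: length M. Returns activations before the
# nonlinearity plus the im2col matrix needed for the backward pass.
conv1d_forward <- function(x, W, b, idx, out_len) {
  d <- dim(x)
  B <- d[3L]
  xm <- matrix(x, d[1L] * d[2L], B)
  xcol <- xm[idx, , drop = FALSE]
  dim(xcol) <- c(length(idx) %/% out_len, out_len * B)
  y <- W %*% xcol + b
  dim(y) <- c(nrow(W), out_len, B)
  list(out = y, xcol = xcol)
}

conv1d_backward <- function(dout, xcol, W, idx, in_dim, need_dx = TRUE) {
  M <- dim(dout)[1L]; out_len <- dim(dout)[2L]; B <- dim(dout)[3L]
  dm <- matrix(dout, M, out_len * B)
  dW <- tcrossprod(dm, xcol)
  db <- rowSums(dm)
  dx <- NULL
  if (need_dx) {
    dxcol <- crossprod(W, dm)                   # (C*m, out_len*B)
    dim(dxcol) <- c(length(idx), B)
    acc <- rowsum(dxcol, group = idx)           # sorted unique idx
    dx <- matrix(0, in_dim[1L] * in_dim[2L], B)
    dx[as.integer(rownames(acc)), ] <- acc
    dim(dx) <- c(in_dim[1L], in_dim[2L], B)
  }
  list(dx = dx, dW = dW, db = db)
}

# x: (C, H, W, B); weights (M, C*kh*kw).
conv2d_forward <- function(x, W, b, idx, oh, ow) {
  d <- dim(x)
  B <- d[4L]
  xm <- matrix(x, prod(d[1:3]), B)
  xcol <- xm[idx, , drop = FALSE]
  dim(xcol) <- c(length(idx) %/% (oh * ow), oh * ow * B)
  y <- W %*% xcol + b
  dim(y) <- c(nrow(W), oh, ow, B)
  list(out = y, xcol = xcol)
}

conv2d_backward <- function(dout, xcol, W, idx, in_dim, need_dx = TRUE) {
  d <- dim(dout)
  M <- d[1L]; B <- d[4L]
  dm <- matrix(dout, M, d[2L] * d[3L] * B)
  dW <- tcrossprod(dm, xcol)
  db <- rowSums(dm)
  dx <- NULL
  if (need_dx) {
    dxcol <- crossprod(W, dm)
    dim(dxcol) <- c(length(idx), B)
    acc <- rowsum(dxcol, group = idx)
    dx <- matrix(0, prod(in_dim[1:3]), B)
    dx[as.integer(rownames(acc)), ] <- acc
    dim(dx) <- c(in_dim[1L], in_dim[2L], in_dim[3L], B)
  }
  list(dx = dx, dW = dW, db = db)
}

# x: (C, L, B); non-overlapping windows of width w, remainder truncated.
pool1d_forward <- function(x, w, mode) {
  d <- dim(x)
  C <- d[1L]; L <- d[2L]; B <- d[3L]
  Lo <- L %/% w
  xt <- if (Lo * w == L) x else x[, seq_len(Lo * w), , drop = FALSE]
  arr <- array(xt, c(C, w, Lo, B))
  if (mode == "avg") {
    out <- arr[, 1L, , , drop = FALSE]
    if (w > 1L) for (k in 2:w) out <- out + arr[, k, , , drop = FALSE]
    out <- array(out / w, c(C, Lo, B))
    return(list(out = out, argmax = NULL, in_dim = d))
  }
  out <- array(arr[, 1L, , , drop = FALSE], c(C, Lo, B))
  argk <- array(1L, c(C, Lo, B))
  if (w > 1L) {
    for (k in 2:w) {
      cand <- array(arr[, k, , , drop = FALSE], c(C, Lo, B))
      upd <- cand > out
      out[upd] <- cand[upd]
      argk[upd] <- k
    }
  }
  list(out = out, argmax = argk, in_dim = d)
}

pool1d_backward <- function(dout, w, mode, argmax, in_dim) {
  C <- in_dim[1L]; L <- in_dim[2L]; B <- in_dim[3L]
  Lo <- dim(dout)[2L]
  dx <- array(0, c(C, w * Lo, B))
  if (mode == "avg") {
    darr <- array(0, c(C, w, Lo, B))
    for (k in seq_len(w)) darr[, k, , ] <- dout / w
    dx <- array(darr, c(C, w * Lo, B))
  } else {
    # linear index of (c, argk, o, b) inside the (C, w, Lo, B) array
    base <- array(0, c(C, Lo, B))
    cs <- slice.index(base, 1L); os <- slice.index(base, 2L)
    bs <- slice.index(base, 3L)
    lin <- cs + (argmax - 1L) * C + (os - 1L) * C * w +
      (bs - 1L) * C * w * Lo
    darr <- numeric(C * w * Lo * B)
    darr[as.vector(lin)] <- as.vector(dout)
    dx <- array(darr, c(C, w * Lo, B))
  }
  if (w * Lo < L) {
    full <- array(0, c(C, L, B))
    full[, seq_len(w * Lo), ] <- dx
    dx <- full
  }
  dx
}

# x: (C, H, W, B); square w x w blocks.
pool2d_forward <- function(x, w, mode) {
  d <- dim(x)
  C <- d[1L]; H <- d[2L]; Wd <- d[3L]; B <- d[4L]
  Ho <- H %/% w; Wo <- Wd %/% w
  xt <- x[, seq_len(Ho * w), seq_len(Wo * w), , drop = FALSE]
  arr <- array(xt, c(C, w, Ho, w, Wo, B))
  if (mode == "avg") {
    out <- array(0, c(C, Ho, Wo, B))
    for (k1 in seq_len(w)) for (k2 in seq_len(w)) {
      out <- out + array(arr[, k1, , k2, , , drop = FALSE], c(C, Ho, Wo, B))
    }
    return(list(out = out / (w * w), argmax = NULL, in_dim = d))
  }
  out <- array(arr[, 1L, , 1L, , , drop = FALSE], c(C, Ho, Wo, B))
  argk <- array(1L, c(C, Ho, Wo, B))     # encodes (k1, k2) as k1 + (k2-1)*w
  for (k1 in seq_len(w)) for (k2 in seq_len(w)) {
    if (k1 == 1L && k2 == 1L) next
    cand <- array(arr[, k1, , k2, , , drop = FALSE], c(C, Ho, Wo, B))
    upd <- cand > out
    out[upd] <- cand[upd]
    argk[upd] <- k1 + (k2 - 1L) * w
  }
  list(out = out, argmax = argk, in_dim = d)
}

pool2d_backward <- function(dout, w, mode, argmax, in_dim) {
  C <- in_dim[1L]; H <- in_dim[2L]; Wd <- in_dim[3L]; B <- in_dim[4L]
  Ho <- dim(dout)[2L]; Wo <- dim(dout)[3L]
  darr <- array(0, c(C, w, Ho, w, Wo, B))
  if (mode == "avg") {
    for (k1 in seq_len(w)) for (k2 in seq_len(w)) {
      darr[, k1, , k2, , ] <- dout / (w * w)
    }
  } else {
    k1 <- (argmax - 1L) %% w + 1L
    k2 <- (argmax - 1L) %/% w + 1L
    base <- array(0, c(C, Ho, Wo, B))
    cs <- slice.index(base, 1L); o1 <- slice.index(base, 2L)
    o2 <- slice.index(base, 3L); bs <- slice.index(base, 4L)
    lin <- cs + (k1 - 1L) * C + (o1 - 1L) * C * w +
      (k2 - 1L) * (C * w * Ho) + (o2 - 1L) * (C * w * Ho * w) +
      (bs - 1L) * (C * w * Ho * w * Wo)
    dv <- numeric(C * w * Ho * w * Wo * B)
    dv[as.vector(lin)] <- as.vector(dout)
    darr <- array(dv, c(C, w, Ho, w, Wo, B))
  }
  dx <- array(darr, c(C, w * Ho, w * Wo, B))
  if (w * Ho < H || w * Wo < Wd) {
    full <- array(0, c(C, H, Wd, B))
    full[, seq_len(w * Ho), seq_len(w * Wo), ] <- dx
    dx <- full
  }
  dx
}
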