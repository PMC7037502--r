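# PLS-DA baseline: PLS2 regression of the (mean-centered) feature-segment
# matrix onto the one-hot class indicator matrix, with an argmax decision
# rule over the fitted class responses. The latent decomposition is
# delegated to mixOmics; prediction takes the raw fitted indicator
# responses and applies the argmax itself (ties to the lower class index).

#' Fit a PLS-DA classifier
#'
#' @param x Numeric feature matrix (samples x variables), typically the
#'   preprocessed feature-segment spectra.
#' @param labels Integer class labels in `1..K` (K >= 2).
#' @param n_components Number of latent variables (default 7).
#' @return A `plsda_fit`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 3), 10))
#' fit <- fit_plsda(x, rep(1:2, each = 10), n_components = 1)
#' @export
fit_plsda <- function(x, labels, n_components = 7L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  n_components <- as.integer(n_components)
  K <- max(labels)
  if (n_components < 1L) abort("`n_components` must be >= 1.")
  if (K < 2L) abort("PLS-DA needs at least 2 classes.")
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    abort(sprintf(
      "`n_components` = %d exceeds min(n_samples - 1, n_features) = %d.",
      n_components, min(nrow(x) - 1L, ncol(x))))
  }
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  model <- mixOmics::plsda(x, factor(labels, levels = seq_len(K)),
                           ncomp = n_components, scale = FALSE)
  structure(list(model = model, n_components = n_components, K = K,
                 n_features = ncol(x)),
            class = "plsda_fit")
}

#' Predict class labels with a fitted PLS-DA model
#'
#' Argmax over the K fitted indicator responses; ties break toward the
#' lower class index.
#'
#' @param fit A `plsda_fit`.
#' @param x New feature matrix with the training column count.
#' @return Integer labels in `1..K`.
#' @export
predict_plsda <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != fit$n_features) {
    abort(sprintf("Model was fit on %d features; newdata has %d.",
                  fit$n_features, ncol(x)))
  }
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  pr <- predict(fit$model, x, dist = "max.dist")
  resp <- pr$predict[, , fit$n_components, drop = TRUE]
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = 1L)
  max.col(resp, ties.method = "first")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("<plsda_fit> %d classes, %d features, %d latent component(s)\n",
              x$K, x$n_features, x$n_components))
  invisible(x)
}

#' @rdname fit_plsda
#' @param x A `plsda_fit`.
#' @param ... Unused.
#' @export
glance.plsda_fit <- function(x, ...) {
  tibble(n_components = x$n_components, n_classes = x$K,
         n_features = x$n_features,
         explained_x_variance = sum(x$model$prop_expl_var$X))
}

#' @rdname fit_plsda
#' @export
tidy.plsda_fit <- function(x, ...) {
  ld <- x$model$loadings$X
  out <- as_tibble(ld, .name_repair = ~ paste0("comp", seq_len(ncol(ld))))
  out$variable <- rownames(ld)
  tidyr::pivot_longer(out, -"variable", names_to = "component",
                      values_to = "loading")
}

#' Two-dimensional embedding of a spectra matrix
#'
#' `method = "pca"` returns the first two principal-component scores of
#' the column-centered matrix together with their explained-variance
#' fractions; `method = "tsne"` runs a seeded exact t-SNE (perplexity
#' 30, 1000 iterations by default).
#'
#' @param x Numeric matrix (>= 3 samples).
#' @param method `"pca"` or `"tsne"`.
#' @param labels Optional labels attached to the coordinates (used by
#'   the plot method).
#' @param seed Seed for the t-SNE initialization.
#' @param perplexity,max_iter t-SNE settings.
#' @return A tibble with columns `dim1`, `dim2` (and `label` if given),
#'   class `spectra_embedding`; for PCA the attribute
#'   `explained_variance` holds the two variance fractions.
#' @export
embed_2d <- function(x, method = c("pca", "tsne"), labels = NULL,
                     seed = 1L, perplexity = 30, max_iter = 1000L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 3L) abort("Need at least 3 samples to embed.")
  if (method == "pca") {
    if (all(apply(x, 2L, var) == 0)) {
      abort("Constant matrix: PCA variance fractions are undefined.")
    }
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    coords <- tibble(dim1 = pc$x[, 1L], dim2 = pc$x[, 2L])
    attr(coords, "explained_variance") <- ev[1:2]
  } else {
    coords <- tsne_exact(x, seed = seed, perplexity = perplexity,
                         max_iter = max_iter)
    coords <- tibble(dim1 = coords[, 1L], dim2 = coords[, 2L])
  }
  if (!is.null(labels)) coords$label <- labels
  attr(coords, "method") <- method
  class(coords) <- c("spectra_embedding", class(coords))
  coords
}

#' @rdname embed_2d
#' @param object A `spectra_embedding`.
#' @param ... Unused.
#' @export
autoplot.spectra_embedding <- function(object, ...) {
  method <- attr(object, "method")
  ev <- attr(object, "explained_variance")
  lab <- if (method == "pca" && !is.null(ev)) {
    c(sprintf("PC1 (%.1f%%)", 100 * ev[1L]),
      sprintf("PC2 (%.1f%%)", 100 * ev[2L]))
  } else {
    c("t-SNE 1", "t-SNE 2")
  }
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$dim1, y = .data$dim2))
  p <- if ("label" %in% names(object)) {
    p + ggplot2::geom_point(ggplot2::aes(color = factor(.data$label)),
                            size = 1, alpha = 0.8) +
      ggplot2::labs(color = "Class")
  } else {
    p + ggplot2::geom_point(size = 1, alpha = 0.8)
  }
  p + ggplot2::labs(x = lab[1L], y = lab[2L]) + ggplot2::theme_minimal()
}

# ---- exact t-SNE -----------------------------------------------------------
# Quadratic-time t-SNE (adequate for the few thousand spectra handled
# here; no installed R package provides it). Perplexity calibration by
# bisection on the per-point Gaussian precision, early exaggeration, and
# momentum gradient descent with adaptive gains.

tsne_exact <- function(x, seed = 1L, perplexity = 30, max_iter = 1000L,
                       learning_rate = 100, momentum_start = 0.5,
                       momentum_final = 0.8, exaggeration = 4,
                       exaggeration_iters = 100L) {
  n <- nrow(x)
  if (n - 1 < 3 * perplexity) perplexity <- max(2, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        H <- log(sumP) + beta * sum(di * p) / sumP
        p <- p / sumP
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(derive_seed(seed, 5L))
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * exaggeration
  for (it in seq_len(max_iter)) {
    Pit <- if (it <= exaggeration_iters) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    mom <- if (it < 250) momentum_start else momentum_final
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
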