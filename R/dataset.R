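# The spectra container: an absorbance matrix (samples x wavenumbers) with
# integer class labels, a train/test split flag, the wavenumber axis and
# class names.

#' Wavenumber grid
#'
#' Uniform, strictly increasing axis in cm^-1. The default reproduces the
#' acquisition geometry of the study design this package emulates: 1609
#' points spanning 4000-10000 cm^-1.
#'
#' @param n_points Number of grid points (>= 2).
#' @param wn_min,wn_max First and last wavenumber (cm^-1).
#' @return Numeric vector of class `wavenumber_grid`.
#' @examples
#' g <- wavenumber_grid()
#' range(g); length(g)
#' @export
wavenumber_grid <- function(n_points = 1609L, wn_min = 4000, wn_max = 10000) {
  if (n_points < 2L) abort("`n_points` must be >= 2.")
  if (wn_max <= wn_min) abort("`wn_max` must exceed `wn_min`.")
  structure(seq(wn_min, wn_max, length.out = n_points),
            class = "wavenumber_grid")
}

grid_spacing <- function(grid) {
  d <- diff(grid)
  if (any(d <= 0)) abort("Wavenumber grid must be strictly increasing.")
  if (max(d) - min(d) > 1e-8 * mean(d)) {
    abort("Wavenumber grid must be uniform.")
  }
  mean(d)
}

#' Construct a spectra dataset
#'
#' @param absorbance Numeric matrix, samples in rows, one column per
#'   wavenumber; all entries finite.
#' @param labels Integer class labels in `1..K`.
#' @param split Character vector of `"train"` / `"test"` flags.
#' @param grid A [wavenumber_grid()] whose length matches `ncol(absorbance)`.
#' @param class_names K class names (default `C1..CK`).
#' @param preprocessed Logical: has the derivative preprocessing been
#'   applied?
#' @return A `spectra_dataset`.
#' @export
spectra_dataset <- function(absorbance, labels, split,
                            grid = wavenumber_grid(ncol(absorbance)),
                            class_names = NULL, preprocessed = FALSE) {
  absorbance <- as.matrix(absorbance)
  labels <- as.integer(labels)
  if (nrow(absorbance) != length(labels) ||
      nrow(absorbance) != length(split)) {
    abort("`absorbance`, `labels` and `split` must agree in length.")
  }
  if (!all(is.finite(absorbance))) {
    bad <- which(!apply(is.finite(absorbance), 1L, all))[1L]
    abort(sprintf("Non-finite absorbance values (first offending row: %d).",
                  bad))
  }
  if (ncol(absorbance) != length(grid)) {
    abort(sprintf(
      "Dataset has %d absorbance columns but the grid has %d points.",
      ncol(absorbance), length(grid)))
  }
  K <- if (is.null(class_names)) max(labels) else length(class_names)
  if (any(labels < 1L | labels > K)) {
    abort(sprintf("Labels must lie in 1..%d.", K))
  }
  if (is.null(class_names)) class_names <- paste0("C", seq_len(K))
  if (!all(split %in% c("train", "test"))) {
    abort("`split` entries must be \"train\" or \"test\".")
  }
  structure(list(absorbance = unname(absorbance), labels = labels,
                 split = split, grid = grid, class_names = class_names,
                 preprocessed = isTRUE(preprocessed)),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  tab <- table(x$labels, x$split)
  cat(sprintf(
    "<spectra_dataset> %d spectra x %d points (%.0f-%.0f cm^-1), %d classes%s\n",
    nrow(x$absorbance), ncol(x$absorbance), min(x$grid), max(x$grid),
    length(x$class_names), if (x$preprocessed) ", preprocessed" else ""))
  cat(sprintf("  split: %d train / %d test\n",
              sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$absorbance)

#' Dataset accessors
#'
#' @param ds A [spectra_dataset].
#' @return `n_points()`: columns of the absorbance matrix;
#'   `n_classes()`: number of classes; `n_samples()`: number of spectra.
#' @export
n_points <- function(ds) ncol(ds$absorbance)

#' @rdname n_points
#' @export
n_classes <- function(ds) length(ds$class_names)

#' @rdname n_points
#' @export
n_samples <- function(ds) nrow(ds$absorbance)

#' Subset a dataset by split
#'
#' @param ds A [spectra_dataset].
#' @param split `"train"` or `"test"`.
#' @return The subset as a `spectra_dataset`.
#' @export
dataset_split <- function(ds, split = c("train", "test")) {
  split <- match.arg(split)
  keep <- ds$split == split
  spectra_dataset(ds$absorbance[keep, , drop = FALSE], ds$labels[keep],
                  ds$split[keep], ds$grid, ds$class_names, ds$preprocessed)
}

#' @export
as_tibble.spectra_dataset <- function(x, ...) {
  out <- as_tibble(x$absorbance, .name_repair = ~ paste0(
    "wavenumber_", seq_len(ncol(x$absorbance))))
  out$label <- x$labels
  out$split <- x$split
  out
}

#' @rdname spectra_dataset
#' @param object A `spectra_dataset`.
#' @param n_per_class Spectra drawn per class for the plot.
#' @param ... Unused.
#' @export
autoplot.spectra_dataset <- function(object, n_per_class = 3L, ...) {
  idx <- unlist(lapply(seq_along(object$class_names), function(k) {
    head(which(object$labels == k), n_per_class)
  }))
  df <- purrr::map_dfr(idx, function(i) {
    tibble(wavenumber = as.numeric(object$grid),
           absorbance = object$absorbance[i, ],
           class = object$class_names[object$labels[i]],
           sample = i)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber,
                                   y = .data$absorbance,
                                   group = .data$sample,
                                   color = .data$class)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::labs(x = "Wavenumber (cm⁻¹)",
                  y = if (object$preprocessed)
                    "1st derivative absorbance" else "Absorbance",
                  color = "Origin") +
    ggplot2::theme_minimal()
}
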