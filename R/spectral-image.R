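# 1-D spectra -> square 2-D images by row-major prefix reshaping: points
# 1..n go into the first image row, points n+1..2n into the second, and
# so on; surplus trailing points are discarded. On the default 1609-point
# grid the full-spectrum case drops the last 9 points and yields a 40x40
# image; shrinking the window from the high-wavenumber side gives the
# 38x38 ... 26x26 feature-segment series (32x32 consumes the first 1024
# points, about 4000-7740 cm^-1).

#' Reshape a spectrum prefix into a square image
#'
#' Consumes exactly the first `n^2` points of the spectrum, filling the
#' image row by row (row r holds points `(r-1)*n + 1 .. r*n`); trailing
#' surplus points are discarded.
#'
#' @param spectrum Numeric vector with at least `n^2` points.
#' @param n Image side length.
#' @return A `spectral_image`: an `n x n` matrix with attribute
#'   `source_range = c(1, n^2)`.
#' @examples
#' vector_to_image(1:16, 4)
#' @export
vector_to_image <- function(spectrum, n) {
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  if (length(spectrum) < n^2) {
    abort(sprintf("Spectrum has %d points; %d (= %d^2) required.",
                  length(spectrum), n^2, n))
  }
  img <- matrix(spectrum[seq_len(n^2)], n, n, byrow = TRUE)
  structure(img, class = c("spectral_image", class(img)),
            source_range = c(1L, n^2))
}

#' Flatten a spectral image back to the consumed prefix
#'
#' Inverse of [vector_to_image()] on the consumed prefix:
#' `image_to_vector(vector_to_image(v, n))` equals `v[1:n^2]`.
#'
#' @param img A `spectral_image` (or any matrix, read row-major).
#' @return Numeric vector of length `n^2`.
#' @export
image_to_vector <- function(img) {
  as.vector(t(unclass(img)))
}

#' Feature-segment image from the low-wavenumber end
#'
#' Takes the first `n^2` points counted from the low-wavenumber
#' (4000 cm^-1) end — shrinking the window truncates the noisy
#' high-wavenumber tail — and reshapes them row-major. The retained
#' wavenumber range is looked up on the grid rather than hard-coded.
#'
#' @param spectrum Numeric vector.
#' @param grid Matching [wavenumber_grid()].
#' @param n Side length; the supported interception series is the even
#'   sides 26..40 (other values work but warn).
#' @return A `spectral_image` with attribute `wavenumber_range`, the
#'   approximate retained range in cm^-1.
#' @export
feature_segment_image <- function(spectrum,
                                  grid = wavenumber_grid(length(spectrum)),
                                  n = 32L) {
  n <- as.integer(n)
  if (!n %in% seq(26L, 40L, by = 2L)) {
    warn(sprintf(
      "Side %d is outside the supported interception series 26, 28, ..., 40.",
      n))
  }
  if (length(spectrum) != length(grid)) {
    abort("`spectrum` and `grid` lengths differ.")
  }
  img <- vector_to_image(spectrum, n)
  attr(img, "wavenumber_range") <- c(grid[1L], grid[n^2])
  img
}

#' Convert a whole dataset into labeled spectral images
#'
#' One image per sample; labels and split flags are preserved. Pixel
#' values are the preprocessed spectra, min-max scaled to `[0, 1]` over
#' the whole dataset (`scale = FALSE` keeps raw values).
#'
#' @param ds A (preprocessed) [spectra_dataset].
#' @param n Image side length.
#' @param scale Min-max scale pixels to `[0, 1]` per dataset.
#' @return An `image_dataset`: list with `pixels` (array `n x n x
#'   n_samples`), `labels`, `split`, `side`, `wavenumber_range`.
#' @export
image_dataset <- function(ds, n = 32L, scale = TRUE) {
  n <- as.integer(n)
  if (n^2 > n_points(ds)) {
    abort(sprintf("Side %d needs %d points; dataset has %d.",
                  n, n^2, n_points(ds)))
  }
  seg <- ds$absorbance[, seq_len(n^2), drop = FALSE]
  if (scale) {
    rng <- range(seg)
    if (rng[2L] > rng[1L]) seg <- (seg - rng[1L]) / (rng[2L] - rng[1L])
  }
  # row i of seg, reshaped row-major, becomes image i
  pixels <- aperm(array(t(seg), c(n, n, nrow(seg))), c(2L, 1L, 3L))
  structure(list(pixels = pixels, labels = ds$labels, split = ds$split,
                 side = n, class_names = ds$class_names,
                 wavenumber_range = c(ds$grid[1L], ds$grid[n^2])),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf(
    "<image_dataset> %d images of %d x %d (approx. %.0f-%.0f cm^-1)\n",
    dim(x$pixels)[3L], x$side, x$side,
    x$wavenumber_range[1L], x$wavenumber_range[2L]))
  invisible(x)
}

#' @rdname image_dataset
#' @param object An `image_dataset`.
#' @param sample Index of the image to draw.
#' @param ... Unused.
#' @export
autoplot.image_dataset <- function(object, sample = 1L, ...) {
  img <- object$pixels[, , sample]
  df <- tidyr::expand_grid(row = seq_len(nrow(img)),
                           col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Spectral image, sample %d (class %s)", sample,
                      object$class_names[object$labels[sample]]),
      x = NULL, y = NULL, fill = "Intensity") +
    ggplot2::theme_minimal()
}
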