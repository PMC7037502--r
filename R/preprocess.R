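# Savitzky-Golay derivative preprocessing: smoothing and differentiation
# in one local least-squares polynomial fit (window 9, polynomial order 3,
# first derivative by default), applied per spectrum with respect to
# wavenumber. At the boundaries the polynomial is fitted on the window
# anchored inside the data, so no values outside the measured range are
# fabricated and the output length equals the input length.

#' Savitzky-Golay filter parameters
#'
#' @param window Odd moving-window width >= 3.
#' @param polyorder Order of the local polynomial (>= 1, < window).
#' @param deriv Derivative order (0 = smoothing only; <= polyorder).
#' @return An `sg_params` list.
#' @export
sg_params <- function(window = 9L, polyorder = 3L, deriv = 1L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window < 3L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 3.")
  }
  if (polyorder < 1L || polyorder >= window) {
    abort("`polyorder` must satisfy 1 <= polyorder < window.")
  }
  if (deriv < 0L || deriv > polyorder) {
    abort("`deriv` must satisfy 0 <= deriv <= polyorder.")
  }
  structure(list(window = window, polyorder = polyorder, deriv = deriv),
            class = "sg_params")
}

sg_filter_matrix <- function(params, spacing) {
  signal::sgolay(p = params$polyorder, n = params$window, m = params$deriv,
                 ts = spacing)
}

#' Savitzky-Golay derivative of a single spectrum
#'
#' Computes the least-squares local-polynomial derivative with respect to
#' wavenumber (units: absorbance x cm for the first derivative), exact
#' for polynomials up to `polyorder`. Output length equals input length.
#'
#' @param spectrum Numeric absorbance vector, at least `window` long.
#' @param grid Uniform [wavenumber_grid()] matching the spectrum.
#' @param params An [sg_params()].
#' @return Numeric derivative vector of the same length.
#' @examples
#' g <- wavenumber_grid(101)
#' d <- sg_derivative(0.001 * as.numeric(g), g)
#' range(d)  # constant slope recovered everywhere
#' @export
sg_derivative <- function(spectrum, grid = wavenumber_grid(length(spectrum)),
                          params = sg_params()) {
  if (length(spectrum) != length(grid)) {
    abort("`spectrum` and `grid` lengths differ.")
  }
  if (length(spectrum) < params$window) {
    abort(sprintf("Spectrum (length %d) is shorter than the window (%d).",
                  length(spectrum), params$window))
  }
  h <- grid_spacing(grid)
  as.vector(signal::sgolayfilt(spectrum, sg_filter_matrix(params, h)))
}

#' Apply the derivative preprocessing to a whole dataset
#'
#' Row-wise [sg_derivative()]; labels, split and grid are untouched.
#' Because the first derivative annihilates constants, additive baseline
#' offsets are removed: a dataset shifted by a constant per spectrum
#' preprocesses to the same output.
#'
#' @param ds A [spectra_dataset].
#' @param params An [sg_params()].
#' @return The preprocessed `spectra_dataset` (`preprocessed = TRUE`).
#' @export
preprocess_dataset <- function(ds, params = sg_params()) {
  h <- grid_spacing(ds$grid)
  Fm <- sg_filter_matrix(params, h)
  out <- t(apply(ds$absorbance, 1L, function(r) signal::sgolayfilt(r, Fm)))
  res <- spectra_dataset(out, ds$labels, ds$split, ds$grid, ds$class_names,
                         preprocessed = TRUE)
  res$config <- ds$config
  res$sg_params <- params
  res
}
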