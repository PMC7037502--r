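# Synthetic NIR spectra with the statistical structure of a multi-origin
# plant-material study: every class (origin) has its own set of Gaussian
# absorption bands on top of bands shared by all classes and a smooth
# baseline; each recorded spectrum is the mean of a few replicate scans,
# each perturbed by baseline drift (random offset + slope) and white
# noise. The default design is 13 origins x 400 samples with a 320/80
# train/test split per origin.

#' Synthetic study configuration
#'
#' @param n_classes Number of origins K.
#' @param samples_per_class Spectra per origin.
#' @param train_per_class Training spectra per origin (the remainder is
#'   the test split).
#' @param n_replicates Replicate scans averaged into each spectrum.
#' @param n_points Points on the wavenumber grid.
#' @param bands_per_class Class-specific Gaussian absorption bands.
#' @param shared_band_count Bands common to every class (controls the
#'   overlap between origins).
#' @param band_amplitude_range,band_width_range Uniform ranges for band
#'   amplitude (absorbance units) and width (Gaussian sigma, cm^-1).
#' @param band_center_range Range (cm^-1) from which band centers are
#'   drawn; the default keeps the discriminative bands inside the
#'   high signal-to-noise 4000-7740 cm^-1 segment.
#' @param baseline_slope_sd,baseline_offset_sd Standard deviations of the
#'   per-replicate linear baseline drift (slope over the full range, and
#'   offset).
#' @param noise_sd Standard deviation of the per-point replicate noise.
#' @param separability Scalar >= 0 multiplying the class-specific band
#'   amplitudes; 0 makes all class templates identical.
#' @param mixture_components Sub-populations per class. With the default
#'   1 each class is unimodal; larger values give each class several
#'   independently drawn band sets (samples cycle through them), a
#'   nonlinear band-position structure that a linear classifier cannot
#'   separate by class means.
#' @param seed Integer seed; a fixed seed yields byte-identical datasets.
#' @return A `synth_config`.
#' @examples
#' cfg <- synth_config(n_classes = 3, samples_per_class = 10,
#'                     train_per_class = 8)
#' @export
synth_config <- function(n_classes = 13L, samples_per_class = 400L,
                         train_per_class = 320L, n_replicates = 3L,
                         n_points = 1609L, bands_per_class = 6L,
                         shared_band_count = 8L,
                         band_amplitude_range = c(0.05, 0.35),
                         band_width_range = c(40, 200),
                         band_center_range = c(4100, 7600),
                         baseline_slope_sd = 0.05,
                         baseline_offset_sd = 0.02,
                         noise_sd = 0.02, separability = 1,
                         mixture_components = 1L, seed = 1L) {
  n_classes <- as.integer(n_classes)
  samples_per_class <- as.integer(samples_per_class)
  train_per_class <- as.integer(train_per_class)
  if (n_classes < 1L) abort("`n_classes` must be positive.")
  if (samples_per_class < 1L) abort("`samples_per_class` must be positive.")
  if (train_per_class < 1L || train_per_class >= samples_per_class) {
    abort("`train_per_class` must satisfy 0 < train < samples_per_class.")
  }
  if (n_replicates < 1L) abort("`n_replicates` must be >= 1.")
  if (noise_sd < 0 || baseline_slope_sd < 0 || baseline_offset_sd < 0) {
    abort("Standard deviations must be >= 0.")
  }
  if (separability < 0) abort("`separability` must be >= 0.")
  if (mixture_components < 1L) abort("`mixture_components` must be >= 1.")
  structure(list(n_classes = n_classes,
                 samples_per_class = samples_per_class,
                 train_per_class = train_per_class,
                 n_replicates = as.integer(n_replicates),
                 n_points = as.integer(n_points),
                 bands_per_class = as.integer(bands_per_class),
                 shared_band_count = as.integer(shared_band_count),
                 band_amplitude_range = band_amplitude_range,
                 band_width_range = band_width_range,
                 band_center_range = band_center_range,
                 baseline_slope_sd = baseline_slope_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 noise_sd = noise_sd, separability = separability,
                 mixture_components = as.integer(mixture_components),
                 seed = as.integer(seed)),
            class = "synth_config")
}

gaussian_band <- function(x, center, sigma, amplitude) {
  amplitude * exp(-(x - center)^2 / (2 * sigma^2))
}

draw_bands <- function(n, cfg) {
  # one runif call per property keeps the draw order stable
  list(center = runif(n, cfg$band_center_range[1L], cfg$band_center_range[2L]),
       sigma = runif(n, cfg$band_width_range[1L], cfg$band_width_range[2L]),
       amplitude = runif(n, cfg$band_amplitude_range[1L],
                         cfg$band_amplitude_range[2L]))
}

# All band parameters come from one seeded stream; shared bands first, then
# classes in order (each class's mixture components in order), so adding a
# class never perturbs the bands of earlier classes.
template_params <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  shared <- draw_bands(cfg$shared_band_count, cfg)
  classes <- lapply(seq_len(cfg$n_classes), function(k) {
    lapply(seq_len(cfg$mixture_components), function(m) {
      draw_bands(cfg$bands_per_class, cfg)
    })
  })
  list(shared = shared, classes = classes)
}

eval_bands <- function(x, bands) {
  out <- numeric(length(x))
  for (j in seq_along(bands$center)) {
    out <- out + gaussian_band(x, bands$center[j], bands$sigma[j],
                               bands$amplitude[j])
  }
  out
}

# Smooth baseline common to every class (gentle scattering-like trend).
baseline_curve <- function(x) {
  xn <- (x - min(x)) / (max(x) - min(x))
  0.6 + 0.2 * xn + 0.1 * xn^2
}

#' Noise-free class template spectrum
#'
#' The template is the sum of the shared absorption bands, the
#' class-specific bands scaled by `separability`, and a smooth baseline.
#' With `separability = 0` every class has the same template.
#'
#' @param class_id Class index in `1..n_classes`.
#' @param cfg A [synth_config()].
#' @param grid A [wavenumber_grid()]; defaults to the config's grid.
#' @param component Mixture component (for `mixture_components > 1`).
#' @return Numeric absorbance vector along `grid`.
#' @export
class_template <- function(class_id, cfg, grid = NULL, component = 1L) {
  if (class_id < 1L || class_id > cfg$n_classes) {
    abort(sprintf("`class_id` must lie in 1..%d.", cfg$n_classes))
  }
  if (component < 1L || component > cfg$mixture_components) {
    abort(sprintf("`component` must lie in 1..%d.", cfg$mixture_components))
  }
  if (is.null(grid)) grid <- wavenumber_grid(cfg$n_points)
  pars <- template_params(cfg)
  x <- as.numeric(grid)
  baseline_curve(x) + eval_bands(x, pars$shared) +
    cfg$separability * eval_bands(x, pars$classes[[class_id]][[component]])
}

#' Generate a labeled synthetic spectra dataset
#'
#' Every sample is the arithmetic mean of `n_replicates` replicate scans
#' of its class template, each replicate perturbed by a linear baseline
#' drift (random offset and slope) and i.i.d. Gaussian noise. The first
#' `train_per_class` samples of each class form the training split, the
#' remainder the test split. A fixed seed yields byte-identical output.
#'
#' @param cfg A [synth_config()].
#' @return A [spectra_dataset] with
#'   `n_classes * samples_per_class` rows.
#' @examples
#' ds <- generate_dataset(synth_config(n_classes = 2, samples_per_class = 6,
#'                                     train_per_class = 4, n_points = 64))
#' dim(ds)
#' @export
generate_dataset <- function(cfg) {
  if (!inherits(cfg, "synth_config")) abort("`cfg` must be a synth_config.")
  grid <- wavenumber_grid(cfg$n_points)
  x <- as.numeric(grid)
  xn <- (x - mean(x)) / ((max(x) - min(x)) / 2)    # -1..1 for the drift slope
  pars <- template_params(cfg)
  shared_part <- baseline_curve(x) + eval_bands(x, pars$shared)

  set.seed(derive_seed(cfg$seed, 2L))
  p <- cfg$n_points
  n_per <- cfg$samples_per_class
  total <- cfg$n_classes * n_per
  absorbance <- matrix(NA_real_, total, p)
  labels <- rep(seq_len(cfg$n_classes), each = n_per)
  for (k in seq_len(cfg$n_classes)) {
    templates <- lapply(seq_len(cfg$mixture_components), function(m) {
      shared_part + cfg$separability * eval_bands(x, pars$classes[[k]][[m]])
    })
    comp <- rep_len(seq_len(cfg$mixture_components), n_per)
    nrep <- cfg$n_replicates
    offsets <- rnorm(n_per * nrep, 0, cfg$baseline_offset_sd)
    slopes <- rnorm(n_per * nrep, 0, cfg$baseline_slope_sd)
    noise <- matrix(rnorm(p * n_per * nrep, 0, cfg$noise_sd), p)
    for (i in seq_len(n_per)) {
      cols <- (i - 1L) * nrep + seq_len(nrep)
      reps <- templates[[comp[i]]] +
        outer(xn, slopes[cols]) +
        matrix(offsets[cols], p, nrep, byrow = TRUE) +
        noise[, cols, drop = FALSE]
      absorbance[(k - 1L) * n_per + i, ] <- rowMeans(reps)
    }
  }
  split <- rep(c(rep("train", cfg$train_per_class),
                 rep("test", n_per - cfg$train_per_class)), cfg$n_classes)
  ds <- spectra_dataset(absorbance, labels, split, grid)
  ds$config <- cfg
  ds
}
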