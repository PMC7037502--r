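---
title: "Methods: multimodal CNNs for NIR spectral origin classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal CNNs for NIR spectral origin classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specnet)
```

## The problem

Near-infrared (NIR) absorbance spectra of dried, ground plant material
carry overtone and combination bands of C-H, O-H and N-H vibrations.
Material grown in different regions differs subtly and collinearly
across the whole 4000-10000 cm⁻¹ range, so assigning a geographic
origin from a spectrum is a hard multiclass problem: linear
chemometric baselines (PLS-DA) saturate well below perfect accuracy.
specnet implements two convolutional alternatives and the machinery to
compare all three:

* a **1-D CNN family** that consumes the derivative spectrum directly,
* a **2-D CNN** (LeNet-5-style) that consumes the spectrum reshaped
  into a square image,
* a **PLS-DA baseline** on the high signal-to-noise feature segment,

together with Savitzky-Golay derivative preprocessing, PCA/t-SNE
visualization, architecture sweeps, and a synthetic-spectra generator
that emulates a 13-origin study design (the real tobacco spectra the
design mirrors are proprietary, so everything here is exercised on
synthetic data; see "What the generator does and does not emulate").

## Data model and the synthetic generator

A dataset is a samples × wavenumbers absorbance matrix on a uniform
grid of 1609 points spanning 4000-10000 cm⁻¹, with integer origin
labels 1..13 and a fixed train/test split of 320/80 per origin
(`synth_config()` defaults; 13 × 400 = 5,200 spectra).

Each origin k has a noise-free *template*: a smooth baseline (a gentle
quadratic trend emulating scattering), a set of Gaussian absorption
bands shared by all origins, and `bands_per_class` origin-specific
Gaussian bands whose amplitudes are multiplied by `separability`.
Setting `separability = 0` collapses all templates onto one another;
increasing it moves the class means apart linearly. A recorded
spectrum is the arithmetic mean of `n_replicates` (default 3)
replicate scans, each perturbed by a random linear baseline drift
(offset sd 0.02, slope sd 0.05 over the full range) and white noise
(`noise_sd`, default 0.02 absorbance units). Replicate averaging and
the 320/80 split mirror the emulated acquisition protocol.

Defaults for the free shape parameters were fixed once at values
typical for NIR of organic powders: 8 shared and 6 class bands,
amplitudes 0.05-0.35, Gaussian widths 40-200 cm⁻¹, centers drawn from
4100-7600 cm⁻¹. Centering the informative bands in the low-wavenumber
half reflects the physical situation the feature-segment analysis
relies on: the 4000-7740 cm⁻¹ region carries most of the signal while
the high-wavenumber tail is noise-dominated.

`mixture_components > 1` gives each class several independently drawn
band sets and assigns samples to them cyclically. Classes are then
unions of well-separated clusters distinguished by band-*position*
interactions rather than by their means — a deliberately nonlinear
structure on which a linear indicator regression cannot carve class
regions but a CNN can. This is the regime used to probe the expected
CNN > PLS-DA ordering.

The generator is deterministic: one user seed feeds a fixed sub-seed
derivation, band parameters are drawn shared-first then class-by-class
(so adding classes never perturbs earlier ones), and a fixed seed
reproduces the dataset bit for bit.

**Zero-noise semantics.** The generator has three stochastic
sample-level components: point noise (`noise_sd`), drift offset and
drift slope. "Noise-free data" in the tests means all three are set to
0; `noise_sd = 0` alone still leaves baseline drift, which is the
realistic reading of replicate-to-replicate variation.

## Preprocessing

First-derivative Savitzky-Golay filtering with window 9 and
polynomial order 3, the standard chemometric pretreatment: it removes
additive baseline offsets exactly and suppresses smooth drift while
preserving band structure. Smoothing and differentiation are done in
one local least-squares fit (not difference-then-smooth), which makes
the operator linear and exact on polynomials up to order 3 — the
property the tests pin down (cubic data differentiate exactly at
interior points; constants map to zero). The derivative is taken with
respect to wavenumber (absorbance·cm units), using the uniform grid
spacing ≈ 3.73 cm⁻¹. At the spectrum ends the polynomial is fitted on
the window anchored inside the data (the `signal::sgolay` transient
rows), so no values outside the measured range are fabricated and the
output keeps the input length.

## The 1-D CNN family

One *stage* is a valid (no padding, stride 1) cross-correlation of
width `conv_width` with `feature_maps` kernels, ReLU, then
non-overlapping max pooling of width `pool_width`. Kernels are
correlations, not flipped convolutions — the usual CNN convention, and
the summation-over-support form used throughout. A network has 1-5
stages, then two fully connected ReLU layers with dropout 0.5, then a
13-way softmax. The first fully connected layer is the feature-merge
layer and its size *equals* the flattened feature length (final
sequence length × feature maps); the second has the same size. The
reported depth counts hidden plus output layers: `2 · n_stages + 3`,
so the family spans depths 5, 7, 9, 11, 13.

Pooling uses stride = width; when the pooled length is not integral
the trailing remainder is dropped and a warning is emitted, since a
well-formed configuration should have the sampling kernel divide the
post-convolution length. Pooling mode is max (the generic pooling
operator also implements averaging); max pooling is the modern default
and matches the feature-highlighting role the pooling layer plays
here.

The reference architecture is the depth-11 member (4 stages) with
conv width 15, pool width 2 and M = 24 maps, whose shape trace on a
1609-point input is 1609 → 1595 → 797 → 783 → 391 → 377 → 188 → 174 →
87, giving 87 × 24 = 2088 units in each fully connected layer. The
sweep helpers (`sweep_depth()`, `sweep_kernel()`, `sweep_pool()`,
`sweep_maps()`) vary one structural scalar at a time across all
stages, each run under a deterministic sub-seed.

## Spectral images and the 2-D CNN

`vector_to_image()` consumes the first n² points of a spectrum and
stacks consecutive length-n windows as image rows (row-major). The
full 1609-point spectrum maps to 40 × 40 after dropping the last 9
points. Shrinking the side in steps of 2 down to 26 truncates the
spectrum from the high-wavenumber end only; 32 × 32 consumes exactly
the first 1024 points, approximately 4000-7740 cm⁻¹ — the high-SNR
feature segment. The retained range reported for each side is looked
up on the grid rather than hard-coded. Pixels are the preprocessed
derivative values min-max scaled to [0, 1] per dataset — the
interchange convention for the images themselves. Because derivative
spectra compress into a narrow band around a large constant offset
under min-max scaling (little contrast), the 2-D trainer additionally
standardizes intensities by the training-split mean/sd before the
network sees them, exactly as the 1-D driver standardizes spectra;
without this the fixed-learning-rate SGD stalls.

The 2-D model is a LeNet-5 topology: 6 then 16 valid 5 × 5
convolution kernels, each followed by 2 × 2 max pooling, then fully
connected layers of 120 and 84 units and a K-way softmax head
replacing the original output layer. Two deliberate modernizations:
ReLU activations instead of tanh, and max instead of average
subsampling, keeping the 2-D model consistent with the 1-D family.
The flatten size is recomputed from the valid-convolution arithmetic
for any side ≥ 16 (for 32 × 32: 32 → 28 → 14 → 10 → 5, flatten 400).
After the main training run the softmax head is, by default,
re-initialized and re-fit with the convolutional trunk frozen — a
brand-new single-layer classifier on the extracted features
(`refit = TRUE`).

## Training protocol

Plain mini-batch SGD (no momentum, no schedule) minimizing softmax
cross-entropy: learning rate 0.01, batch size 40, at most 50 epochs,
dropout p = 0.5 on the fully connected layers only (inverted dropout,
so evaluation needs no rescaling). Cross-entropy is the canonical
companion of a softmax likelihood and is adopted explicitly since
nothing else about the loss is constrained.

Early stopping watches a monitored error after every epoch and halts
once it has failed to improve for 5 consecutive epochs (patience
chosen here; only the turn-up criterion itself is inherent to the
protocol), returning the weights of the best monitored epoch, not the
last. The monitored set is, by default, a class-stratified 20%
carve-out of the training split. A `monitor = "test"` mode instead
watches the test split itself — some published protocols do exactly
that, but it leaks test information into the stopping rule, so it is
opt-in and clearly labelled.

Weights start from a zero-mean uniform distribution scaled by
1/√fan_in with bound √(6/fan_in) (He-style uniform); biases start at
zero. With the small bound 1/√fan_in the deeper family members barely
move in 50 epochs at the fixed learning rate — activation variance
decays geometrically through the stack — so the variance-preserving
bound is used. For the same reason the 1-D driver standardizes input
spectra by the global mean/sd of the training split: S-G derivative
magnitudes are ~10⁻³ and would otherwise stall SGD at lr 0.01. Both
choices are initialization/conditioning decisions of this package,
recorded here because the protocol's fixed learning rate makes them
load-bearing.

Everything stochastic (initialization, shuffling, dropout, validation
carving) derives from one seed, so a training history is exactly
reproducible.

## PLS-DA baseline and embeddings

PLS-DA regresses the mean-centered feature-segment matrix (the first
1024 points, matching the 32 × 32 image) on the one-hot class
indicator matrix with 7 latent components (NIPALS PLS2 via mixOmics,
`scale = FALSE`), and classifies by argmax over the K fitted
responses, ties toward the lower class index. The first latent weight
vector equals the dominant singular direction of XᵀY, which the tests
verify against an SVD oracle. An argmax rule is the standard reading
when no threshold rule is specified.

`embed_2d()` provides the two visualization routes: PCA scores with
explained-variance fractions (centered, unscaled), and an exact
O(n²) t-SNE (perplexity 30, 1000 iterations, early exaggeration ×4
for 100 iterations, momentum 0.5→0.8, adaptive gains), written in R
because no t-SNE implementation is otherwise available to the
package; it is seeded and deterministic.

## Evaluation

Accuracy is the percent correct, `P_A = 100 · N_C / N_T`, with a
K × K confusion matrix oriented rows = true class, columns =
predicted, and per-class accuracies; the identity
`P_A = 100 · trace(confusion) / sum(confusion)` is enforced by tests
on every report. `compare_models()` trains the depth-11 1-D CNN, the
32 × 32 2-D CNN and the 7-component PLS-DA under one shared seed and
tabulates the three test accuracies.

## Numerical choices and degenerate inputs

* Convolutions: correlation, stride 1, valid padding; inputs shorter
  than a kernel are a build-time error naming the stage.
* Pooling: stride = width, remainder dropped with a warning; width 1
  is the identity and is a legal configuration.
* Softmax: max-shifted exponentials; log-loss clamps probabilities at
  1e-300 to avoid -Inf on saturated heads.
* Ties in every argmax (prediction, PLS-DA decision) go to the lower
  class index.
* A non-finite loss aborts training with the epoch and batch in the
  message rather than silently continuing.
* Gradient correctness is pinned by central finite differences on
  random parameter subsets of both model families (relative error
  < 1e-4).

## Problem sizes used by the tests and the acceptance script

The full 13 × 400 design is generated where only counting is at
stake (it costs well under a minute). Training-based checks run the
design at reduced per-class size chosen once: 13 × 50 (40 train / 10
test per class) in the test suite and 13 × 40 in the acceptance
script, with low noise (0.005-0.01) and separability 2 for the
separable-recovery runs, and two mixture components for the nonlinear
comparison. At these sizes the depth-11 model trains in a few minutes
on one CPU; the qualitative phenomena (near-ceiling recovery on
separable data, chance level at zero separability, CNN ≥ PLS-DA on
mixtures) are stable across seeds.

## What passing tests do and do not show

The generator produces Gaussian bands, linear drift and white noise;
it does not simulate Fourier-transform instrument physics, water-vapor
interference, detector nonlinearity, scattering (beyond a smooth
trend) or real tobacco chemistry, and band counts/amplitudes are free
parameters rather than calibrated to any material. Green end-to-end
tests therefore demonstrate that the pipeline, optimization and
evaluation machinery are correct and that the models behave as
expected on data with the *statistical shape* of the study design —
they do not certify accuracies on real spectra, which depend on
structure the generator does not model.

## Known limitations

* Plain SGD at a fixed learning rate: convergence on hard mixtures
  can be slow within the 50-epoch budget; no momentum or schedules by
  design.
* The exact t-SNE is quadratic in samples; beyond ~5,000 spectra it
  becomes the dominant cost of `embed_2d()`.
* PLS-DA component count is validated against min(n-1, p), not the
  effective rank; severely collinear inputs can still produce unstable
  trailing components.
* Single-channel inputs only (one spectrum per sample; no multi-sensor
  fusion).
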