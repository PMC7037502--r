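Package: specnet
Title: Multimodal Convolutional Neural Networks for Near-Infrared
    Spectral Origin Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies near-infrared (NIR) spectra of plant material by
    geographic origin with convolutional neural networks trained from
    scratch. Provides a parameterized family of 1-D CNNs operating
    directly on derivative spectra, a spectrum-to-image conversion that
    feeds a LeNet-5-style 2-D CNN, Savitzky-Golay derivative
    preprocessing, a PLS-DA baseline, PCA/t-SNE visualization, and an
    architecture-sweep harness. Includes a synthetic NIR spectra
    generator (Gaussian absorption bands, baseline drift, replicate
    scans) emulating a 13-origin study design so the whole pipeline is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mixOmics,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
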