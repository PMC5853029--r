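Package: focusqc
Title: Absolute Microscope Image Focus Quality from Patch-Level Deep Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for unattended focus-quality control of fluorescence
    microscope images. Implements a physics-based synthetic-defocus engine
    (Bessel-integral point spread functions, Poisson sensor noise, photometric
    augmentation) that manufactures labeled training data from in-focus
    images; an 11-level ordinal convolutional patch classifier trained with a
    ranked probability score loss; entropy-based prediction certainty with
    certainty-weighted whole-image aggregation and the associated
    visualizations; the power log-log slope (PLLS) spectral focus metric as a
    baseline; and an evaluation harness covering binary in/out-of-focus
    classification, absolute-defocus confusion analysis and gain/offset
    robustness grids. A seeded generator of synthetic nuclei-like scenes
    makes the whole pipeline testable without external image collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
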