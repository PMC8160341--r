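Package: retsim
Title: Synthetic Adaptive-Optics Retinal Image Capture with Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end simulation of image capture through an adaptive-optics
    scanning laser ophthalmoscope (AOSLO). Generates self-organised cone
    photoreceptor mosaics by Gray-Scott reaction-diffusion, fixational eye
    movement traces (microsaccades, drift, tremor) with event-level ground
    truth, and synthetic image frames captured through a double-pass confocal
    optical model with residual Zernike aberrations, a sinusoidal raster scan
    with desinusoiding, and additive detector noise. Every frame is paired
    with exact ground truth (cone parameter tables, eye-motion traces,
    wavefront coefficients, noise seed) for testing, training and validating
    retinal image-processing algorithms. Includes cone-packing regularity
    metrics and radially averaged power spectra for validation against real
    cone mosaics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
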