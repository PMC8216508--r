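Package: boutonquant
Title: Quantification of Presynaptic Potentiation at Hippocampal Mossy
    Fiber Boutons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for measuring presynaptic potentiation at large
    hippocampal mossy fiber boutons across three imaging modalities:
    quantification of evoked glutamate transients from high-speed movies of
    a membrane-bound low-affinity glutamate sensor (dF/F, suprathreshold
    active area, cumulative/mean/maximal amplitudes, paired-pulse ratios,
    decay time constants), ordinal-pattern entropy and non-triviality of 2D
    dF/F fields, Cav2.1 to Munc13-1 coupling-distance measurement from
    three-channel gSTED images (Richardson-Lucy deconvolution with a
    Lorentzian point spread function, prominence-gated maxima, Homer-gated
    triads, line-profile peak-to-peak distances), and 3D morphometry of
    serial-section electron-microscopy reconstructions (bouton complexity,
    active-zone and vesicle densities, pairwise dispersion, nearest-neighbor
    distances, docked/tethered vesicle classification, mitochondrial volume
    fraction). Seeded synthetic-data generators emulate all three modalities
    with known ground truth, and a normality-gated group-comparison layer
    reproduces the study's statistical reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    graphics,
    tidyr,
    tiff,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
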