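Package: qpirbc
Title: Quantitative Phase Imaging Pipeline for Red Blood Cell Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of off-axis digital holographic microscopy
    images of red blood cells: Fourier sideband demodulation and discrete
    cosine transform least-squares phase unwrapping, watershed instance
    segmentation of single cells, a 15-feature single-cell quantification
    scheme (phase-shift statistics, 2-D morphology, gray-level co-occurrence
    texture), six 3-D morphological features from thickness maps,
    gradient-boosted classification of healthy versus thalassemic cells with
    exact Shapley feature attribution, and canonical correlation analysis
    linking 2-D phase statistics to 3-D morphology. Includes a parametric
    biconcave-discocyte phantom generator and hologram forward model so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    xgboost,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
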