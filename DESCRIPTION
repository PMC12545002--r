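Package: ticmapr
Title: Pixel-Wise Time-Intensity Curve Parametric Imaging for
    Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative wash-in analysis of contrast-enhanced ultrasound
    (CEUS) cineloops. Computes pixel-wise time-intensity curves (TICs),
    derives the mean gradient to peak (the average TIC slope from the start
    of enhancement to peak intensity) as a per-pixel perfusion parameter,
    renders colour-coded parametric maps, and classifies the spatial
    discreteness of hyper-perfused regions into a four-tier grading of
    perfusion heterogeneity. Includes rigid motion compensation, a synthetic
    cineloop simulator with known ground truth, and a reader-study
    statistical battery (two-way random absolute-agreement ICC, Fleiss'
    kappa, McNemar's test, the Cochran-Armitage trend test, binary-call
    ROC metrics with exact confidence intervals, and the DeLong test for
    paired AUCs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
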