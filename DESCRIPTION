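Package: istquant
Title: Quantification of Immuno-Spin-Trapping Fluorescence in Cardiac Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying oxidative modifications
    detected by immuno-spin trapping (DMPO nitrone adducts) in triple-channel
    fluorescence micrographs of cardiac tissue. Provides a seeded synthetic
    cohort generator with full ground truth, Otsu thresholding and binary
    morphology for vessel and capillary segmentation, ratio-normalized DMPO
    scores for cardiomyocytes and coronary endothelium, microvessel density
    estimation, the distribution-adaptive statistical decision tree used for
    group comparisons (Shapiro-Wilk gated t / Mann-Whitney, Kruskal-Wallis
    with Dunn post hoc, ANOVA with Fisher LSD, linear trend contrasts), and
    deterministic calculators for spectrophotometric antioxidant-enzyme
    assays and Western-blot lane densitometry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    tiff,
    EBImage,
    mgcv,
    yaml,
    jsonlite,
    withr,
    zoo,
    car,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
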