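Package: laryngovib
Title: Vocal-Fold Vibration Analysis from High-Speed Videoendoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of vocal-fold oscillation from high-speed
    laryngeal video. Implements pixel-wise Fourier laryngotopography (per-pixel
    fundamental frequency, amplitude and phase maps), vibration-mask extraction
    and the Stiffness Asymmetry Index (SAI) with straight or locally adaptive
    left/right glottis partitioning; kymographic edge-trajectory extraction and
    a registry of 38 named vibratory parameters (amplitudes, open quotients,
    amplitude asymmetries, phase differences); normality-gated group statistics
    with Bonferroni-corrected pairwise Mann-Whitney tests; bootstrap ROC
    analysis with percentile confidence intervals and Youden-index cutoffs; and
    SVM classification with sequential floating forward feature selection under
    stratified cross-validation. A synthetic-recording generator provides
    ground-truth-annotated glottal oscillation videos and tabular cohorts for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
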