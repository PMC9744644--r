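Package: foctr
Title: Functional OCT Analysis of Retinal Perfusion and Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for functional optical coherence tomography
    (fOCT) of the macula: en-face projection of 3-D OCT volumes, rigid
    coregistration, multiscale Frangi vessel enhancement, robust-PCA band
    artifact removal, global thresholding to retinal vascular perfusion
    density (rVPD), dynamic-programming extraction of ILM/RPE surfaces and
    retinal thickness maps, plus the physiology indices (arterial oxygen
    content, stimulus index, mean arterial pressure) and repeated-measures
    statistics (rmcorr, RM-ANOVA with Bonferroni pairwise comparisons) used
    to relate retinal microvascular responses to arterial blood gases. A
    synthetic cohort generator with known ground truth makes every stage
    testable without clinical scans.
License: MIT + file LICENSE
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
    generics,
    jsonlite,
    yaml,
    readr,
    withr,
    tiff,
    png,
    RNifti,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
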