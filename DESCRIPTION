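Package: petrad
Title: Segmentation-Dependent Radiomic Prognostic Modelling for PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to study how the choice of automatic PET tumour
    segmentation method propagates into radiomic texture features, Cox
    prognostic models and patient risk stratification in FDG PET
    oncology cohorts. Provides a synthetic FDG-PET phantom and survival
    cohort generator with known effect sizes; nine automatic metabolic
    tumour volume delineation algorithms (adaptive iterative
    thresholding, k-means, fuzzy c-means and Gaussian-mixture
    clustering, region growing, and a watershed transform on the Sobel
    gradient) with an automated contour-failure screen; ten standardised
    first- and higher-order image features (GLCM dissimilarity, GLSZM
    grey-level non-uniformity and zone percentage, NGTDM coarseness)
    under fixed-bin-size SUV discretisation; Cox proportional-hazards
    model construction with backward elimination, prognostic scores and
    risk-tertile stratification; and cross-method risk-group concordance
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    survival,
    utils
Suggests:
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
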