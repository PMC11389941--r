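Package: crlmrad
Title: Baseline-CT Radiomics Survival Pipeline for Colorectal Liver Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for predicting time to recurrence and
    disease-specific survival in colorectal-cancer liver-metastasis patients
    from baseline contrast-enhanced CT radiomics. Provides per-lesion feature
    extraction (first-order, shape, GLCM, GLRLM on original and
    Laplacian-of-Gaussian channels), seven multi-lesion aggregation
    strategies, the Fong clinical risk score, a repeated
    MRMR/univariate-Cox/Lasso-Cox signature cascade, random survival forests
    and a compact Cox partial-likelihood neural network, two-stage landmark
    classification, and bootstrap evaluation with Harrell's concordance index
    and ROC AUC. A synthetic cohort and phantom generator with known
    proportional-hazards structure makes every stage testable without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    ranger,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
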