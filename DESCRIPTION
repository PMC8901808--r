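Package: slnradiomics
Title: Intratumoral and Peritumoral DCE-MRI Radiomics for Sentinel Lymph
    Node Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for preoperative prediction of sentinel lymph node
    metastasis from breast DCE-MRI. Computes wash-in, wash-out and signal
    enhancement ratio (SER) kinetic maps from a five-phase dynamic series,
    builds intratumoral and 0-4 mm peritumoral regions of interest, extracts
    conventional radiomic features (shape, first-order, GLCM, NGLDM, GLRLM,
    GLZLM, Laws texture energy) and deep-learning-based features (activations
    of a frozen convolutional backbone), and runs a train-anchored reduction
    and modeling protocol: z-score normalisation, adaptive synthetic minority
    oversampling, Mann-Whitney and Spearman-correlation filtering, optional
    PCA, LASSO-penalised logistic feature selection with the one-standard-error
    rule, Youden-index thresholding, and a multi-seed model-selection loop.
    Includes a synthetic two-resolution phantom cohort generator with planted,
    recoverable kinetic and clinical class signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    withr,
    RNifti
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
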