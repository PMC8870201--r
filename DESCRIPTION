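Package: radiopcr
Title: Multimodal Radiomics Prediction of Pathological Complete Response in
    Rectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end multimodal radiomics pipeline for predicting
    pathological complete response (pCR) to neoadjuvant chemoradiotherapy in
    locally advanced rectal cancer. Provides 3D IBSI-style feature extraction
    (shape, intensity histogram, and merged-direction GLCM/GLRLM/GLSZM/NGTDM
    texture features) from NIfTI image/mask pairs, parametric empirical-Bayes
    ComBat harmonization of multi-institution feature tables, AUC and rank
    correlation based feature selection, SMOTE oversampling, a single
    hidden-layer neural network classifier with bootstrap internal validation
    and Youden-index cutoff locking, fixed-cutoff external evaluation with
    decision-curve analysis, and a synthetic two-institution cohort generator
    so the whole workflow runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    nnet,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
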