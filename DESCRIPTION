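Package: pcrpet
Title: Multimodal Prediction of Pathological Complete Response in
    Triple-Negative Breast Cancer from Pretreatment PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting pathological
    complete response (pCR) to neoadjuvant chemotherapy in
    triple-negative breast cancer from pretreatment multimodal data:
    FDG-PET imaging (fixed-fraction SUVmax segmentation and IBSI-style
    radiomics), clinical, histopathological and genomic features.
    Includes a synthetic phantom and cohort generator with planted
    ground truth, one-hot encoding and standardization, mean-only
    batch correction for genomic expression, non-parametric univariate
    screening, bootstrap-stability hierarchical clustering of radiomic
    features, chained-equation imputation with randomized trees,
    nested leave-pair-out cross-validated model evaluation with
    stratified pair bootstrap, linear-model Shapley attributions, and
    Kaplan-Meier / log-rank survival stratification of predicted
    response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    glue,
    stats,
    utils,
    RNifti,
    yaml,
    glmnet,
    e1071,
    rpart,
    ranger,
    mclust,
    survival
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
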