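Package: wavemics
Title: Wavelet Radiomics for Two-Class Brain Tumor Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for discriminating glioblastoma from brain
    metastasis with multi-sequence MRI radiomics. Computes 107 shape,
    first-order and texture (GLCM, GLRLM, GLSZM, GLDM, NGTDM) features per
    sequence from 3D regions of interest, filters features by intra- and
    inter-observer intraclass correlation, selects features with
    cross-validated LASSO logistic regression, derives a 36-criterion
    profile per patient from a single-level two-dimensional discrete
    wavelet transform under 31 filter banks, and benchmarks eight
    classifier families with repeated stratified cross-validation,
    pairwise ROC testing and percent-increase comparisons. Includes a
    synthetic cohort generator (ellipsoidal lesions with class-dependent
    texture and repeated segmentations) so every stage is exercisable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    RNifti,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
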