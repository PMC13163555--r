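Package: gddp
Title: Gradient-Enhanced Decimal Descriptor Patterns for MRI Texture
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Texture descriptors and an evaluation harness for automated
    multiple-sclerosis detection and severity grading on MRI slices.
    Implements the classical intensity-based Decimal Descriptor Pattern
    (DDP) and its gradient-enhanced variant (Gradient-DDP), which encodes
    per-block gradient-magnitude mean and variance together with the
    circular-mean gradient direction into 11 discrete codes and a 16-bin
    normalized histogram. Includes a synthetic multi-modality brain phantom
    with graded elliptical lesions (mild/moderate/severe), NIfTI and PNG
    slice loaders, leakage-free subject-wise grouped stratified
    cross-validation, four reference classifiers (RBF SVM, distance-weighted
    k-nearest neighbours, linear discriminant analysis, penalized logistic
    regression), and confusion-matrix metrics including the Matthews
    correlation coefficient with per-modality aggregation.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    RNifti,
    e1071,
    glmnet,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
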