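Package: roitexture
Title: ROI-Masked GLCM Texture Radiomics with Group Testing and SVM Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomic texture analysis of segmented regions of interest in 3D
    intensity volumes. Quantizes masked regions to a fixed number of grey
    levels, computes per-slice grey-level co-occurrence matrices (GLCM) and
    eleven Haralick-type texture quantifiers, and aggregates them to one
    feature vector per region per subject. Downstream tools cover two-group
    ANOVA with Holm-Bonferroni correction, Dice overlap of rater masks,
    leave-one-out and k-fold SVM classification with RBF kernels,
    label-permutation null calibration of classifier accuracy, and
    random-forest root-node feature importance. A synthetic-cohort generator
    produces labeled Gaussian-random-field phantoms with ellipsoidal masks so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
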