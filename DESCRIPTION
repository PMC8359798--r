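Package: beakid
Title: Cephalopod Species Identification from Beak Images
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for identifying cephalopod species from
    photographs of their chitinous beaks. Provides a synthetic beak-image
    generator with ground-truth masks, lightbox-style image preprocessing and
    threshold segmentation, histogram-of-oriented-gradients (grey and colour)
    and morphological shape descriptors computed from the beak contour,
    random-weight deep-feature backbone adapters, eight configured classifiers
    behind a single train/score contract, and a repeated stratified
    shuffle-split evaluation harness with confusion matrices, per-class
    precision/recall and precision-recall AUC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    nnet,
    MASS,
    e1071,
    randomForest,
    rpart,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Software
RoxygenNote: 7.3.3
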