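Package: PNSgrade
Title: Machine-Vision Quality Grading of Panax notoginseng Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grades dried Panax notoginseng slices by their total saponin
    (PNS) content using cross-section images. Extracts a 113-dimensional
    fused descriptor per slice (14 color moments over RGB/HSV/Lab channels,
    a 59-bin uniform local binary pattern histogram, and mean magnitudes of
    a 40-filter Gabor bank), derives saponin-content grade boundaries from
    assay values by average-linkage hierarchical clustering with an
    elbow-rule model selection, and trains, compares and tunes tree-ensemble
    classifiers (with SMOTE balancing, cumulative-importance feature
    selection, particle-swarm hyperparameter optimization and stratified
    cross-validation) that predict the grade from image features alone.
    A synthetic slice and assay generator makes the whole pipeline testable
    without any deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'color-features.R'
    'dataset-prep.R'
    'texture-features.R'
    'extract-features.R'
    'grade-derivation.R'
    'modeling.R'
    'pipeline.R'
    'pso-tuning.R'
    'synthetic.R'
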