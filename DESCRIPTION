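Package: lipidCPC
Title: Compositional Feature Selection for MRM-Profiling Lipidomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for flow-injection MRM-profiling lipidomics of the mouse
    epidermis: extraction of SRM chromatogram intensities from mzML files into
    a SummarizedExperiment-based intensity matrix, compositional preprocessing
    (closure, multiplicative zero replacement, centered and isometric log-ratio
    transforms), per-category singular-value-decomposition compression into
    compositional principal component ("CPC") features, two-tier feature
    selection combining per-feature linear models (eta-squared effect sizes,
    Benjamini-Hochberg adjustment) with elastic-net penalized classification
    under leave-one-out cross-validation, class-imbalance handling via class
    weights or SMOTE, and a synthetic-data generator that emulates the
    sex/genotype/disease-stage structure of a murine dermatitis study for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    mzR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Lipidomics, MassSpectrometry, Classification, FeatureExtraction,
    DimensionReduction
RoxygenNote: 7.3.3
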