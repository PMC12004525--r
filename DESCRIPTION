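Package: confagg
Title: Conformer-Ensemble Descriptor Aggregation for Molecular Property
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how conformer ensembles and their
    aggregation affect quantitative structure-property modelling.
    Provides multi-conformer SDF input/output, a synthetic
    conformer-ensemble generator with tunable conformational dependency
    of the target property, Kabsch superposition and ensemble diversity
    statistics, per-conformer 3D descriptors (3D-MoRSE, pharmacophore
    triplets, many-body tensor representation) with 2D baselines, six
    descriptor aggregation schemes including Boltzmann weighting and
    multi-instance nonaggregation, compound-level cross-validated
    regression with random-forest and neural-network adapters, and
    paired nonparametric comparison of modelling pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ranger,
    glmnet,
    nnet,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
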