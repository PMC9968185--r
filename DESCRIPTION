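Package: coamscreen
Title: Descriptor-Based Screening of Co-Amorphous Drug Combinations
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts whether a binary combination of two small molecules
    will form a co-amorphous system (COAMS). Molecules supplied as SMILES
    are featurised with a 29-descriptor panel (counts, topology,
    polarizability, Wildman-Crippen logP, polar and charged-partial
    surface areas); pairs are encoded as 34 features (absolute descriptor
    differences, donor/acceptor-acid/base cross terms and the preparation
    pathway). A voting ensemble of 50 gradient-boosted tree classifiers
    trained on repeated random 85/15 splits yields a predicted score, an
    applicability-domain Euclidean distance to the training data, and an
    uncertainty factor UF = d/p^4 for ranking candidate API-API pairs.
    Includes dataset curation rules, a stratified train/test split, a
    four-learner benchmark, gain-based feature importance and a synthetic
    labelled-data generator with a planted decision rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    xgboost,
    randomForest,
    e1071,
    class,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python 3 with RDKit (the 'python' executable on the
    PATH, or COAMSCREEN_PYTHON) for SMILES parsing and 3D embedding
Config/testthat/edition: 3
biocViews: Cheminformatics, Classification, Pharmacogenomics
RoxygenNote: 7.3.3
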