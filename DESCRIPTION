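Package: somkit
Title: Atom-Level Site-of-Metabolism Prediction with Rooted Circular
    Fingerprints and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@somkit.org",
           role = c("aut", "cre"))
Description: An open, trainable toolkit for predicting phase 1 and phase 2
    sites of metabolism (SOMs) of small molecules at the atom level. Encodes
    every heavy atom by a rooted circular fingerprint over SYBYL atom types
    (32-bit block or count variant), ten physicochemical atom descriptors and
    four topological descriptors, classifies atoms with a deterministic random
    forest, and quantifies prediction reliability with a k-nearest-neighbour
    Tanimoto applicability-domain score and the Shannon entropy of the
    predicted probability. Includes the full evaluation protocol (ROC-AUC,
    PR-AUC, F1, MCC, precision, recall, molecule-level top-2 correctness), a
    synthetic fixture generator with deterministic rule-based SOM labels, and
    a command-line interface covering descriptor generation, training,
    prediction and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ChemmineR,
    ChemmineOB,
    igraph,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
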