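Package: AffinityTransfer
Title: Transfer Learning for Drug-Target Affinity Prediction with
    Cold-Start Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts real-valued drug-target binding affinity (DTA) with
    encoders pretrained on auxiliary interaction tasks. A graph isomorphism
    network (GIN) encodes molecules built from SMILES; a token-embedding
    sequence encoder represents proteins; both are pretrained as siamese
    classifiers on chemical-chemical (CCI) and protein-protein (PPI)
    interaction pairs and then transferred into an affinity regressor.
    Includes entity-disjoint cold-drug/cold-target splitting, concordance
    index and correlation metrics, a synthetic-data generator with shared
    latent structure that makes the transfer effect testable at small
    scale, and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    ChemmineR,
    ChemmineOB
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
biocViews: Software, Cheminformatics, MachineLearning, Regression
RoxygenNote: 7.3.3
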