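Package: dwlmi
Title: LncRNA-miRNA Association Prediction from a Heterogeneous
    Molecular Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers candidate lncRNA-miRNA associations by fusing
    intrinsic node attributes (3-mer sequence composition, MeSH-style
    disease semantic similarity, circular drug fingerprints, unified to a
    common dimension by a stacked autoencoder) with network behavior
    vectors learned by DeepWalk over a five-entity heterogeneous
    association graph (lncRNA, miRNA, disease, protein, drug). Candidate
    pairs are scored by a random forest and evaluated with k-fold
    cross-validation and leave-one-node-out candidate ranking. Includes a
    synthetic fixture generator with planted block structure so the whole
    pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineOB,
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
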