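Package: sappred
Title: Pathogenicity Prediction for Single Amino Acid Polymorphisms from
    Sequence, Structure and Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a single amino acid polymorphism (SAP) is
    disease-related or neutral using a support vector machine over features
    derived from the protein sequence, an evolutionary sequence profile, the
    structural microenvironment and solvent accessibility of the mutated
    residue, external per-variant predictor output, and a Gene Ontology
    log-odds functional score computed over the annotation ancestor closure.
    Ships readers for FASTA, OBO 1.2, PDB and DSSP-style accessibility files,
    a calibrated classifier with a reliability index, a full evaluation suite
    (accuracy, per-class sensitivity and precision, Matthews correlation,
    ROC/AUC, reliability-stratified performance, cluster-aware k-fold
    cross-validation), and a synthetic-data generator with planted
    conservation, functional and burial signals for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    igraph,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
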