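Package: carbsite
Title: Prediction of Protein Carbonylation Sites from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Residue-type-specific (K/R/T/P) prediction of human protein
    carbonylation sites from primary sequence. Candidate sites are cut into
    fixed +/-n peptide windows; four families of features are extracted
    (position-specific propensities of amino acids and k-spaced amino acid
    pairs, increments of k-mer diversity against class pools, BLOSUM62-based
    k-nearest-neighbour scores, and normalized physicochemical indices);
    features are ranked by minimum-redundancy-maximum-relevance and pruned by
    incremental feature selection on cross-validated Matthews correlation;
    classification uses a class-weighted RBF support vector machine with
    probability outputs. Includes stratified spliced-probability
    cross-validation, ROC/AUC and confusion metrics, position-composition and
    hydrophobicity analyses of site flanks, and a deterministic synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
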