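Package: misvep
Title: Interpretable Missense Variant Effect Prediction with
    Reference-Amino-Acid Subset Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether human missense variants are neutral or
    disease-associated from five sequence-derived feature categories
    (amino-acid substitution identity, surrounding-sequence composition,
    alignment-column conservation, physicochemical conservation against
    the alignment column, and Pfam domain membership), using one linear
    support vector machine per reference amino acid so that feature
    weights stay interpretable.  Includes dataset-construction filters
    based on single-nucleotide codon reachability, stratified
    cross-validation with pooled ROC analysis, weight-matrix extraction
    and standardization with heat-map ordering, a validating log-odds
    substitution matrix, and a synthetic-data generator with planted
    feature effects for end-to-end testing.
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
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
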