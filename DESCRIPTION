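Package: synoptic
Title: Semantic Labelling of Semi-Structured Pathology Synopses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps semi-structured pathology synopses (ordered field:description
    records, e.g. bone marrow aspirate reports) to multiple semantic labels.
    Implements a binary-relevance classifier over feature-hashing text
    embeddings trained with decoupled-weight-decay Adam, field-order shuffle
    augmentation with max-aggregated prediction, a rare-label (CRL) active
    learning loop against a pluggable labelling oracle, an adapted Monte Carlo
    cross-validation splitter with per-label validation guarantees, word
    knockout influence scoring for interpretability, embedding-space analyses
    (2-D projection, label co-occurrence), and a synthetic synopsis generator
    with planted ground truth so the whole pipeline is testable without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    jsonlite,
    stringi,
    Matrix,
    ggplot2,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
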