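Package: nestner
Title: Nested Named Entity Recognition with a Boundary-Supervised Biaffine Span Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Span-based recognition of nested named entities in tokenized
    text. Sentences are encoded with character-CNN and word embeddings and a
    bidirectional LSTM; separate head and tail projections feed a biaffine
    scorer that classifies every candidate (start, end) interval, and an
    auxiliary per-token boundary-detection task trained jointly under a
    mixed multi-task loss supplies explicit boundary supervision. Includes
    readers and writers for CoNLL-2003 and a span-JSONL dialect, a
    configurable generator of synthetic nested-entity corpora, greedy
    overlap-resolving decoding, entity-level precision/recall/F1
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
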