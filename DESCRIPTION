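Package: milink
Title: Unsupervised Medical Entity Linking with Multi-Instance Learning
Version: 0.1.0
Authors@R:
    person("Milo", "Linker", email = "milink@example.org", role = c("aut", "cre"))
Description: Links colloquial symptom mentions in raw text to entities in an
    ICD10-style knowledge base without annotated training data. Provides a
    basic embedding-similarity linker (average word vectors + cosine),
    hierarchical-code-aware candidate generation (TopK and ClusterK positive
    bags, Random-All and Random-TopN hard negatives), multi-instance learning
    (MIL) dataset construction, and a neural ranker (BiLSTM boundary-state
    context encoder, token-average entity encoder, feed-forward scorer)
    trained with a triplet max-margin loss. A synthetic-data module generates
    knowledge bases, embeddings, dictionaries and labeled corpora with
    controllable cluster structure so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
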