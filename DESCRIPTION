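Package: phonosemNER
Title: Phono-Semantic Character Analysis and Radical-Pinyin Embeddings for
    Chinese Clinical Named Entity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for character-level Chinese clinical named entity
    recognition built on graphical and phonetic character features. Provides
    a character knowledge base (primary radical, pinyin readings, Ideographic
    Description Sequences), pinyin initial/final/tone segmentation, nested-IDS
    phono-semantic character detection, skip-gram pretraining of character,
    radical, pinyin and final embedding tables, a learned composition layer
    that combines a radical embedding with a character, pinyin or final
    embedding, a Bi-LSTM-CRF sequence tagger over the composed embeddings,
    entity-level evaluation with cross-validation, corpus sectioning by
    phono-semantic proportion, radical-occurrence statistics, and a seeded
    synthetic corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp (>= 1.0.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
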