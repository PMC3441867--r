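Package: causepattern
Title: Inter-Sentential Language Pattern Mining for Causality Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects implicit cause-effect relations between sentence pairs by
    mining intra-sentential language patterns (frequent word sets scored by
    pointwise mutual information) within cause and effect text spans, combining
    them into inter-sentential language patterns across the span boundary, and
    feeding them together with word-pair features into a factored probabilistic
    classifier. Includes corpus input/output for pre-tokenized, POS-tagged
    sentence pairs, a discourse-connective splitter, a CoNLL-U reader for
    parse-derived dependency patterns, a stratified cross-validation and
    parameter-sweep harness with paired t-tests, and a synthetic corpus
    generator with planted co-occurrence structure so every stage is testable
    without access to clinical text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
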