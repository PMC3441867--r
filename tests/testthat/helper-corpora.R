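# builders for in-code fixtures

# token table with every word tagged noun (content word) unless pos given
ctok <- function(words, pos = "noun") tokens(words, pos)

# sentence-pair table from lists of content-word vectors
mk_pairs <- function(cause_words, effect_words, labels = "causality",
                     ids = sprintf("p%03d", seq_along(cause_words))) {
  sentence_pairs(
    ids,
    lapply(cause_words, ctok),
    lapply(effect_words, ctok),
    rep_len(labels, length(cause_words))
  )
}

# random span collection over a small vocabulary, for oracle comparisons
random_spans <- function(seed, max_vocab = 12, max_spans = 30) {
  withr::with_seed(seed, {
    nv <- sample(4:max_vocab, 1)
    vocab <- paste0("w", seq_len(nv))
    n <- sample(5:max_spans, 1)
    lapply(seq_len(n), function(i) {
      sample(vocab, sample(0:min(6, nv), 1))
    })
  })
}

example_file <- function(name) {
  system.file("extdata", name, package = "causepattern", mustWork = TRUE)
}
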