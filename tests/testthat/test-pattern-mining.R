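test_that("support counts spans containing every item", {
  spans <- list(c("broke_up", "boyfriend"), "failed",
                c("broke_up", "boyfriend", "quarrel"))
  expect_equal(wordset_support(c("broke_up", "boyfriend"), spans), 2)
  expect_equal(wordset_support("failed", spans), 1)
  expect_equal(wordset_support("anything", list()), 0L)
  # repeated words within one span count once
  expect_equal(wordset_support("a", list(c("a", "a", "a"))), 1)
})

test_that("level-wise search reproduces the worked join/prune example", {
  freq <- find_frequent_wordsets(
    list(c("a", "b", "c"), c("a", "b"), c("a", "c"), "d"), min_support = 2
  )
  got <- freq_keys(freq)
  expect_setequal(got, c("a 3", "b 2", "c 2", "a b 2", "a c 2"))
  # {a,b,c} is pruned: its subset {b,c} has support 1
  expect_false(any(freq$k == 3))
})

test_that("min_support above the span count yields no frequent sets", {
  expect_equal(nrow(find_frequent_wordsets(list(c("a", "b"), "a"), 3)), 0)
})

test_that("level-wise search equals exhaustive enumeration on random corpora", {
  for (seed in 1:40) {
    spans <- random_spans(seed)
    ms <- (seed %% 3) + 1
    got <- find_frequent_wordsets(spans, min_support = ms)
    want <- bf_frequent_sets(spans, min_support = ms)
    expect_setequal(freq_keys(got), paste(want$key, want$support))
  }
})

test_that("support is anti-monotone under set inclusion", {
  for (seed in 41:60) {
    spans <- random_spans(seed)
    vocab <- unique(unlist(spans))
    if (length(vocab) < 3) next
    withr::with_seed(seed, {
      for (rep in 1:10) {
        big <- sample(vocab, sample(2:min(4, length(vocab)), 1))
        small <- big[seq_len(sample(length(big) - 1, 1))]
        expect_gte(wordset_support(small, spans),
                   wordset_support(big, spans))
      }
    })
  }
})

test_that("pattern confidence matches hand-evaluated mutual information", {
  # two words, each in 2 of 4 spans, always together
  expect_equal(
    intra_confidence(c("w1", "w2"), list(c("w1", "w2"), c("w1", "w2"),
                                         "x", "y")),
    0.5 * log(0.5 / 0.25), tolerance = 1e-12
  )
  # independence: joint equals the product of marginals
  expect_identical(
    intra_confidence(c("w1", "w2"), list(c("w1", "w2"), "w1", "w2", "z")),
    0
  )
  # three words always together in 2 of 4 spans
  expect_equal(
    intra_confidence(c("a", "b", "c"), list(c("a", "b", "c"), c("a", "b", "c"),
                                            "x", "y")),
    0.5 * log(0.5 / 0.125), tolerance = 1e-12
  )
  # zero joint support: p log p limit
  expect_identical(intra_confidence(c("a", "q"), list("a", "q")), 0)
})

test_that("intra pattern generation filters by the confidence rule", {
  spans <- list(c("broke_up", "boyfriend", "x1"), c("broke_up", "boyfriend"),
                c("x1", "x2"), c("x2", "x3"), c("broke_up", "boyfriend", "x3"),
                "x1")
  pat <- mine_intra_patterns(spans, "cause", min_support = 2,
                             min_confidence = 0.05)
  expect_true("cause:boyfriend,broke_up" %in% pat$id)
  # display order follows first occurrence, mining order is canonical
  expect_equal(pat$words[[match("cause:boyfriend,broke_up", pat$id)]],
               c("broke_up", "boyfriend"))
  # an infinite floor removes everything
  expect_equal(nrow(mine_intra_patterns(spans, "cause", 2,
                                        min_confidence = Inf)), 0)
  # emitted set equals the brute-force filter over all frequent k >= 2 sets
  for (seed in 61:75) {
    rspans <- random_spans(seed)
    got <- mine_intra_patterns(rspans, "effect", min_support = 2,
                               min_confidence = 0.02)
    bf <- bf_frequent_sets(rspans, min_support = 2)
    bf <- bf[bf$k >= 2, ]
    want <- bf$key[vapply(strsplit(bf$key, " "), function(w) {
      intra_confidence(w, rspans) >= 0.02
    }, logical(1))]
    expect_setequal(vapply(strsplit(sub("^effect:", "", got$id), ","),
                           paste, "", collapse = " "),
                    want)
    expect_false(is.unsorted(rev(got$confidence)))
  }
})

test_that("patterns are single words never; sets have at least two words", {
  pat <- mine_intra_patterns(list(c("a", "b"), c("a", "b"), "a"), "cause",
                             min_support = 1, min_confidence = 0)
  expect_true(all(pat$k >= 2))
})

test_that("frequent pattern sets span the cause/effect boundary", {
  pairs <- read_pairs(example_file("example_pairs.jsonl"))
  cause_pat <- mine_intra_patterns(
    lapply(pairs$cause, function(s) tolower(content_words(s))), "cause", 2)
  effect_pat <- mine_intra_patterns(
    lapply(pairs$effect, function(s) tolower(content_words(s))), "effect", 2)
  fps <- find_frequent_patternsets(cause_pat, effect_pat, pairs, 2)
  expect_true(all(vapply(fps$items, function(it) {
    any(startsWith(it, "cause:")) && any(startsWith(it, "effect:"))
  }, logical(1))))
  # brute-force check of every cause x effect pattern combination
  for (ci in seq_len(nrow(cause_pat))) {
    for (ei in seq_len(nrow(effect_pat))) {
      joint <- sum(vapply(seq_len(nrow(pairs)), function(r) {
        all(tolower(cause_pat$words[[ci]]) %in%
              tolower(pairs$cause[[r]]$surface)) &&
          all(tolower(effect_pat$words[[ei]]) %in%
                tolower(pairs$effect[[r]]$surface))
      }, logical(1)))
      key <- paste(sort(c(cause_pat$id[ci], effect_pat$id[ei]),
                        method = "radix"), collapse = " ")
      in_result <- key %in% vapply(fps$items[fps$k == 2],
                                   paste, "", collapse = " ")
      expect_equal(in_result, joint >= 2)
    }
  }
  # support floor beyond the corpus empties the result
  expect_equal(nrow(find_frequent_patternsets(cause_pat, effect_pat,
                                              pairs, 99)), 0)
  # one empty side warns and returns nothing
  expect_warning(
    none <- find_frequent_patternsets(cause_pat[0, ], effect_pat, pairs, 2),
    "no intra"
  )
  expect_equal(nrow(none), 0)
})

test_that("inter confidence matches hand evaluation and independence is 0", {
  # 4 pairs; cause pattern in 2 cause spans, effect pattern in 2 effect
  # spans, co-occurring in 2 pairs
  pairs <- mk_pairs(
    list(c("a", "b"), c("a", "b"), "q", "r"),
    list(c("x", "y"), c("x", "y"), "s", "t")
  )
  pat <- tibble::tibble(
    side = c("cause", "effect"),
    words = list(c("a", "b"), c("x", "y"))
  )
  expect_equal(inter_confidence(pat, pairs), 0.5 * log(0.5 / 0.25),
               tolerance = 1e-12)
  # independent placement: joint = product of marginals
  pairs_ind <- mk_pairs(
    list(c("a", "b"), c("a", "b"), "q", "r"),
    list(c("x", "y"), "s", c("x", "y"), "t")
  )
  expect_identical(inter_confidence(pat, pairs_ind), 0)
})

test_that("inter mining recovers the planted pair combination on top", {
  pairs <- read_pairs(example_file("example_pairs.jsonl"))
  pat <- mine_patterns(pairs, min_support = 2)
  expect_gt(nrow(pat$inter), 0)
  # the <broke up, boyfriend> / <life, meaningless> combination is the most
  # confident one-plus-one pattern
  two <- pat$inter[pat$inter$k == 2, ]
  top <- two[1, ]
  expect_setequal(top$cause_patterns[[1]], "cause:boyfriend,broke up")
  expect_setequal(top$effect_patterns[[1]], "effect:life,meaningless")
  expect_equal(top$confidence, 0.3 * log(0.3 / 0.09), tolerance = 1e-12)
  # confidence ranking equals a direct re-scoring of each mined pattern
  mining_pairs <- pairs[pairs$label == "causality", ]
  rescored <- vapply(seq_len(nrow(pat$inter)), function(i) {
    members <- dplyr::bind_rows(pat$intra_cause, pat$intra_effect)
    members <- members[members$id %in% c(pat$inter$cause_patterns[[i]],
                                         pat$inter$effect_patterns[[i]]), ]
    inter_confidence(members, mining_pairs)
  }, double(1))
  expect_equal(pat$inter$confidence, rescored, tolerance = 1e-12)
  expect_false(is.unsorted(rev(pat$inter$confidence)))
})

test_that("top-fraction selection returns a deterministic sorted prefix", {
  pat <- tibble::tibble(
    confidence = c(5, 4, 4, 3, 2, 2, 2, 1, 0.5, 0.1),
    id = sprintf("p%02d", 10:1)
  )
  expect_equal(nrow(select_top_patterns(pat, 0.3)), 3)
  expect_equal(nrow(select_top_patterns(pat, 0.7)), 7)
  full <- select_top_patterns(pat, 1.0)
  expect_equal(nrow(full), 10)
  expect_false(is.unsorted(rev(full$confidence)))
  # ties broken lexicographically by id
  expect_equal(select_top_patterns(pat, 0.3)$id, c("p10", "p08", "p09"))
  # always a prefix of the sorted list; size monotone in the fraction
  prev <- 0
  for (fr in seq(0.1, 1, by = 0.1)) {
    sel <- select_top_patterns(pat, fr)
    expect_equal(sel, utils::head(full, nrow(sel)))
    expect_gte(nrow(sel), prev)
    prev <- nrow(sel)
  }
  expect_equal(nrow(select_top_patterns(pat[0, ], 0.5)), 0)
  expect_error(select_top_patterns(pat, 0))
})

test_that("pattern inventories serialize to TSV", {
  pairs <- read_pairs(example_file("example_pairs.jsonl"))
  pat <- mine_patterns(pairs, min_support = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(pat, path)
  lines <- readLines(path)
  expect_match(lines[1], "table\tside\twords")
  expect_equal(length(lines),
               1 + nrow(pat$intra_cause) + nrow(pat$intra_effect) +
                 nrow(pat$inter))
})
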