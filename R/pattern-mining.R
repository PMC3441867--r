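#' Support of an item set over a span collection
#'
#' Support is counted at span level: the number of spans (transactions) that
#' contain every item of the set, regardless of how many times an item repeats
#' inside one span.
#'
#' @param items Character vector of items (words, or pattern identifiers at
#'   the inter-sentential stage). Must be non-empty.
#' @param spans List of character vectors, one per span.
#' @return Integer count in `[0, length(spans)]`.
#' @examples
#' wordset_support(c("broke_up", "boyfriend"),
#'                 list(c("broke_up", "boyfriend"), "failed",
#'                      c("broke_up", "boyfriend", "quarrel")))
#' @export
wordset_support <- function(items, spans) {
  if (length(items) == 0) stop("items must be non-empty", call. = FALSE)
  if (length(spans) == 0) return(0L)
  sum(vapply(spans, function(s) all(items %in% s), logical(1)))
}

# Apriori over generic transactions (lists of item strings).
# Canonical item order is lexicographic (radix/byte order, locale-independent),
# as the classical join step presupposes ordered item sets. Returns a tibble
# with columns k, items (list of character vectors in canonical order),
# support.
apriori_frequent <- function(transactions, min_support, max_k) {
  stopifnot(min_support >= 1, max_k >= 1)
  empty <- tibble::tibble(k = integer(), items = list(), support = integer())
  transactions <- lapply(transactions, unique)
  n <- length(transactions)
  if (n == 0 || min_support > n) return(empty)
  vocab <- sort(unique(unlist(transactions)), method = "radix")
  if (length(vocab) == 0) return(empty)
  ii <- match(unlist(transactions), vocab)
  jj <- rep.int(seq_len(n), lengths(transactions))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(vocab), n))
  supp1 <- Matrix::rowSums(M)
  l1 <- which(supp1 >= min_support)
  levels <- list()
  levels[[1]] <- list(sets = as.list(l1), support = as.integer(supp1[l1]))
  if (length(l1) > 0 && max_k >= 2) {
    # k = 2 by direct co-occurrence counting
    co <- Matrix::tcrossprod(M[l1, , drop = FALSE])
    co <- as(Matrix::triu(co, k = 1), "TsparseMatrix")
    keep <- co@x >= min_support
    sets2 <- Map(function(a, b) sort(c(l1[a], l1[b])),
                 co@i[keep] + 1L, co@j[keep] + 1L)
    ord <- order(vapply(sets2, `[`, 0L, 1), vapply(sets2, `[`, 0L, 2))
    levels[[2]] <- list(sets = sets2[ord], support = as.integer(co@x[keep])[ord])
    k <- 3L
    while (k <= max_k && length(levels[[k - 1]]$sets) > 0) {
      prev_mat <- do.call(rbind, levels[[k - 1]]$sets)
      key_of <- function(m) do.call(paste, as.data.frame(m))
      prev_keys <- key_of(prev_mat)
      prefix_keys <- key_of(prev_mat[, seq_len(k - 2), drop = FALSE])
      grp <- split(seq_len(nrow(prev_mat)), prefix_keys)
      grp <- grp[lengths(grp) >= 2]
      if (length(grp) == 0) break
      cand <- do.call(rbind, lapply(grp, function(rows) {
        lasts <- sort(prev_mat[rows, k - 1])
        cmb <- utils::combn(lasts, 2)
        cbind(matrix(prev_mat[rows[1], seq_len(k - 2)],
                     nrow = ncol(cmb), ncol = k - 2, byrow = TRUE), t(cmb))
      }))
      # prune: all (k-1)-subsets must be frequent
      ok <- rep(TRUE, nrow(cand))
      for (d in seq_len(k)) {
        ok <- ok & key_of(cand[, -d, drop = FALSE]) %in% prev_keys
      }
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) break
      A <- Matrix::sparseMatrix(i = rep(seq_len(nrow(cand)), k),
                                j = as.vector(cand), x = 1,
                                dims = c(nrow(cand), nrow(M)))
      supp <- Matrix::rowSums((A %*% M) == k)
      keep <- supp >= min_support
      if (!any(keep)) break
      cand <- cand[keep, , drop = FALSE]
      supp <- as.integer(supp[keep])
      ord <- do.call(order, as.data.frame(cand))
      cand <- cand[ord, , drop = FALSE]
      levels[[k]] <- list(
        sets = lapply(seq_len(nrow(cand)), function(r) cand[r, ]),
        support = supp[ord]
      )
      k <- k + 1L
    }
  }
  rows <- purrr::imap(levels, function(lv, k) {
    tibble::tibble(
      k = as.integer(k),
      items = lapply(lv$sets, function(s) vocab[s]),
      support = lv$support
    )
  })
  out <- dplyr::bind_rows(rows)
  out[out$support >= min_support, , drop = FALSE]
}

#' Find frequent word sets by level-wise (Apriori) search
#'
#' Level 1 collects the single words meeting the support floor; each further
#' level is built from the previous one by the classical join step (only sets
#' sharing their first `k - 2` canonical items merge), pruned by the
#' frequent-subset condition and then by a support count. Iteration stops when
#' a level comes out empty or `max_k` is reached.
#'
#' @param spans List of character vectors, one per span (repeated words within
#'   a span count once).
#' @param min_support Minimum number of spans a set must occur in (default 2).
#' @param max_k Upper bound on set size.
#' @return A tibble with columns `k`, `items` (list of character vectors in
#'   canonical lexicographic order) and `support`, covering every frequent set
#'   of every level.
#' @examples
#' find_frequent_wordsets(list(c("a", "b", "c"), c("a", "b"), c("a", "c"), "d"),
#'                        min_support = 2)
#' @export
find_frequent_wordsets <- function(spans, min_support = 2, max_k = 8) {
  apriori_frequent(spans, min_support, max_k)
}

#' Pointwise mutual information of a word set over spans
#'
#' The confidence of an intra-sentential language pattern
#' `<w1, ..., wk>` is `P(w1, ..., wk) * log(P(w1, ..., wk) / prod_i P(wi))`,
#' with all probabilities estimated as span-containment fractions and the
#' logarithm natural. A joint probability of zero returns 0 (the `p log p`
#' limit).
#'
#' @param words Character vector (length >= 1) of words.
#' @param spans List of character vectors.
#' @return The mutual-information confidence, in nats.
#' @examples
#' intra_confidence(c("w1", "w2"),
#'                  list(c("w1", "w2"), c("w1", "w2"), "x", "y"))
#' @export
intra_confidence <- function(words, spans) {
  n <- length(spans)
  if (n == 0) return(0)
  joint <- wordset_support(words, spans)
  if (joint == 0) return(0)
  marg <- vapply(words, function(w) wordset_support(w, spans), 0L)
  p <- joint / n
  p * log(p / prod(marg / n))
}

mi_score <- function(joint, marg, n) {
  # vectorized: joint scalar count, marg vector of counts
  if (joint == 0) return(0)
  p <- joint / n
  p * log(p / prod(marg / n))
}

first_occurrence_order <- function(words, spans) {
  # order words by their first appearance scanning spans left-to-right
  flat <- unlist(spans, use.names = FALSE)
  r <- match(words, flat)
  r[is.na(r)] <- Inf
  words[order(r, words, method = "radix")]
}

#' Generate intra-sentential language patterns from frequent word sets
#'
#' Every frequent set of two or more words is scored by [intra_confidence()];
#' those reaching the confidence rule become patterns. Single words are not
#' patterns (a pattern is a meaningful combination of words). Exactly one of
#' `min_confidence` / `top_frac` is active.
#'
#' @param spans List of character vectors (content words of one side's spans).
#' @param side `"cause"` or `"effect"`; recorded on every pattern.
#' @param min_support,max_k Passed to [find_frequent_wordsets()].
#' @param min_confidence Absolute confidence floor in nats. The default of
#'   0.05 nats sits well above the mutual information that word sets at the
#'   support floor reach through sampling noise alone, while genuinely
#'   dependent groups score an order of magnitude higher; admitting
#'   near-independent patterns also inflates the candidate pattern-set space
#'   at the inter-sentential stage combinatorially.
#' @param top_frac If given (in `(0, 1]`), overrides `min_confidence`: keeps
#'   the top fraction of patterns by confidence.
#' @return A tibble with columns `side`, `words` (list, in order of first
#'   occurrence in the spans), `pattern` (display form `<w1, w2>`), `k`,
#'   `support`, `confidence`, `id` (canonical `side:w1,w2` key), sorted by
#'   descending confidence (ties broken by canonical key).
#' @export
mine_intra_patterns <- function(spans, side = c("cause", "effect"),
                                min_support = 2, max_k = 8,
                                min_confidence = 0.05, top_frac = NULL) {
  side <- match.arg(side)
  freq <- find_frequent_wordsets(spans, min_support, max_k)
  n <- length(spans)
  empty <- tibble::tibble(
    side = character(), words = list(), pattern = character(),
    k = integer(), support = integer(), confidence = double(), id = character()
  )
  sets <- freq[freq$k >= 2, , drop = FALSE]
  if (nrow(sets) == 0) return(empty)
  supp1 <- stats::setNames(
    freq$support[freq$k == 1],
    vapply(freq$items[freq$k == 1], `[[`, "", 1)
  )
  spans_u <- lapply(spans, unique)
  conf <- purrr::map2_dbl(sets$items, sets$support, function(w, s) {
    marg <- supp1[w]
    if (anyNA(marg)) marg[is.na(marg)] <-
        vapply(w[is.na(marg)], function(x) wordset_support(x, spans_u), 0L)
    mi_score(s, marg, n)
  })
  out <- tibble::tibble(
    side = side,
    words = local({
      flat <- unlist(spans, use.names = FALSE)
      lapply(sets$items, function(w) {
        r <- match(w, flat)
        r[is.na(r)] <- Inf
        w[order(r, w, method = "radix")]
      })
    }),
    pattern = NA_character_,
    k = sets$k,
    support = as.integer(sets$support),
    confidence = conf,
    id = paste0(side, ":", vapply(sets$items, paste, "", collapse = ","))
  )
  out$pattern <- vapply(out$words,
                        function(w) paste0("<", paste(w, collapse = ", "), ">"), "")
  out <- out[order(-out$confidence, out$id, method = "radix"), , drop = FALSE]
  if (!is.null(top_frac)) {
    out <- select_top_patterns(out, top_frac)
  } else {
    out <- out[out$confidence >= min_confidence, , drop = FALSE]
  }
  out
}

# sparse containment of patterns (list of word vectors) in spans (list of word
# sets); returns logical dense matrix patterns x spans
pattern_containment <- function(pattern_words, span_sets) {
  np <- length(pattern_words)
  n <- length(span_sets)
  if (np == 0 || n == 0) {
    return(matrix(FALSE, nrow = np, ncol = n))
  }
  vocab <- unique(c(unlist(pattern_words), unlist(span_sets)))
  M <- Matrix::sparseMatrix(
    i = match(unlist(span_sets), vocab),
    j = rep.int(seq_len(n), lengths(span_sets)),
    x = 1, dims = c(length(vocab), n)
  )
  A <- Matrix::sparseMatrix(
    i = rep.int(seq_len(np), lengths(pattern_words)),
    j = match(unlist(pattern_words), vocab),
    x = 1, dims = c(np, length(vocab))
  )
  counts <- as.matrix(A %*% M)
  counts == lengths(pattern_words)
}

#' Find frequent pattern sets across the cause/effect boundary
#'
#' Treats each sentence pair as a transaction whose items are the
#' intra-sentential patterns it contains (a pair contains a cause-side pattern
#' when every pattern word occurs in its cause span, likewise for effect), and
#' reruns the same join/prune level-wise search over these pattern items.
#' Only sets combining at least one cause-side and one effect-side pattern are
#' returned, since an inter-sentential pattern needs both halves of the
#' relation.
#'
#' @param cause_patterns,effect_patterns Intra-pattern tibbles from
#'   [mine_intra_patterns()] (or [dependency_intra_patterns()]).
#' @param pairs A sentence-pair tibble.
#' @param min_support Minimum number of sentence pairs containing all member
#'   patterns.
#' @param max_k Upper bound on pattern-set size.
#' @return A tibble with columns `k`, `items` (list of pattern-id vectors) and
#'   `support`.
#' @export
find_frequent_patternsets <- function(cause_patterns, effect_patterns, pairs,
                                      min_support = 2, max_k = 4) {
  empty <- tibble::tibble(k = integer(), items = list(), support = integer())
  if (nrow(cause_patterns) == 0 || nrow(effect_patterns) == 0) {
    warning("no intra-sentential patterns on one side; no pattern sets mined")
    return(empty)
  }
  trans <- pattern_transactions(cause_patterns, effect_patterns, pairs)
  freq <- apriori_frequent(trans, min_support, max_k)
  freq <- freq[freq$k >= 2, , drop = FALSE]
  if (nrow(freq) == 0) return(freq)
  mixed <- vapply(freq$items, function(it) {
    any(startsWith(it, "cause:")) && any(startsWith(it, "effect:"))
  }, logical(1))
  freq[mixed, , drop = FALSE]
}

pattern_transactions <- function(cause_patterns, effect_patterns, pairs) {
  cc <- pattern_containment(cause_patterns$words,
                            span_word_sets(pairs$cause, content_only = FALSE))
  ce <- pattern_containment(effect_patterns$words,
                            span_word_sets(pairs$effect, content_only = FALSE))
  lapply(seq_len(nrow(pairs)), function(i) {
    c(cause_patterns$id[cc[, i]], effect_patterns$id[ce[, i]])
  })
}

#' Pointwise mutual information of a pattern set over sentence pairs
#'
#' The confidence of an inter-sentential language pattern is
#' `P(lp1, ..., lpk) * log(P(lp1, ..., lpk) / prod_i P(lpi))` with the joint
#' probability taken over sentence pairs (all member patterns contained in one
#' pair) and each marginal taken over the pattern's own side's span
#' collection; natural log.
#'
#' @param patterns An intra-pattern tibble (rows are the member patterns, with
#'   their `side` and `words`).
#' @param pairs A sentence-pair tibble.
#' @return The mutual-information confidence, in nats.
#' @export
inter_confidence <- function(patterns, pairs) {
  n <- nrow(pairs)
  np <- nrow(patterns)
  if (n == 0 || np == 0) return(0)
  contain <- vapply(seq_len(np), function(r) {
    side <- patterns$side[r]
    sets <- span_word_sets(pairs[[side]], content_only = FALSE)
    vapply(sets, function(s) all(tolower(patterns$words[[r]]) %in% s),
           logical(1))
  }, logical(n))
  contain <- matrix(contain, nrow = n)   # pairs x patterns
  joint <- sum(rowSums(contain) == np)
  mi_score(joint, colSums(contain), n)
}

#' Generate scored inter-sentential language patterns
#'
#' Runs [find_frequent_patternsets()] and scores every frequent mixed-side
#' pattern set by [inter_confidence()]. Exactly one of `min_confidence` /
#' `top_frac` is active; with neither, all patterns are returned sorted.
#'
#' @inheritParams find_frequent_patternsets
#' @param min_confidence Absolute confidence floor in nats.
#' @param top_frac If given, keeps the top fraction of patterns by confidence
#'   (the quantity tuned in threshold sweeps).
#' @return A tibble with columns `cause_patterns` / `effect_patterns` (lists
#'   of member pattern ids), `cause_words` / `effect_words` (lists of the
#'   union of member words per side, used for matching), `pattern` (display
#'   form), `k`, `support`, `confidence`, `id`; sorted by descending
#'   confidence with lexicographic tie-break.
#' @export
mine_inter_patterns <- function(cause_patterns, effect_patterns, pairs,
                                min_support = 2, max_k = 4,
                                min_confidence = NULL, top_frac = NULL) {
  empty <- tibble::tibble(
    cause_patterns = list(), effect_patterns = list(),
    cause_words = list(), effect_words = list(), pattern = character(),
    k = integer(), support = integer(), confidence = double(), id = character()
  )
  freq <- find_frequent_patternsets(cause_patterns, effect_patterns, pairs,
                                    min_support, max_k)
  if (nrow(freq) == 0) return(empty)
  n <- nrow(pairs)
  all_intra <- dplyr::bind_rows(cause_patterns, effect_patterns)
  cc <- pattern_containment(cause_patterns$words,
                            span_word_sets(pairs$cause, content_only = FALSE))
  ce <- pattern_containment(effect_patterns$words,
                            span_word_sets(pairs$effect, content_only = FALSE))
  marg <- c(
    stats::setNames(rowSums(cc), cause_patterns$id),
    stats::setNames(rowSums(ce), effect_patterns$id)
  )
  lookup <- stats::setNames(seq_len(nrow(all_intra)), all_intra$id)
  rows <- purrr::map2(freq$items, freq$support, function(ids, s) {
    members <- all_intra[lookup[ids], , drop = FALSE]
    cm <- members[members$side == "cause", , drop = FALSE]
    em <- members[members$side == "effect", , drop = FALSE]
    disp <- function(m) paste(m$pattern, collapse = ", ")
    tibble::tibble(
      cause_patterns = list(cm$id),
      effect_patterns = list(em$id),
      cause_words = list(unique(unlist(cm$words))),
      effect_words = list(unique(unlist(em$words))),
      pattern = paste0("<", disp(cm), " | ", disp(em), ">"),
      k = length(ids),
      support = as.integer(s),
      confidence = mi_score(s, marg[ids], n),
      id = paste(sort(ids, method = "radix"), collapse = " + ")
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$confidence, out$id, method = "radix"), , drop = FALSE]
  if (!is.null(top_frac)) {
    out <- select_top_patterns(out, top_frac)
  } else if (!is.null(min_confidence)) {
    out <- out[out$confidence >= min_confidence, , drop = FALSE]
  }
  out
}

#' Keep the top fraction of patterns by confidence
#'
#' Sorts by descending confidence (ties broken lexicographically by pattern
#' identifier so selection is deterministic) and keeps the first
#' `ceiling(fraction * n)` rows.
#'
#' @param patterns A pattern tibble with `confidence` and `id` columns.
#' @param fraction Fraction in `(0, 1]`.
#' @return The selected rows, a prefix of the sorted table.
#' @export
select_top_patterns <- function(patterns, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction <= 1)
  if (nrow(patterns) == 0) return(patterns)
  out <- patterns[order(-patterns$confidence, patterns$id, method = "radix"), ,
                  drop = FALSE]
  utils::head(out, ceiling(fraction * nrow(out)))
}

#' Mine the full pattern inventory from a labeled corpus
#'
#' End-to-end convenience wrapper: takes the causality-labeled pairs, mines
#' intra-sentential patterns separately over their cause and effect span
#' collections (content words, case-folded), combines them into
#' inter-sentential patterns, and applies top-fraction selection.
#'
#' @param pairs A sentence-pair tibble; only rows labeled `"causality"` are
#'   mined (patterns characterize the causal relation).
#' @param min_support Support floor used at both stages.
#' @param intra_min_confidence Confidence floor (nats) for intra patterns.
#' @param top_frac Top fraction of inter patterns kept (`NULL` keeps all).
#' @param max_k_intra,max_k_inter Level caps for the two stages.
#' @param method `"arm"` (frequent word sets) or `"parsing"` (dependency
#'   word--head pairs; requires `parses`).
#' @param parses Parsed spans from [read_conllu()], required for
#'   `method = "parsing"`.
#' @return A list of class `cp_patterns` with elements `intra_cause`,
#'   `intra_effect`, `inter` (tibbles as documented in
#'   [mine_intra_patterns()] and [mine_inter_patterns()]).
#' @export
mine_patterns <- function(pairs, min_support = 2, intra_min_confidence = 0.05,
                          top_frac = NULL, max_k_intra = 8, max_k_inter = 4,
                          method = c("arm", "parsing"), parses = NULL) {
  method <- match.arg(method)
  mining_pairs <- pairs[!is.na(pairs$label) & pairs$label == "causality", ,
                        drop = FALSE]
  if (method == "arm") {
    cause_spans <- span_word_sets(mining_pairs$cause)
    effect_spans <- span_word_sets(mining_pairs$effect)
    ic <- mine_intra_patterns(cause_spans, "cause", min_support, max_k_intra,
                              intra_min_confidence)
    ie <- mine_intra_patterns(effect_spans, "effect", min_support, max_k_intra,
                              intra_min_confidence)
  } else {
    if (is.null(parses)) {
      stop("method = 'parsing' requires `parses` from read_conllu()",
           call. = FALSE)
    }
    ic <- dependency_intra_patterns(parses, mining_pairs, "cause",
                                    min_support, intra_min_confidence)
    ie <- dependency_intra_patterns(parses, mining_pairs, "effect",
                                    min_support, intra_min_confidence)
  }
  inter <- mine_inter_patterns(ic, ie, mining_pairs, min_support, max_k_inter,
                               top_frac = top_frac)
  structure(list(intra_cause = ic, intra_effect = ie, inter = inter),
            class = "cp_patterns")
}

#' @export
print.cp_patterns <- function(x, ...) {
  cat("Causality pattern inventory\n")
  cat("  intra cause:  ", nrow(x$intra_cause), " patterns\n", sep = "")
  cat("  intra effect: ", nrow(x$intra_effect), " patterns\n", sep = "")
  cat("  inter:        ", nrow(x$inter), " patterns\n", sep = "")
  if (nrow(x$inter) > 0) {
    top <- utils::head(x$inter, 5)
    cat("  top inter patterns:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s  (support %d, confidence %.4f)\n",
                  top$pattern[i], top$support[i], top$confidence[i]))
    }
  }
  invisible(x)
}

#' Write a pattern inventory to TSV
#'
#' Intra patterns are written as `side, words (comma-joined), support,
#' confidence`; inter patterns as `cause-words | effect-words, support,
#' confidence` with member pattern ids alongside.
#'
#' @param patterns A `cp_patterns` object from [mine_patterns()].
#' @param path Output path; intra and inter tables are written to
#'   `<path>` with a `table` column distinguishing them.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "cp_patterns"))
  intra <- dplyr::bind_rows(patterns$intra_cause, patterns$intra_effect)
  lines <- c(
    "table\tside\twords\tsupport\tconfidence",
    if (nrow(intra) > 0) {
      paste("intra", intra$side,
            vapply(intra$words, paste, "", collapse = ","),
            intra$support, format(intra$confidence, digits = 12), sep = "\t")
    },
    if (nrow(patterns$inter) > 0) {
      paste("inter", "both",
            paste(vapply(patterns$inter$cause_words, paste, "", collapse = ","),
                  vapply(patterns$inter$effect_words, paste, "", collapse = ","),
                  sep = " | "),
            patterns$inter$support,
            format(patterns$inter$confidence, digits = 12), sep = "\t")
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
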