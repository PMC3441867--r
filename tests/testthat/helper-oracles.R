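# independent oracles, kept free of the implementation paths they check

# exhaustive frequent-set enumeration via span bitmasks (vocab <= 16)
bf_frequent_sets <- function(spans, min_support, max_k = Inf) {
  vocab <- sort(unique(unlist(spans)), method = "radix")
  nv <- length(vocab)
  stopifnot(nv <= 16)
  if (nv == 0 || length(spans) == 0) {
    return(tibble::tibble(k = integer(), key = character(),
                          support = integer()))
  }
  masks <- vapply(spans, function(s) {
    idx <- match(unique(s), vocab)
    sum(bitwShiftL(1L, idx - 1L))
  }, integer(1))
  bits <- bitwShiftL(1L, seq_len(nv) - 1L)
  rows <- vector("list", bitwShiftL(1L, nv) - 1L)
  for (m in seq_along(rows)) {
    idx <- which(bitwAnd(m, bits) != 0L)
    if (length(idx) > max_k) next
    supp <- sum(bitwAnd(masks, m) == m)
    if (supp >= min_support) {
      rows[[m]] <- list(k = length(idx),
                        key = paste(vocab[idx], collapse = " "),
                        support = supp)
    }
  }
  rows <- Filter(Negate(is.null), rows)
  tibble::tibble(
    k = vapply(rows, `[[`, 0L, "k"),
    key = vapply(rows, `[[`, "", "key"),
    support = vapply(rows, function(r) as.integer(r$support), 0L)
  )
}

# canonical key/support view of a find_frequent_wordsets() result
freq_keys <- function(freq) {
  paste(vapply(freq$items, paste, "", collapse = " "), freq$support)
}

# direct evaluation of the factored-product score in the linear domain,
# recounting every probability from the raw training table (add-one smoothing)
bf_product_score <- function(train_pairs, test_pair, class,
                             patterns = NULL) {
  cls_rows <- which(train_pairs$label == class)
  n_class <- length(cls_rows)
  n_total <- nrow(train_pairs)
  span_set <- function(tokdf, content) {
    w <- if (content) tokdf$surface[tokdf$pos %in% c("noun", "verb")] else
      tokdf$surface
    unique(tolower(w))
  }
  pair_wp <- function(row) {
    cw <- span_set(row$cause[[1]], TRUE)
    ew <- span_set(row$effect[[1]], TRUE)
    if (length(cw) == 0 || length(ew) == 0) return(character())
    as.vector(outer(cw, ew, function(a, b) paste(a, b, sep = " -> ")))
  }
  pair_islp <- function(row) {
    if (is.null(patterns) || nrow(patterns) == 0) return(character())
    cs <- span_set(row$cause[[1]], FALSE)
    es <- span_set(row$effect[[1]], FALSE)
    hit <- vapply(seq_len(nrow(patterns)), function(p) {
      all(patterns$cause_words[[p]] %in% cs) &&
        all(patterns$effect_words[[p]] %in% es)
    }, logical(1))
    patterns$id[hit]
  }
  all_rows <- lapply(seq_len(n_total), function(i) train_pairs[i, ])
  wp_by_pair <- lapply(all_rows, pair_wp)
  islp_by_pair <- lapply(all_rows, pair_islp)
  wp_vocab <- unique(unlist(wp_by_pair))
  islp_vocab <- unique(unlist(islp_by_pair))
  count_in_class <- function(feature, by_pair) {
    sum(vapply(cls_rows, function(i) feature %in% by_pair[[i]], logical(1)))
  }
  score <- n_class / n_total
  for (f in pair_wp(test_pair)) {
    score <- score * (count_in_class(f, wp_by_pair) + 1) /
      (n_class + length(wp_vocab))
  }
  if (!is.null(patterns) && nrow(patterns) > 0) {
    for (f in pair_islp(test_pair)) {
      score <- score * (count_in_class(f, islp_by_pair) + 1) /
        (n_class + length(islp_vocab))
    }
  }
  score
}
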