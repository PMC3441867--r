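#' Build a token table
#'
#' Tokens are the atoms of every span: a surface form plus a coarse
#' part-of-speech category. Only three categories are distinguished because
#' pattern generation considers nouns and verbs and ignores everything else.
#'
#' @param surface Character vector of token surfaces. Must be non-empty strings.
#' @param pos Character vector of part-of-speech tags, recycled to the length
#'   of `surface`. Tags are passed through [normalize_pos()], so fine-grained
#'   tagsets (Penn, Universal Dependencies) are accepted.
#' @return A tibble with columns `surface` and `pos`
#'   (`pos` in `"noun"`, `"verb"`, `"other"`).
#' @examples
#' tokens(c("boss", "cut", "my", "salary"), c("noun", "verb", "other", "noun"))
#' @export
tokens <- function(surface, pos = "other") {
  surface <- as.character(surface)
  if (length(surface) > 0 && any(!nzchar(surface) | is.na(surface))) {
    stop("token surfaces must be non-empty strings", call. = FALSE)
  }
  pos <- rep_len(normalize_pos(as.character(pos)), length(surface))
  tibble::tibble(surface = surface, pos = pos)
}

#' Map part-of-speech tags onto the coarse noun/verb/other categories
#'
#' @param pos Character vector of tags from any common tagset.
#' @return Character vector over `"noun"`, `"verb"`, `"other"`.
#' @examples
#' normalize_pos(c("NN", "VBD", "NOUN", "JJ", "verb"))
#' @export
normalize_pos <- function(pos) {
  out <- rep("other", length(pos))
  p <- toupper(pos)
  out[p %in% c("NOUN", "PROPN") | startsWith(p, "NN")] <- "noun"
  out[p %in% c("VERB", "AUX") | startsWith(p, "VB")] <- "verb"
  out[tolower(pos) %in% c("noun", "verb", "other")] <-
    tolower(pos)[tolower(pos) %in% c("noun", "verb", "other")]
  out
}

#' Construct a sentence-pair table
#'
#' A sentence pair is the unit of training and prediction: a cause span and an
#' effect span, each a token table, with an optional causality label.
#'
#' @param id Character vector of unique record identifiers.
#' @param cause,effect Lists of token tables (see [tokens()]).
#' @param label Character vector: `"causality"`, `"non-causality"`, or `NA`
#'   for unlabeled records.
#' @return A tibble with columns `id`, `cause`, `effect`, `label`; `cause` and
#'   `effect` are list-columns of token tables.
#' @export
sentence_pairs <- function(id, cause, effect, label = NA_character_) {
  out <- tibble::tibble(
    id = as.character(id),
    cause = cause,
    effect = effect,
    label = rep_len(as.character(label), length(id))
  )
  validate_pairs(out)
}

validate_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  missing <- setdiff(c("id", "cause", "effect", "label"), names(pairs))
  if (length(missing) > 0) {
    stop("sentence-pair table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pairs$id)) {
    stop("sentence-pair ids must be unique; duplicated: ",
         paste(unique(pairs$id[duplicated(pairs$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !pairs$label %in% c("causality", "non-causality") & !is.na(pairs$label)
  if (any(bad)) {
    stop("invalid label(s): ", paste(unique(pairs$label[bad]), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(pairs)
}

#' Extract content words from a span
#'
#' Returns the surfaces of the noun and verb tokens of a span, in original
#' order, duplicates retained. These are the words pattern mining and the
#' word-pair features operate on.
#'
#' @param span A token table (see [tokens()]).
#' @param all_words If `TRUE`, return every surface regardless of tag.
#' @return Character vector of surfaces.
#' @examples
#' sp <- tokens(c("my", "boss", "cut", "my", "salary"),
#'              c("other", "noun", "verb", "other", "noun"))
#' content_words(sp)
#' @export
content_words <- function(span, all_words = FALSE) {
  if (all_words) return(span$surface)
  span$surface[span$pos %in% c("noun", "verb")]
}

# lowercased word sets per span, for containment matching
span_word_sets <- function(spans, content_only = TRUE) {
  lapply(spans, function(sp) {
    unique(tolower(if (content_only) content_words(sp) else sp$surface))
  })
}

#' Read a discourse-connective lexicon
#'
#' Plain-text format: one `connective<TAB>direction` per line, where direction
#' is `cause-first` (the cause span precedes the connective) or `effect-first`
#' (the cause span follows it). `#` starts a comment; blank lines are skipped.
#' Connectives may be multi-token (space-separated). Matching is case-folded.
#'
#' @param path Path to the lexicon file.
#' @return A tibble with columns `connective` and `direction`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("cannot read lexicon: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("lexicon is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed lexicon line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    connective = tolower(trimws(vapply(parts, `[[`, "", 1))),
    direction = trimws(vapply(parts, `[[`, "", 2))
  )
  if (!all(out$direction %in% c("cause-first", "effect-first"))) {
    stop("lexicon directions must be 'cause-first' or 'effect-first'",
         call. = FALSE)
  }
  if (anyDuplicated(out$connective)) {
    warning("duplicate connectives after case-folding; keeping first entries")
    out <- out[!duplicated(out$connective), ]
  }
  out
}

#' Split a connective-bearing sentence into cause and effect spans
#'
#' Scans the token sequence for lexicon connectives (case-folded; multi-token
#' connectives match contiguous token windows). If a connective is found, it is
#' removed and the two flanking spans are assigned the cause and effect roles
#' according to the connective's direction entry. With several occurrences the
#' first (leftmost, longest at a tie) is used and a warning is raised.
#'
#' @param sentence_tokens A token table for one sentence.
#' @param lexicon A connective lexicon, see [read_lexicon()].
#' @param id Record identifier for the resulting pair.
#' @param label Label to attach (`"causality"` by default, since the split is
#'   what defines an explicit causality sentence).
#' @return A one-row sentence-pair tibble, or `NULL` when no lexicon
#'   connective occurs or when the split would leave an empty span (the latter
#'   with a warning).
#' @examples
#' lex <- tibble::tibble(connective = "because", direction = "effect-first")
#' s <- tokens(c("I", "slept", "because", "boss", "cut", "salary"),
#'             c("other", "verb", "other", "noun", "verb", "noun"))
#' split_on_connective(s, lex, id = "e1")
#' @export
split_on_connective <- function(sentence_tokens, lexicon, id = "s1",
                                label = "causality") {
  surf <- tolower(sentence_tokens$surface)
  n <- length(surf)
  hits <- list()
  for (r in seq_len(nrow(lexicon))) {
    conn <- strsplit(lexicon$connective[r], " ", fixed = TRUE)[[1]]
    k <- length(conn)
    if (k > n) next
    for (start in seq_len(n - k + 1)) {
      if (all(surf[start:(start + k - 1)] == conn)) {
        hits[[length(hits) + 1]] <-
          list(start = start, len = k, direction = lexicon$direction[r])
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  ord <- order(vapply(hits, `[[`, 0, "start"), -vapply(hits, `[[`, 0, "len"))
  if (length(hits) > 1) {
    warning("sentence '", id, "' contains ", length(hits),
            " connective occurrences; splitting on the first")
  }
  h <- hits[[ord[1]]]
  left <- sentence_tokens[seq_len(h$start - 1), , drop = FALSE]
  right <- sentence_tokens[seq(h$start + h$len, length.out = n - h$start - h$len + 1), ,
                           drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) {
    warning("connective at sentence edge leaves an empty span; skipping '",
            id, "'")
    return(NULL)
  }
  if (h$direction == "cause-first") {
    sentence_pairs(id, list(left), list(right), label)
  } else {
    sentence_pairs(id, list(right), list(left), label)
  }
}

#' Split every sentence of a corpus on its discourse connective
#'
#' @param sentences A tibble with columns `id` and `tokens` (list of token
#'   tables).
#' @param lexicon A connective lexicon, see [read_lexicon()].
#' @return A sentence-pair tibble containing one row per sentence in which
#'   exactly one usable connective split was found.
#' @export
split_corpus <- function(sentences, lexicon) {
  rows <- purrr::map2(sentences$tokens, sentences$id,
                      ~ split_on_connective(.x, lexicon, id = .y))
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(sentence_pairs(character(), list(), list(), character()))
  }
  dplyr::bind_rows(rows)
}

token_list_to_df <- function(x, line, field) {
  if (length(x) == 0) return(tokens(character()))
  bad <- vapply(x, function(t) length(t) != 2 || any(!nzchar(t)), TRUE)
  if (any(bad)) {
    stop(sprintf("line %d: field '%s' has malformed [surface, pos] token(s)",
                 line, field), call. = FALSE)
  }
  tokens(vapply(x, `[[`, "", 1), vapply(x, `[[`, "", 2))
}

#' Read a sentence-pair corpus
#'
#' Two line-oriented formats are supported. JSONL (the primary format): one
#' object per line with fields `id`, `cause`, `effect` (arrays of
#' `[surface, pos]` token pairs) and optional `label`. TSV: four columns
#' `id`, cause tokens, effect tokens, `label`, with tokens written as
#' space-separated `surface/pos` items (surfaces containing spaces therefore
#' need JSONL).
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @return A sentence-pair tibble in file order. Malformed lines abort with an
#'   error naming the offending field and line number; an empty file yields an
#'   empty table with a warning.
#' @seealso [write_pairs()]
#' @export
read_pairs <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_idx <- which(nzchar(trimws(lines)))
  if (length(lines_idx) == 0) {
    warning("corpus file is empty: ", path)
    return(sentence_pairs(character(), list(), list(), character()))
  }
  parse_one <- if (format == "jsonl") parse_jsonl_line else parse_tsv_line
  rows <- purrr::map2(lines[lines_idx], lines_idx, parse_one)
  validate_pairs(dplyr::bind_rows(rows))
}

parse_jsonl_line <- function(line, lineno) {
  rec <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("line %d: invalid JSON (%s)", lineno, conditionMessage(e)),
           call. = FALSE)
    }
  )
  for (field in c("id", "cause", "effect")) {
    if (is.null(rec[[field]])) {
      stop(sprintf("line %d: missing mandatory field '%s'", lineno, field),
           call. = FALSE)
    }
  }
  label <- rec$label
  if (is.null(label) || identical(label, "unlabeled")) label <- NA_character_
  tibble::tibble(
    id = as.character(rec$id),
    cause = list(token_list_to_df(rec$cause, lineno, "cause")),
    effect = list(token_list_to_df(rec$effect, lineno, "effect")),
    label = as.character(label)
  )
}

parse_tsv_line <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3) {
    stop(sprintf("line %d: expected 4 tab-separated columns, found %d",
                 lineno, length(parts)), call. = FALSE)
  }
  parse_span <- function(text, field) {
    items <- strsplit(trimws(text), " +")[[1]]
    items <- items[nzchar(items)]
    if (length(items) == 0) return(tokens(character()))
    m <- regmatches(items, regexec("^(.*)/([^/]+)$", items))
    bad <- lengths(m) != 3
    if (any(bad)) {
      stop(sprintf("line %d: field '%s' has token(s) without a /pos suffix",
                   lineno, field), call. = FALSE)
    }
    tokens(vapply(m, `[[`, "", 2), vapply(m, `[[`, "", 3))
  }
  label <- if (length(parts) >= 4 && nzchar(trimws(parts[4])) &&
               trimws(parts[4]) != "unlabeled") trimws(parts[4]) else NA_character_
  tibble::tibble(
    id = parts[1],
    cause = list(parse_span(parts[2], "cause")),
    effect = list(parse_span(parts[3], "effect")),
    label = label
  )
}

#' Write a sentence-pair corpus
#'
#' Inverse of [read_pairs()]; a written corpus reads back field-for-field
#' identical. Output is deterministic (fixed field order, no whitespace
#' variation), so identical tables produce byte-identical files.
#'
#' @param pairs A sentence-pair tibble.
#' @param path Output path.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  pairs <- validate_pairs(pairs)
  lines <- purrr::pmap_chr(pairs, function(id, cause, effect, label) {
    if (format == "jsonl") {
      rec <- list(
        id = id,
        cause = purrr::map2(cause$surface, cause$pos, c),
        effect = purrr::map2(effect$surface, effect$pos, c),
        label = if (is.na(label)) NULL else label
      )
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"))
    } else {
      span_txt <- function(sp) paste(sp$surface, sp$pos, sep = "/", collapse = " ")
      paste(id, span_txt(cause), span_txt(effect),
            if (is.na(label)) "unlabeled" else label, sep = "\t")
    }
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read tokenized sentences (pre-splitting format)
#'
#' One JSON object per line with fields `id` and `tokens` (an array of
#' `[surface, pos]` pairs). This is the input to [split_corpus()]: whole
#' sentences whose discourse connective has not yet been removed.
#'
#' @param path Path to the JSONL file.
#' @return A tibble with columns `id` and `tokens` (list of token tables).
#' @export
read_sentences <- function(path) {
  if (!file.exists(path)) stop("cannot read sentences: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  idx <- which(nzchar(trimws(lines)))
  if (length(idx) == 0) {
    warning("sentence file is empty: ", path)
    return(tibble::tibble(id = character(), tokens = list()))
  }
  rows <- purrr::map2(lines[idx], idx, function(line, lineno) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("line %d: invalid JSON (%s)", lineno,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    for (field in c("id", "tokens")) {
      if (is.null(rec[[field]])) {
        stop(sprintf("line %d: missing mandatory field '%s'", lineno, field),
             call. = FALSE)
      }
    }
    tibble::tibble(id = as.character(rec$id),
                   tokens = list(token_list_to_df(rec$tokens, lineno, "tokens")))
  })
  dplyr::bind_rows(rows)
}
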