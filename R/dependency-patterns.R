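#' Read dependency-parsed spans from a CoNLL-U file
#'
#' Reads the standard 10-column CoNLL-U format produced by any dependency
#' parser. Spans are aligned to corpus records through sentence-id comments of
#' the form `# sent_id = <record-id>/<cause|effect>`. Multiword-token ranges
#' (`1-2`) and empty nodes (`1.1`) are skipped; only basic-dependency token
#' lines are kept.
#'
#' @param path Path to a CoNLL-U file.
#' @return A tibble with columns `record_id`, `side` and `tokens`, where each
#'   `tokens` element is a tibble with `id`, `surface`, `pos` (coarse), `head`
#'   (0 = root) and `deprel`. Head indices out of range, a missing or
#'   duplicated root, or a cyclic parse abort with an error naming the
#'   sentence id. An empty file returns an empty table with a warning.
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) stop("cannot read CoNLL-U file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  empty <- tibble::tibble(record_id = character(), side = character(),
                          tokens = list())
  if (all(!nzchar(trimws(lines)))) {
    warning("CoNLL-U file is empty: ", path)
    return(empty)
  }
  groups <- split(lines, cumsum(!nzchar(trimws(lines))))
  out <- list()
  for (g in groups) {
    g <- g[nzchar(trimws(g))]
    if (length(g) == 0) next
    sent_id <- NA_character_
    id_line <- grep("^#\\s*sent_id\\s*=", g, value = TRUE)
    if (length(id_line) > 0) {
      sent_id <- trimws(sub("^#\\s*sent_id\\s*=", "", id_line[1]))
    }
    tok_lines <- g[!startsWith(g, "#")]
    tok_lines <- tok_lines[!grepl("^[0-9]+[-.][0-9]+\t", tok_lines)]
    if (length(tok_lines) == 0) next
    fields <- strsplit(tok_lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 10)) {
      stop("sentence '", sent_id, "': token line without 10 tab-separated ",
           "columns", call. = FALSE)
    }
    tok <- tibble::tibble(
      id = as.integer(vapply(fields, `[[`, "", 1)),
      surface = vapply(fields, `[[`, "", 2),
      pos = normalize_pos(vapply(fields, `[[`, "", 4)),
      head = suppressWarnings(as.integer(vapply(fields, `[[`, "", 7))),
      deprel = vapply(fields, `[[`, "", 8)
    )
    validate_parse(tok, sent_id)
    if (is.na(sent_id) || !grepl("/(cause|effect)$", sent_id)) {
      stop("sentence id '", sent_id,
           "' does not follow '<record-id>/<cause|effect>'", call. = FALSE)
    }
    out[[length(out) + 1]] <- tibble::tibble(
      record_id = sub("/(cause|effect)$", "", sent_id),
      side = sub("^.*/", "", sent_id),
      tokens = list(tok)
    )
  }
  if (length(out) == 0) {
    warning("CoNLL-U file has no token lines: ", path)
    return(empty)
  }
  dplyr::bind_rows(out)
}

validate_parse <- function(tok, sent_id) {
  n <- nrow(tok)
  if (anyNA(tok$head) || any(tok$head < 0 | tok$head > n)) {
    stop("sentence '", sent_id, "': head index out of range", call. = FALSE)
  }
  if (!identical(tok$id, seq_len(n))) {
    stop("sentence '", sent_id, "': token ids are not 1..n", call. = FALSE)
  }
  if (sum(tok$head == 0) != 1) {
    stop("sentence '", sent_id, "': parse must have exactly one root",
         call. = FALSE)
  }
  # cycle check: every token must reach the root within n steps
  for (i in seq_len(n)) {
    cur <- i
    steps <- 0
    while (tok$head[cur] != 0) {
      cur <- tok$head[cur]
      steps <- steps + 1
      if (steps > n) {
        stop("sentence '", sent_id, "': cyclic parse", call. = FALSE)
      }
    }
  }
  invisible(tok)
}

#' Extract word--head dependency pairs from a parsed span
#'
#' Every non-root token contributes one `(dependent, head)` pair; these pairs
#' are the parse-derived intra-sentential language patterns (scored later by
#' [intra_confidence()] over the span collection, exactly like mined word
#' sets). For a well-formed single-root parse of `n` tokens this yields
#' `n - 1` pairs.
#'
#' @param parsed A parsed-token tibble (one `tokens` element of
#'   [read_conllu()] output).
#' @return A tibble with columns `dependent` and `head` (surfaces).
#' @examples
#' tok <- tibble::tibble(id = 1:3, surface = c("a", "b", "c"),
#'                       pos = "noun", head = c(0L, 1L, 2L), deprel = "dep")
#' extract_dependency_pairs(tok)
#' @export
extract_dependency_pairs <- function(parsed) {
  validate_parse(parsed, sent_id = "<in-memory>")
  dep <- parsed[parsed$head != 0, , drop = FALSE]
  tibble::tibble(
    dependent = dep$surface,
    head = parsed$surface[dep$head]
  )
}

#' Parse-derived intra-sentential patterns for one side
#'
#' Collects the word--head pairs of every parsed span of the requested side,
#' then applies the same support and confidence filters as word-set mining so
#' that parse-derived and mined inventories are comparable. Function words are
#' retained by default (a possessive can head a noun pair); set
#' `content_only = TRUE` to drop pairs involving non-noun/verb tokens.
#'
#' @param parses Output of [read_conllu()].
#' @param pairs The sentence-pair tibble being mined; every pair id must have
#'   a parse for the requested side.
#' @param side `"cause"` or `"effect"`.
#' @param min_support Support floor over the side's spans.
#' @param min_confidence Confidence floor in nats.
#' @param content_only If `TRUE`, keep only pairs whose two words are tagged
#'   noun or verb in the parse.
#' @return An intra-pattern tibble of k = 2 patterns, same shape as
#'   [mine_intra_patterns()] output (words stored in dependent, head order).
#' @export
dependency_intra_patterns <- function(parses, pairs, side = c("cause", "effect"),
                                      min_support = 2, min_confidence = 0.05,
                                      content_only = FALSE) {
  side <- match.arg(side)
  sel <- parses[parses$side == side, , drop = FALSE]
  missing <- setdiff(pairs$id, sel$record_id)
  if (length(missing) > 0) {
    stop("no ", side, " parse for record(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  sel <- sel[match(pairs$id, sel$record_id), , drop = FALSE]
  dep_pairs <- purrr::map(sel$tokens, function(tok) {
    dp <- extract_dependency_pairs(tok)
    if (content_only) {
      content <- tok$surface[tok$pos %in% c("noun", "verb")]
      dp <- dp[dp$dependent %in% content & dp$head %in% content, , drop = FALSE]
    }
    dp
  })
  all_dp <- dplyr::bind_rows(dep_pairs)
  empty <- tibble::tibble(
    side = character(), words = list(), pattern = character(),
    k = integer(), support = integer(), confidence = double(), id = character()
  )
  if (nrow(all_dp) == 0) return(empty)
  all_dp <- dplyr::mutate(all_dp,
                          dependent = tolower(.data$dependent),
                          head = tolower(.data$head))
  all_dp <- dplyr::distinct(all_dp[all_dp$dependent != all_dp$head, ,
                                   drop = FALSE])
  if (nrow(all_dp) == 0) return(empty)
  spans <- span_word_sets(pairs[[side]], content_only = FALSE)
  n <- length(spans)
  word_supp <- new.env(parent = emptyenv())
  supp_of <- function(w) {
    if (is.null(word_supp[[w]])) {
      word_supp[[w]] <- wordset_support(w, spans)
    }
    word_supp[[w]]
  }
  rows <- purrr::pmap(all_dp, function(dependent, head) {
    s <- wordset_support(c(dependent, head), spans)
    if (s < min_support) return(NULL)
    conf <- mi_score(s, c(supp_of(dependent), supp_of(head)), n)
    tibble::tibble(
      side = side,
      words = list(c(dependent, head)),
      pattern = paste0("<", dependent, ", ", head, ">"),
      k = 2L,
      support = as.integer(s),
      confidence = conf,
      id = paste0(side, ":",
                  paste(sort(c(dependent, head), method = "radix"),
                        collapse = ","))
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) return(empty)
  out <- dplyr::distinct(out, .data$id, .keep_all = TRUE)
  out <- out[out$confidence >= min_confidence, , drop = FALSE]
  out[order(-out$confidence, out$id, method = "radix"), , drop = FALSE]
}
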