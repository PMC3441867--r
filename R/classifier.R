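wp_feature_key <- function(cause_word, effect_word) {
  paste(cause_word, effect_word, sep = " -> ")
}

#' Feature representation of sentence pairs
#'
#' Transforms each sentence pair into its two feature sets: the
#' inter-sentential patterns it matches (a pattern matches when every
#' cause-side word occurs in the cause span and every effect-side word in the
#' effect span, case-folded) and the word pairs formed as the full cross
#' product of cause and effect content words. Features are sets: a feature
#' matched several times in one pair counts once.
#'
#' @param pairs A sentence-pair tibble.
#' @param patterns An inter-pattern tibble ([mine_inter_patterns()] output),
#'   or `NULL` for word pairs only.
#' @param wp_all_words If `TRUE`, word pairs are formed over all surfaces
#'   rather than content words only.
#' @return A tibble with columns `id`, `islp_matches` (list of matched
#'   pattern ids) and `word_pairs` (list of `"cause -> effect"` keys).
#' @export
featurize <- function(pairs, patterns = NULL, wp_all_words = FALSE) {
  cause_sets <- span_word_sets(pairs$cause, content_only = FALSE)
  effect_sets <- span_word_sets(pairs$effect, content_only = FALSE)
  cause_cw <- span_word_sets(pairs$cause, content_only = !wp_all_words)
  effect_cw <- span_word_sets(pairs$effect, content_only = !wp_all_words)
  n <- nrow(pairs)
  if (!is.null(patterns) && nrow(patterns) > 0) {
    mc <- pattern_containment(patterns$cause_words, cause_sets)
    me <- pattern_containment(patterns$effect_words, effect_sets)
    matched <- mc & me
    islp <- lapply(seq_len(n), function(i) patterns$id[matched[, i]])
  } else {
    islp <- rep(list(character()), n)
  }
  wp <- purrr::map2(cause_cw, effect_cw, function(cw, ew) {
    if (length(cw) == 0 || length(ew) == 0) return(character())
    grid <- expand.grid(cause = cw, effect = ew,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    unique(wp_feature_key(grid$cause, grid$effect))
  })
  tibble::tibble(id = pairs$id, islp_matches = islp, word_pairs = wp)
}

count_features <- function(feature_sets, labels) {
  df <- tibble::tibble(
    feature = unlist(feature_sets),
    label = rep(labels, lengths(feature_sets))
  )
  if (nrow(df) == 0) {
    return(tibble::tibble(feature = character(),
                          n_causality = integer(), n_noncausality = integer()))
  }
  counts <- dplyr::count(df, .data$feature, .data$label)
  wide <- tidyr::pivot_wider(counts, names_from = "label",
                             values_from = "n", values_fill = 0L)
  for (col in c("causality", "non-causality")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  tibble::tibble(
    feature = wide$feature,
    n_causality = as.integer(wide$causality),
    n_noncausality = as.integer(wide$`non-causality`)
  )
}

#' Train the causality classifier
#'
#' Fits the factored probabilistic model: class priors from relative class
#' frequencies, and per-feature class-conditional probabilities
#' `P(feature | class) = N(feature, class) / N(class)`, where `N(class)` is
#' the number of training pairs of that class and `N(feature, class)` the
#' number of such pairs containing the feature. With additive smoothing
#' (default) the estimate becomes `(N(feature, class) + 1) / (N(class) + V)`
#' with `V` the size of that feature family's training vocabulary, and unseen
#' test features receive the floor `1 / (N(class) + V)`; with
#' `smoothing = "none"` zero-count features are skipped during scoring.
#'
#' @param pairs A labeled sentence-pair tibble; both classes must be present.
#' @param patterns An inter-pattern tibble (the selected inventory), required
#'   when `"islp"` is among `features`.
#' @param features Feature families to use: any of `"wp"`, `"islp"`.
#' @param smoothing `"add_one"` (default) or `"none"`.
#' @param wp_all_words Passed to [featurize()].
#' @return An object of class `causality_model`.
#' @seealso [predict.causality_model()], [tidy.causality_model()]
#' @export
train_classifier <- function(pairs, patterns = NULL,
                             features = c("wp", "islp"),
                             smoothing = c("add_one", "none"),
                             wp_all_words = FALSE) {
  smoothing <- match.arg(smoothing)
  stopifnot(all(features %in% c("wp", "islp")), length(features) >= 1)
  pairs <- pairs[!is.na(pairs$label), , drop = FALSE]
  n_c <- sum(pairs$label == "causality")
  n_nc <- sum(pairs$label == "non-causality")
  if (n_c == 0 || n_nc == 0) {
    stop("training data must contain both classes (causality: ", n_c,
         ", non-causality: ", n_nc, ")", call. = FALSE)
  }
  use_islp <- "islp" %in% features
  if (use_islp && (is.null(patterns) || nrow(patterns) == 0)) {
    patterns <- NULL
    use_islp <- FALSE
  }
  feats <- featurize(pairs, patterns, wp_all_words)
  tables <- list()
  if ("wp" %in% features) {
    tables$wp <- count_features(feats$word_pairs, pairs$label)
  }
  if (use_islp) {
    tables$islp <- count_features(feats$islp_matches, pairs$label)
  }
  structure(
    list(
      priors = c(causality = n_c / (n_c + n_nc),
                 `non-causality` = n_nc / (n_c + n_nc)),
      n_class = c(causality = n_c, `non-causality` = n_nc),
      tables = tables,
      smoothing = smoothing,
      features = intersect(features, c("wp", if (use_islp) "islp")),
      wp_all_words = wp_all_words,
      patterns = patterns
    ),
    class = "causality_model"
  )
}

feature_log_probs <- function(model, type, feats, class) {
  tab <- model$tables[[type]]
  n_class <- model$n_class[[class]]
  col <- if (class == "causality") "n_causality" else "n_noncausality"
  counts <- tab[[col]][match(feats, tab$feature)]
  counts[is.na(counts)] <- 0L
  if (model$smoothing == "add_one") {
    v <- nrow(tab)
    log((counts + 1) / (n_class + v))
  } else {
    out <- rep(0, length(counts))       # zero-count features are skipped
    nz <- counts > 0
    out[nz] <- log(counts[nz] / n_class)
    out
  }
}

#' Predict causality for sentence pairs
#'
#' Scores each pair in the log domain: the class log-prior plus the sum of
#' log-probabilities of every matched inter-sentential pattern and every word
#' pair, per class; the argmax is returned. An exact tie is resolved to
#' `"non-causality"` (the conservative choice for a detector).
#'
#' @param object A `causality_model` from [train_classifier()].
#' @param pairs A sentence-pair tibble to classify.
#' @param ... Unused.
#' @return A tibble with columns `id`, `label` (the prediction),
#'   `log_causality` and `log_noncausality`.
#' @export
predict.causality_model <- function(object, pairs, ...) {
  feats <- featurize(pairs, object$patterns, object$wp_all_words)
  score_class <- function(class) {
    base <- log(object$priors[[class]])
    vapply(seq_len(nrow(feats)), function(i) {
      s <- base
      if ("wp" %in% object$features) {
        s <- s + sum(feature_log_probs(object, "wp",
                                       feats$word_pairs[[i]], class))
      }
      if ("islp" %in% object$features) {
        s <- s + sum(feature_log_probs(object, "islp",
                                       feats$islp_matches[[i]], class))
      }
      s
    }, double(1))
  }
  lc <- score_class("causality")
  lnc <- score_class("non-causality")
  tibble::tibble(
    id = pairs$id,
    label = ifelse(lc > lnc, "causality", "non-causality"),
    log_causality = lc,
    log_noncausality = lnc
  )
}

#' @export
print.causality_model <- function(x, ...) {
  cat("Causality detection model\n")
  cat(sprintf("  prior P(causality) = %.4f  (n = %d vs %d)\n",
              x$priors[["causality"]], x$n_class[["causality"]],
              x$n_class[["non-causality"]]))
  for (type in names(x$tables)) {
    cat(sprintf("  %s features: %d\n", type, nrow(x$tables[[type]])))
  }
  cat("  smoothing:", x$smoothing, "\n")
  invisible(x)
}

#' Tidy a causality model's feature tables
#'
#' @param x A `causality_model`.
#' @param ... Unused.
#' @return A tibble with one row per (feature family, feature): counts and
#'   smoothed class-conditional probabilities.
#' @export
tidy.causality_model <- function(x, ...) {
  purrr::imap_dfr(x$tables, function(tab, type) {
    if (nrow(tab) == 0) {
      return(tibble::tibble(type = character(), feature = character(),
                            n_causality = integer(), n_noncausality = integer(),
                            p_causality = double(), p_noncausality = double()))
    }
    p_c <- exp(feature_log_probs(x, type, tab$feature, "causality"))
    p_n <- exp(feature_log_probs(x, type, tab$feature, "non-causality"))
    tibble::tibble(
      type = type,
      feature = tab$feature,
      n_causality = tab$n_causality,
      n_noncausality = tab$n_noncausality,
      p_causality = p_c,
      p_noncausality = p_n
    )
  })
}

#' One-row summary of a causality model
#'
#' @param x A `causality_model`.
#' @param ... Unused.
#' @return A one-row tibble: training sizes, prior, feature counts, smoothing.
#' @export
glance.causality_model <- function(x, ...) {
  tibble::tibble(
    n_train = sum(x$n_class),
    n_causality = x$n_class[["causality"]],
    n_noncausality = x$n_class[["non-causality"]],
    prior_causality = x$priors[["causality"]],
    n_wp_features = if (!is.null(x$tables$wp)) nrow(x$tables$wp) else 0L,
    n_islp_features = if (!is.null(x$tables$islp)) nrow(x$tables$islp) else 0L,
    n_patterns = if (!is.null(x$patterns)) nrow(x$patterns) else 0L,
    smoothing = x$smoothing
  )
}

#' Persist a trained model as versioned JSON
#'
#' @param model A `causality_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "causality_model"))
  payload <- list(
    format = "causepattern-model",
    version = 1L,
    priors = as.list(model$priors),
    n_class = as.list(model$n_class),
    smoothing = model$smoothing,
    features = model$features,
    wp_all_words = model$wp_all_words,
    tables = lapply(model$tables, as.data.frame),
    patterns = if (is.null(model$patterns)) NULL else {
      p <- model$patterns
      lapply(seq_len(nrow(p)), function(i) list(
        id = p$id[i],
        cause_patterns = as.list(p$cause_patterns[[i]]),
        effect_patterns = as.list(p$effect_patterns[[i]]),
        cause_words = as.list(p$cause_words[[i]]),
        effect_words = as.list(p$effect_words[[i]]),
        pattern = p$pattern[i], k = p$k[i],
        support = p$support[i], confidence = p$confidence[i]
      ))
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `causality_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
  if (!identical(payload$format, "causepattern-model")) {
    stop("not a causepattern model file: ", path, call. = FALSE)
  }
  patterns <- NULL
  if (!is.null(payload$patterns) && length(payload$patterns) > 0) {
    p <- payload$patterns
    patterns <- tibble::tibble(
      cause_patterns = lapply(p$cause_patterns, unlist),
      effect_patterns = lapply(p$effect_patterns, unlist),
      cause_words = lapply(p$cause_words, unlist),
      effect_words = lapply(p$effect_words, unlist),
      pattern = p$pattern, k = as.integer(p$k),
      support = as.integer(p$support), confidence = p$confidence,
      id = p$id
    )
  }
  structure(
    list(
      priors = unlist(payload$priors),
      n_class = unlist(payload$n_class),
      tables = lapply(payload$tables, tibble::as_tibble),
      smoothing = payload$smoothing,
      features = payload$features,
      wp_all_words = isTRUE(payload$wp_all_words),
      patterns = patterns
    ),
    class = "causality_model"
  )
}
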