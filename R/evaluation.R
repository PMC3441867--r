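#' Score predictions against gold labels
#'
#' Computes the confusion counts with `"causality"` as the positive class and
#' derives recall (correctly identified causality pairs over gold causality
#' pairs), precision (over predicted causality pairs) and the F-measure
#' `2RP / (R + P)`. Degenerate cases use the conventions: no predicted
#' positives gives precision 0, no gold positives gives recall 0, and
#' `R + P = 0` gives F 0.
#'
#' @param predictions A tibble with columns `id` and `label` (e.g.
#'   [predict.causality_model()] output).
#' @param gold A tibble with columns `id` and `label` carrying the gold
#'   labels (a sentence-pair tibble works). Ids must match the predictions
#'   one-to-one; order is irrelevant.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `recall`, `precision`,
#'   `f_measure`.
#' @export
score_predictions <- function(predictions, gold) {
  if (!setequal(predictions$id, gold$id) ||
      nrow(predictions) != nrow(gold)) {
    stop("prediction and gold ids do not match one-to-one", call. = FALSE)
  }
  g <- gold$label[match(predictions$id, gold$id)]
  p <- predictions$label
  tp <- sum(p == "causality" & g == "causality")
  fp <- sum(p == "causality" & g != "causality")
  fn <- sum(p != "causality" & g == "causality")
  tn <- sum(p != "causality" & g != "causality")
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 recall = recall, precision = precision, f_measure = f)
}

#' Stratified fold assignment
#'
#' @param pairs A labeled sentence-pair tibble.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Integer vector of fold ids aligned with `pairs` rows. Errors when
#'   a class is so small that some training split would lose it entirely.
#' @export
make_folds <- function(pairs, k, seed = 13) {
  stopifnot(k >= 2)
  labels <- pairs$label
  if (anyNA(labels)) stop("all pairs must be labeled for cross-validation",
                          call. = FALSE)
  fold <- integer(nrow(pairs))
  withr::with_seed(seed, {
    # round-robin within each class, carrying the offset across classes so
    # overall fold sizes stay balanced within one
    offset <- 0L
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[sample(idx)] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  for (f in seq_len(k)) {
    train_labels <- labels[fold != f]
    if (length(unique(train_labels)) < 2) {
      stop("class absent from the training split of fold ", f,
           "; use fewer folds or more data", call. = FALSE)
    }
  }
  fold
}

#' k-fold cross-validated causality detection
#'
#' For every fold, pattern mining and model estimation use only that fold's
#' training split (the harness asserts the id-disjointness of the splits, so
#' no test pair ever leaks into mining or probability estimation), then the
#' held-out fold is scored. Folds are stratified by class and seeded.
#'
#' @param pairs A labeled sentence-pair tibble.
#' @param k Number of folds (default 10).
#' @param feature_sets Character vector over `"wp"`, `"wp+islp_arm"`,
#'   `"wp+islp_parsing"` (the last requires `parses`).
#' @param min_support,intra_min_confidence,top_frac,max_k_intra,max_k_inter
#'   Mining configuration, see [mine_patterns()].
#' @param smoothing Classifier smoothing, see [train_classifier()].
#' @param seed Integer seed driving fold assignment (and training-set
#'   subsampling when `training_fraction < 1`).
#' @param parses [read_conllu()] output for the parsing feature set.
#' @param training_fraction Fraction of each training split actually used
#'   (stratified subsample); 1 uses the full split.
#' @return A tibble of class `cp_cv`: one row per fold and feature set with
#'   confusion counts and metrics. Attributes record the configuration.
#' @export
kfold_cv <- function(pairs, k = 10,
                     feature_sets = c("wp", "wp+islp_arm"),
                     min_support = 2, intra_min_confidence = 0.05,
                     top_frac = 0.3, max_k_intra = 8, max_k_inter = 4,
                     smoothing = "add_one", seed = 13, parses = NULL,
                     training_fraction = 1) {
  stopifnot(all(feature_sets %in% c("wp", "wp+islp_arm", "wp+islp_parsing")))
  if ("wp+islp_parsing" %in% feature_sets && is.null(parses)) {
    stop("feature set 'wp+islp_parsing' requires `parses`", call. = FALSE)
  }
  fold <- make_folds(pairs, k, seed)
  out <- list()
  for (f in seq_len(k)) {
    train <- pairs[fold != f, , drop = FALSE]
    test <- pairs[fold == f, , drop = FALSE]
    stopifnot(length(intersect(train$id, test$id)) == 0)
    if (training_fraction < 1) {
      train <- stratified_subsample(train, training_fraction,
                                    seed = seed + 1000L * f)
    }
    need_arm <- "wp+islp_arm" %in% feature_sets
    need_parsing <- "wp+islp_parsing" %in% feature_sets
    pat_arm <- if (need_arm) {
      mine_patterns(train, min_support, intra_min_confidence, top_frac,
                    max_k_intra, max_k_inter, method = "arm")$inter
    }
    pat_parsing <- if (need_parsing) {
      mine_patterns(train, min_support, intra_min_confidence, top_frac,
                    max_k_intra, max_k_inter, method = "parsing",
                    parses = parses)$inter
    }
    for (fs in feature_sets) {
      patterns <- switch(fs, wp = NULL, `wp+islp_arm` = pat_arm,
                         `wp+islp_parsing` = pat_parsing)
      features <- if (fs == "wp") "wp" else c("wp", "islp")
      model <- train_classifier(train, patterns, features, smoothing)
      res <- score_predictions(stats::predict(model, test), test)
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble::tibble(fold = f, feature_set = fs), res
      )
    }
  }
  res <- dplyr::bind_rows(out)
  structure(res,
            class = c("cp_cv", class(res)),
            k = k, seed = seed, top_frac = top_frac,
            min_support = min_support,
            training_fraction = training_fraction)
}

stratified_subsample <- function(pairs, fraction, seed) {
  keep <- integer()
  withr::with_seed(seed, {
    for (cls in unique(pairs$label)) {
      idx <- which(pairs$label == cls)
      n_keep <- max(1L, round(fraction * length(idx)))
      keep <- c(keep, sample(idx, n_keep))
    }
  })
  pairs[sort(keep), , drop = FALSE]
}

#' Mean metrics of a cross-validation run
#'
#' @param cv A `cp_cv` tibble from [kfold_cv()].
#' @return A tibble with one row per feature set: mean recall, precision and
#'   F-measure over folds.
#' @export
cv_summary <- function(cv) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cv), .data$feature_set),
    recall = mean(.data$recall),
    precision = mean(.data$precision),
    f_measure = mean(.data$f_measure),
    .groups = "drop"
  )
}

#' Paired two-tailed t-test between two feature sets
#'
#' Compares per-fold F-measures of two feature sets evaluated on the same
#' folds. Two degenerate cases are handled explicitly: identical fold values
#' report `t = 0, p = 1`; a constant nonzero difference has zero variance,
#' making the statistic unbounded, and is reported with `p = 0` and the
#' `degenerate` flag set.
#'
#' @param fold_results_a,fold_results_b Numeric vectors of per-fold
#'   F-measures, or `cp_cv` tibbles restricted to one feature set each.
#' @return A one-row tibble: `mean_diff` (a minus b), `t`, `df`, `p_value`,
#'   `degenerate`.
#' @export
compare_feature_sets <- function(fold_results_a, fold_results_b) {
  fvals <- function(x) {
    if (is.data.frame(x)) {
      if (length(unique(x$feature_set)) != 1) {
        stop("pass a cp_cv table restricted to a single feature set",
             call. = FALSE)
      }
      x$f_measure[order(x$fold)]
    } else {
      as.numeric(x)
    }
  }
  a <- fvals(fold_results_a)
  b <- fvals(fold_results_b)
  if (length(a) != length(b)) stop("fold lists must have equal length",
                                   call. = FALSE)
  if (length(a) < 2) stop("need at least 2 folds for a paired t-test",
                          call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(mean_diff = 0, t = 0, df = length(d) - 1,
                            p_value = 1, degenerate = TRUE))
    }
    return(tibble::tibble(mean_diff = mean(d), t = sign(mean(d)) * Inf,
                          df = length(d) - 1, p_value = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  tibble::tibble(mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 degenerate = FALSE)
}

#' Sweep a tuning axis across feature sets
#'
#' Reruns the full cross-validated pipeline at each setting of either the
#' training-set fraction or the top-fraction pattern-selection threshold, and
#' records the mean metrics per feature set.
#'
#' @param pairs A labeled sentence-pair tibble.
#' @param axis `"training_fraction"` or `"top_frac"`.
#' @param settings Strictly increasing values in `(0, 1]`.
#' @param feature_sets,k,seed,parses,... Passed to [kfold_cv()].
#' @return A tibble of class `cp_sweep`: one row per (setting, feature set)
#'   with mean recall, precision and F-measure.
#' @export
sweep_performance <- function(pairs, axis = c("training_fraction", "top_frac"),
                              settings, feature_sets = c("wp", "wp+islp_arm"),
                              k = 10, seed = 13, parses = NULL, ...) {
  axis <- match.arg(axis)
  stopifnot(all(settings > 0), all(settings <= 1),
            all(diff(settings) > 0))
  rows <- purrr::map(settings, function(s) {
    cv <- if (axis == "training_fraction") {
      kfold_cv(pairs, k = k, feature_sets = feature_sets, seed = seed,
               parses = parses, training_fraction = s, ...)
    } else {
      kfold_cv(pairs, k = k, feature_sets = feature_sets, seed = seed,
               parses = parses, top_frac = s, ...)
    }
    dplyr::mutate(cv_summary(cv), axis = axis, setting = s, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cp_sweep", class(out)))
}

#' Plot a parameter sweep
#'
#' @param object A `cp_sweep` tibble from [sweep_performance()].
#' @param ... Unused.
#' @return A ggplot: mean F-measure against the swept setting, one line per
#'   feature set.
#' @export
autoplot.cp_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$setting, y = .data$f_measure,
                               colour = .data$feature_set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$axis), y = "mean F-measure",
                  colour = "feature set") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation results
#'
#' @param object A `cp_cv` tibble from [kfold_cv()].
#' @param ... Unused.
#' @return A ggplot: per-fold F-measure by feature set.
#' @export
autoplot.cp_cv <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$feature_set, y = .data$f_measure)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)),
                        position = ggplot2::position_jitter(width = 0.08),
                        alpha = 0.8) +
    ggplot2::labs(x = "feature set", y = "F-measure", colour = "fold") +
    ggplot2::theme_minimal()
}
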