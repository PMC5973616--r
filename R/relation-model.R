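# Relation classification: TF-IDF unigram+bigram features, one-vs-all
# linear SVM, oversampling for class imbalance, and the evaluation
# metrics (per-class and macro-averaged P/R/F1, accuracy).

instance_terms <- function(tokens) {
  uni <- tokens
  bi <- if (length(tokens) > 1) {
    paste(tokens[-length(tokens)], tokens[-1])
  } else character(0)
  c(uni, bi)
}

#' Fit a TF-IDF model over candidate instances
#'
#' Builds the unigram+bigram vocabulary and the inverse document
#' frequencies over the training sentences: `tf(t, s) = f_ts` (raw count
#' of term `t` in sentence `s`), `idf(t) = log(N / n_t)` with `N` the
#' number of sentences and `n_t` the number of sentences containing `t`,
#' and the feature value is `f_ts * log(N / n_t)`. No sublinear scaling or
#' row normalization is applied.
#'
#' @param instances Instance tibble with a `tokens` list column.
#' @return Object of class `tfidf_model` (vocabulary + idf weights).
#' @export
fit_tfidf <- function(instances) {
  stopifnot(is.data.frame(instances))
  if (nrow(instances) == 0) abort("cannot fit TF-IDF on an empty corpus")
  term_lists <- map(instances$tokens, instance_terms)
  vocab <- sort(unique(unlist(term_lists)))
  n_t <- table(factor(unlist(map(term_lists, unique)), levels = vocab))
  N <- length(term_lists)
  structure(
    list(vocabulary = setNames(seq_along(vocab), vocab),
         idf = setNames(log(N / as.numeric(n_t)), vocab),
         n_sentences = N),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("<tfidf_model: %d terms over %d sentences>\n",
              length(x$vocabulary), x$n_sentences))
  invisible(x)
}

#' Featurize instances under a fitted TF-IDF model
#'
#' @param model A `tfidf_model`.
#' @param instances Instance tibble with a `tokens` list column. Terms
#'   absent from the training vocabulary are dropped.
#' @return Sparse `dgCMatrix` (instances x vocabulary).
#' @export
tfidf_features <- function(model, instances) {
  stopifnot(inherits(model, "tfidf_model"))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(nrow(instances))) {
    terms <- instance_terms(instances$tokens[[r]])
    counts <- table(terms)
    keep <- names(counts) %in% names(model$vocabulary)
    counts <- counts[keep]
    if (length(counts) == 0) next
    j <- model$vocabulary[names(counts)]
    ii <- c(ii, rep(r, length(j)))
    jj <- c(jj, unname(j))
    xx <- c(xx, as.numeric(counts) * unname(model$idf[names(counts)]))
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(nrow(instances), length(model$vocabulary)),
    dimnames = list(NULL, names(model$vocabulary)))
}

#' Oversample training instances by per-class factors
#'
#' A class of size `m` with factor `f >= 1` grows to `round(m * f)`
#' instances: every instance is kept `floor(f)` times and the fractional
#' remainder is filled by a seeded uniform sample without replacement.
#' Intended for training folds only; evaluation folds are never
#' oversampled.
#'
#' @param instances Instance tibble with a `label` column.
#' @param factors Named numeric vector, e.g.
#'   `c(negative = 12, positive = 1.35)`; classes not named keep factor 1.
#' @param seed Integer seed for the fractional remainder draw.
#' @return Row-expanded instance tibble.
#' @export
oversample <- function(instances, factors = c(negative = 12,
                                              positive = 1.35),
                       seed = 1L) {
  stopifnot(is.data.frame(instances), "label" %in% names(instances))
  if (any(factors < 1)) abort("oversampling factors must be >= 1")
  withr::with_seed(seed, {
    parts <- map(split(seq_len(nrow(instances)), instances$label),
                 function(idx) {
      cls <- instances$label[idx[1]]
      f <- if (cls %in% names(factors)) factors[[cls]] else 1
      m <- length(idx)
      target <- round(m * f)
      base <- rep(idx, floor(f))
      extra <- target - m * floor(f)
      if (extra > 0) base <- c(base, sample(idx, extra))
      base
    })
    instances[sort(unlist(parts)), ]
  })
}

#' Train the one-vs-all TF-IDF linear SVM relation classifier
#'
#' Fits one binary linear support vector machine per class (`positive`,
#' `negative`, `no-association`) on TF-IDF unigram+bigram features;
#' prediction takes the argmax of the three decision values.
#'
#' @param instances Training instances with `tokens` list column and
#'   `label` column.
#' @param cost SVM regularization constant (default 1).
#' @param oversample_factors Per-class oversampling factors applied to the
#'   training data (default `c(negative = 12, positive = 1.35)`); `NULL`
#'   disables oversampling.
#' @param seed Seed for the fractional oversampling draw.
#' @return Object of class `relation_model`.
#' @export
train_relation_svm <- function(instances, cost = 1,
                               oversample_factors = c(negative = 12,
                                                      positive = 1.35),
                               seed = 1L) {
  stopifnot(is.data.frame(instances), "label" %in% names(instances))
  bad <- setdiff(unique(instances$label), canonical_labels())
  if (length(bad) > 0) {
    abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(unique(instances$label)) < 2) {
    abort("training data must contain at least two classes")
  }
  if (!is.null(oversample_factors)) {
    instances <- oversample(instances, oversample_factors, seed = seed)
  }
  tfidf <- fit_tfidf(instances)
  x <- as.matrix(tfidf_features(tfidf, instances))
  classes <- intersect(canonical_labels(), unique(instances$label))
  svms <- map(setNames(classes, classes), function(cls) {
    y <- factor(ifelse(instances$label == cls, "yes", "no"),
                levels = c("yes", "no"))
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  })
  structure(list(tfidf = tfidf, svms = svms, classes = classes,
                 cost = cost, n_train = nrow(instances)),
            class = "relation_model")
}

#' @export
print.relation_model <- function(x, ...) {
  cat(sprintf(
    "<relation_model: one-vs-all linear SVM, %d classes, %d training instances, %d features>\n",
    length(x$classes), x$n_train, length(x$tfidf$vocabulary)))
  invisible(x)
}

#' Predict association classes for candidate instances
#'
#' @param object A `relation_model`.
#' @param instances Instance tibble with a `tokens` list column.
#' @param ... Unused.
#' @return Tibble: `instance_id` (if present), `.pred`, and one
#'   `score_<class>` decision-value column per class.
#' @export
predict.relation_model <- function(object, instances, ...) {
  x <- as.matrix(tfidf_features(object$tfidf, instances))
  scores <- map(object$svms, function(m) {
    dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")
    # decision value is signed toward the first factor level ("yes")
    if (grepl("^yes/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  })
  score_mat <- do.call(cbind, scores)
  pred <- object$classes[max.col(score_mat, ties.method = "first")]
  out <- tibble(.pred = pred)
  if ("instance_id" %in% names(instances)) {
    out <- bind_cols(tibble(instance_id = instances$instance_id), out)
  }
  bind_cols(out, as_tibble(setNames(as.data.frame(score_mat),
                                    paste0("score_", object$classes))))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Numeric vectors (proportions or percentages;
#'   the result is on the same scale).
#' @return `2 * precision * recall / (precision + recall)`, 0 where both
#'   are 0.
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Evaluate predictions against gold labels
#'
#' Builds one-vs-rest confusion tables per class and reports per-class
#' precision, recall and F1, overall accuracy, and macro-averaged
#' (unweighted class mean) precision, recall and F1. Undefined ratios
#' (0/0) are reported as 0 with a warning.
#'
#' @param predictions Character vector of predicted labels (or a tibble
#'   with a `.pred` column).
#' @param gold Character vector of gold labels, same length.
#' @return Object of class `relation_metrics`: list with `per_class`
#'   tibble (`class`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f1`), `accuracy`, and `macro` (named vector).
#' @export
evaluate_relations <- function(predictions, gold) {
  if (is.data.frame(predictions)) predictions <- predictions$.pred
  stopifnot(length(predictions) == length(gold))
  labs <- canonical_labels()
  bad <- setdiff(unique(c(predictions, gold)), labs)
  if (length(bad) > 0) {
    abort(sprintf("label(s) outside the 3-class set: %s",
                  paste(bad, collapse = ", ")))
  }
  n <- length(gold)
  per_class <- bind_rows(map(labs, function(cls) {
    tp <- sum(predictions == cls & gold == cls)
    fp <- sum(predictions == cls & gold != cls)
    fn <- sum(predictions != cls & gold == cls)
    tn <- n - tp - fp - fn
    if (tp + fp == 0 || tp + fn == 0) {
      warn(sprintf("undefined precision/recall for class `%s` reported as 0",
                   cls))
    }
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    tibble(class = cls, tp = tp, fp = fp, fn = fn, tn = tn,
           precision = precision, recall = recall,
           f1 = f_measure(precision, recall))
  }))
  structure(
    list(per_class = per_class,
         accuracy = mean(predictions == gold),
         macro = c(precision = mean(per_class$precision),
                   recall = mean(per_class$recall),
                   f1 = mean(per_class$f1))),
    class = "relation_metrics"
  )
}

#' @export
print.relation_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro["precision"], x$macro["recall"],
              x$macro["f1"]))
  print(x$per_class)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.relation_metrics <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.relation_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         macro_precision = unname(x$macro["precision"]),
         macro_recall = unname(x$macro["recall"]),
         macro_f1 = unname(x$macro["f1"]))
}

#' Plot per-class evaluation metrics
#'
#' @param object A `relation_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.relation_metrics <- function(object, ...) {
  df <- object$per_class |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-class relation-extraction metrics")
}

#' Stratified k-fold cross-validation of the relation classifier
#'
#' Folds are stratified by class; oversampling is applied inside training
#' folds only, so duplicated instances never cross a train/validation
#' boundary and evaluation folds keep their natural class ratio. When
#' several costs are supplied, the grid is scored by mean validation
#' macro-F1 and the best cost reported.
#'
#' @param instances Labeled instance tibble.
#' @param k Number of folds (default 5).
#' @param seed Seed controlling fold assignment and oversampling.
#' @param costs Numeric vector of SVM costs to try.
#' @param oversample_factors Passed to [train_relation_svm()].
#' @return List: `folds` (per-fold, per-cost metrics tibble),
#'   `best_cost`, `assignments` (fold id per instance).
#' @export
cross_validate <- function(instances, k = 5L, seed = 1L, costs = 1,
                           oversample_factors = c(negative = 12,
                                                  positive = 1.35)) {
  stopifnot(is.data.frame(instances), "label" %in% names(instances))
  if (k < 2) abort("k must be >= 2")
  sizes <- table(instances$label)
  if (any(sizes < k)) {
    abort(sprintf(
      "class `%s` has fewer than k = %d members; use a smaller k",
      names(sizes)[which.min(sizes)], k))
  }
  assignments <- integer(nrow(instances))
  withr::with_seed(seed, {
    for (cls in names(sizes)) {
      idx <- which(instances$label == cls)
      assignments[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  grid <- tidyr::expand_grid(cost = costs, fold = seq_len(k))
  folds <- pmap(grid, function(cost, fold) {
    train <- instances[assignments != fold, ]
    val <- instances[assignments == fold, ]
    fit <- train_relation_svm(train, cost = cost,
                              oversample_factors = oversample_factors,
                              seed = seed + fold)
    m <- evaluate_relations(predict(fit, val), val$label)
    tibble(cost = cost, fold = fold, accuracy = m$accuracy,
           macro_f1 = unname(m$macro["f1"]),
           macro_precision = unname(m$macro["precision"]),
           macro_recall = unname(m$macro["recall"]))
  }) |> bind_rows()
  best <- folds |>
    group_by(.data$cost) |>
    summarise(mean_macro_f1 = mean(.data$macro_f1), .groups = "drop") |>
    arrange(desc(.data$mean_macro_f1))
  list(folds = folds, best_cost = best$cost[1], assignments = assignments)
}
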