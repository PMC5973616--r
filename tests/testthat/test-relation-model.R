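mk_instances <- function(token_lists, labels = NULL) {
  out <- tibble::tibble(
    instance_id = paste0("i", seq_along(token_lists)),
    doc_id = paste0("d", seq_along(token_lists)),
    tokens = token_lists)
  if (!is.null(labels)) out$label <- labels
  out
}

test_that("TF-IDF weights follow f_ts * log(N / n_t)", {
  # term present in every sentence gets idf 0
  inst <- mk_instances(list(c("a", "b"), c("a", "c"), c("a", "d")))
  m <- fit_tfidf(inst)
  expect_equal(unname(m$idf["a"]), 0)
  x <- tfidf_features(m, inst)
  expect_true(all(x[, "a"] == 0))

  # N = 10, n_t = 1, f_ts = 2 -> weight 2 * log(10)
  tl <- c(list(c("t", "t", "u")), replicate(9, c("u", "v"), simplify = FALSE))
  m10 <- fit_tfidf(mk_instances(tl))
  x10 <- tfidf_features(m10, mk_instances(tl))
  expect_equal(unname(x10[1, "t"]), 2 * log(10))

  # identical sentences get identical feature rows
  twin <- mk_instances(list(c("p", "q"), c("p", "q")))
  xt <- tfidf_features(fit_tfidf(twin), twin)
  expect_equal(xt[1, ], xt[2, ])

  # bigrams are part of the vocabulary
  expect_true("p q" %in% names(fit_tfidf(twin)$vocabulary))
  expect_error(fit_tfidf(mk_instances(list())), "empty")
})

test_that("oversampling hits round(m * factor) with seeded remainders", {
  inst10 <- mk_instances(replicate(10, c("x"), simplify = FALSE),
                         labels = rep("negative", 10))
  expect_equal(nrow(oversample(inst10, c(negative = 12))), 120)
  expect_equal(nrow(oversample(inst10, c(negative = 1))), 10)

  inst100 <- mk_instances(replicate(100, c("x"), simplify = FALSE),
                          labels = rep("positive", 100))
  out135 <- oversample(inst100, c(positive = 1.35), seed = 4)
  expect_equal(nrow(out135), 135)
  # duplicates only ever copy existing instances
  expect_true(all(out135$instance_id %in% inst100$instance_id))
  # fractional remainder is drawn without replacement
  expect_true(max(table(out135$instance_id)) <= 2)
  # deterministic given the seed
  expect_identical(oversample(inst100, c(positive = 1.35), seed = 4), out135)
  expect_error(oversample(inst10, c(negative = 0.5)), ">= 1")
})

test_that("one-vs-all SVM separates a separable toy and rejects one class", {
  set.seed(17)
  cues <- list(positive = c("improved", "reduced"),
               negative = c("worsened", "caused"),
               `no-association` = c("mentioned", "recorded"))
  labels <- rep(names(cues), each = 20)
  toks <- lapply(labels, function(cls) {
    c(sample(c("the", "subject", "spice"), 3, replace = TRUE),
      sample(cues[[cls]], 1))
  })
  inst <- mk_instances(toks, labels)
  fit <- train_relation_svm(inst, oversample_factors = NULL)
  pred <- predict(fit, inst)
  expect_equal(mean(pred$.pred == labels), 1)
  expect_true(all(c("score_positive", "score_negative",
                    "score_no-association") %in% names(pred)))

  expect_error(train_relation_svm(
    mk_instances(toks[1:5], labels = rep("positive", 5))), "two classes")
  expect_error(train_relation_svm(
    mk_instances(toks[1:5], labels = rep("bogus", 5))), "unknown label")
})

test_that("evaluation equals a brute-force confusion oracle", {
  set.seed(99)
  labs <- c("no-association", "negative", "positive")
  for (trial in 1:200) {
    n <- sample(5:60, 1)
    pred <- sample(labs, n, replace = TRUE)
    gold <- sample(labs, n, replace = TRUE)
    m <- suppressWarnings(evaluate_relations(pred, gold))
    o <- oracle_metrics(pred, gold, labs)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$per_class$precision, unname(o$per_class[, "precision"]))
    expect_equal(m$per_class$recall, unname(o$per_class[, "recall"]))
    expect_equal(m$per_class$f1, unname(o$per_class[, "f1"]))
    expect_equal(unname(m$macro), unname(o$macro))
    # harmonic-mean bounds
    ok <- m$per_class$precision + m$per_class$recall > 0
    expect_true(all(m$per_class$f1[ok] <= 1e-12 +
                      pmax(m$per_class$precision, m$per_class$recall)[ok]))
    expect_true(all(m$per_class$f1[ok] >= -1e-12 +
                      pmin(m$per_class$precision, m$per_class$recall)[ok]))
  }
})

test_that("evaluation handles edge labels and degenerate ratios", {
  perfect <- suppressWarnings(
    evaluate_relations(rep("positive", 3), rep("positive", 3)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$f1[perfect$per_class$class == "positive"], 1)
  w <- testthat::capture_warnings(
    evaluate_relations(rep("positive", 3), rep("negative", 3)))
  expect_true(any(grepl("undefined", w)))
  expect_error(evaluate_relations(c("positive", "weird"),
                                  c("positive", "positive")), "3-class")
})

test_that("cross-validation stratifies, is seeded, and never leaks", {
  set.seed(5)
  labs <- rep(c("positive", "negative", "no-association"), c(40, 20, 40))
  toks <- lapply(labs, function(cls) c(cls, sample(letters[1:5], 3, TRUE)))
  inst <- mk_instances(toks, labs)
  cv <- cross_validate(inst, k = 5, seed = 2,
                       oversample_factors = c(negative = 2))
  expect_equal(length(cv$assignments), 100)
  expect_equal(as.integer(table(cv$assignments)), rep(20L, 5))
  # stratification: each fold has the class proportions of the whole
  for (f in 1:5) {
    counts <- table(labs[cv$assignments == f])
    expect_equal(as.integer(counts[c("positive", "negative",
                                     "no-association")]),
                 c(8L, 4L, 8L))
  }
  cv2 <- cross_validate(inst, k = 5, seed = 2,
                        oversample_factors = c(negative = 2))
  expect_identical(cv$assignments, cv2$assignments)
  expect_error(cross_validate(inst[c(1:5, 41:45, 61:65), ], k = 10),
               "smaller k")
})

test_that("oversampled duplicates never cross a train/validation boundary", {
  set.seed(6)
  labs <- rep(c("positive", "negative", "no-association"), c(10, 10, 10))
  inst <- mk_instances(lapply(labs, function(x) c(x, "filler")), labs)
  k <- 3
  assign <- rep(1:k, length.out = 30)
  for (f in 1:k) {
    train <- inst[assign != f, ]
    over <- oversample(train, c(negative = 3, positive = 2.5), seed = f)
    expect_true(all(over$instance_id %in% train$instance_id))
    expect_false(any(over$instance_id %in% inst$instance_id[assign == f]))
    # evaluation fold class ratio untouched by construction
    expect_equal(table(inst$label[assign == f]),
                 table(inst$label[assign == f]))
  }
})
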