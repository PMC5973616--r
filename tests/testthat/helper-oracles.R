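# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive longest-match scan: at each position try every pattern
# (O(n^2 * |dict|)), pick the longest that matches, leftmost-first,
# non-overlapping (resume after an emitted match). Returns the same
# column layout as match-based taggers.
oracle_tag <- function(tokens, patterns, ids) {
  pat_tokens <- lapply(patterns, function(p) strsplit(p, " ", fixed = TRUE)[[1]])
  n <- length(tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    best_len <- 0L
    best_j <- NA_integer_
    for (j in seq_along(pat_tokens)) {
      L <- length(pat_tokens[[j]])
      if (L > best_len && i + L - 1L <= n &&
          identical(tokens[i:(i + L - 1L)], pat_tokens[[j]])) {
        best_len <- L
        best_j <- j
      }
    }
    if (best_len > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        token_start = i - 1L, token_end = i - 1L + best_len,
        surface = patterns[best_j], normalized_id = ids[best_j],
        stringsAsFactors = FALSE)
      i <- i + best_len
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    data.frame(token_start = integer(0), token_end = integer(0),
               surface = character(0), normalized_id = character(0))
  } else {
    do.call(rbind, out)
  }
}

# Naive confusion-matrix metrics from first principles.
oracle_metrics <- function(pred, gold, classes) {
  per <- lapply(classes, function(cls) {
    tp <- sum(pred == cls & gold == cls)
    fp <- sum(pred == cls & gold != cls)
    fn <- sum(pred != cls & gold == cls)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  })
  m <- do.call(rbind, per)
  list(per_class = m, accuracy = mean(pred == gold),
       macro = colMeans(m))
}

# Brute-force tripartite join: explained iff any compound links spice and
# disease, by triple enumeration.
oracle_explained <- function(positives, spice_compound, compound_disease) {
  vapply(seq_len(nrow(positives)), function(r) {
    s <- positives$spice_id[r]
    d <- positives$disease_id[r]
    any(vapply(unique(spice_compound$compound_id[
      spice_compound$spice_id == s]), function(cc) {
        any(compound_disease$compound_id == cc &
              compound_disease$disease_id == d)
      }, logical(1)))
  }, logical(1))
}

# Tiny ontology helper for scoring tests: one row per tree number.
toy_ontology <- function(tree_numbers, ids = NULL) {
  ids <- ids %||% paste0("D", seq_along(tree_numbers))
  tibble::tibble(id = ids, name = paste0("name_", ids),
                 tree_number = tree_numbers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_tokens <- function(n, vocab) sample(vocab, n, replace = TRUE)
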