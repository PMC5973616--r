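#' Build a token-level dictionary matcher
#'
#' Compiles a surface table into a matching automaton over token
#' sequences. Surfaces are normalized with the pipeline tokenizer, indexed
#' by first token, and at scan time the longest surface starting at each
#' position wins (greedy, left to right, non-overlapping: scanning resumes
#' after an emitted match). Construction is a single pass over the surface
#' tokens, and the result is independent of surface row order.
#'
#' @param surfaces Tibble with columns `surface` and an identifier column
#'   (`species_id` or `id`).
#' @param id_col Name of the identifier column; defaults to whichever of
#'   `species_id` / `id` is present.
#' @param reserved Reserved token set used by the tokenizer.
#' @return Object of class `token_matcher`.
#' @export
build_matcher <- function(surfaces, id_col = NULL,
                          reserved = reserved_tokens()) {
  stopifnot(is.data.frame(surfaces))
  if (nrow(surfaces) == 0) abort("cannot build a matcher from an empty lexicon")
  id_col <- id_col %||% intersect(c("species_id", "id"), names(surfaces))[1]
  if (is.na(id_col)) abort("surface table needs a `species_id` or `id` column")
  pats <- map(surfaces$surface, normalize_tokens, reserved = reserved)
  keep <- lengths(pats) > 0
  pats <- pats[keep]
  ids <- surfaces[[id_col]][keep]
  key <- map_chr(pats, paste, collapse = " ")
  # deterministic and row-order-insensitive: dedupe surfaces, keep the
  # lexicographically smallest id for a (pathological) shared surface
  ord <- order(key, ids)
  pats <- pats[ord]; ids <- ids[ord]; key <- key[ord]
  first <- !duplicated(key)
  pats <- pats[first]; ids <- ids[first]; key <- key[first]
  lens <- lengths(pats)
  by_first <- split(seq_along(pats), map_chr(pats, 1))
  # within each bucket try longest patterns first
  by_first <- map(by_first, function(idx) idx[order(-lens[idx], key[idx])])
  structure(
    list(patterns = pats, ids = ids, lengths = lens, by_first = by_first,
         n_surfaces = length(pats)),
    class = "token_matcher"
  )
}

#' @export
print.token_matcher <- function(x, ...) {
  cat(sprintf("<token_matcher: %d surfaces, max span %d tokens>\n",
              x$n_surfaces, max(x$lengths)))
  invisible(x)
}

match_tokens <- function(tokens, matcher) {
  n <- length(tokens)
  starts <- integer(0); stops <- integer(0); hit <- integer(0)
  i <- 1L
  while (i <= n) {
    cand <- matcher$by_first[[tokens[i]]]
    matched <- FALSE
    if (!is.null(cand)) {
      for (j in cand) {
        L <- matcher$lengths[j]
        if (i + L - 1L <= n &&
            all(tokens[i:(i + L - 1L)] == matcher$patterns[[j]])) {
          starts <- c(starts, i - 1L)          # 0-based inclusive
          stops <- c(stops, i - 1L + L)        # 0-based exclusive
          hit <- c(hit, j)
          i <- i + L
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) i <- i + 1L
  }
  tibble(
    token_start = starts,
    token_end = stops,
    surface = map_chr(hit, ~ paste(matcher$patterns[[.x]], collapse = " ")),
    normalized_id = matcher$ids[hit]
  )
}

#' Tag spice mentions in a token sequence
#'
#' Runs the longest-match scan of `matcher` over a normalized token vector
#' and returns spice mentions with token spans and normalized species IDs.
#' Mentions are non-overlapping by construction.
#'
#' @param tokens Normalized token vector (see [normalize_tokens()]).
#' @param matcher A `token_matcher` built from the spice lexicon.
#' @param doc_id,sentence_index Provenance attached to each mention.
#' @return Mention tibble: `doc_id`, `sentence_index`, `token_start`
#'   (0-based inclusive), `token_end` (0-based exclusive), `surface`,
#'   `entity_type`, `normalized_id`.
#' @export
tag_spices <- function(tokens, matcher, doc_id = "doc", sentence_index = 0L) {
  stopifnot(is.character(tokens), inherits(matcher, "token_matcher"))
  out <- match_tokens(tokens, matcher)
  tibble(doc_id = doc_id, sentence_index = as.integer(sentence_index),
         out[, c("token_start", "token_end", "surface")],
         entity_type = if (nrow(out)) "spice" else character(0),
         normalized_id = out$normalized_id)
}

#' Tag disease mentions in a token sequence
#'
#' Bundled fallback disease tagger: dictionary matching over ontology node
#' names with the same longest-match semantics as [tag_spices()],
#' normalizing each mention to its ontology ID. An external tagger's
#' character-offset output can be converted instead via
#' [adapt_external_mentions()].
#'
#' @param tokens Normalized token vector.
#' @param ontology Disease ontology tibble (`id`, `name`, `tree_number`)
#'   or a prebuilt `token_matcher`.
#' @param doc_id,sentence_index Provenance attached to each mention.
#' @return Mention tibble as in [tag_spices()] with `entity_type = "disease"`.
#' @export
tag_diseases <- function(tokens, ontology, doc_id = "doc",
                         sentence_index = 0L) {
  matcher <- if (inherits(ontology, "token_matcher")) {
    ontology
  } else {
    build_matcher(distinct(ontology, .data$id, surface = .data$name),
                  id_col = "id")
  }
  out <- tag_spices(tokens, matcher, doc_id = doc_id,
                    sentence_index = sentence_index)
  out$entity_type <- rep("disease", nrow(out))
  out
}

#' Convert external tagger output to token-level mentions
#'
#' Adapter for an external disease tagger emitting character-offset
#' records. Each record's character span is mapped onto the normalized
#' token sequence of its sentence; records whose ID does not resolve in
#' the ontology are dropped with a warning.
#'
#' @param records Tibble with columns `doc_id`, `sentence_index`,
#'   `char_start`, `char_end` (0-based, end-exclusive offsets into the raw
#'   sentence string), `id`.
#' @param sentences Named list: `sentences[[doc_id]]` is the character
#'   vector of raw sentences of that document.
#' @param ontology Disease ontology tibble used to validate IDs.
#' @return Mention tibble as in [tag_diseases()].
#' @export
adapt_external_mentions <- function(records, sentences, ontology) {
  stopifnot(is.data.frame(records))
  known <- unique(ontology$id)
  bad <- !(records$id %in% known)
  if (any(bad)) {
    warn(sprintf("%d external mention(s) with unresolvable IDs dropped",
                 sum(bad)))
    records <- records[!bad, ]
  }
  rows <- pmap(records, function(doc_id, sentence_index, char_start,
                                 char_end, id, ...) {
    sent <- sentences[[doc_id]][sentence_index + 1L]
    span_text <- substr(sent, char_start + 1L, char_end)
    toks <- normalize_tokens(sent)
    span_toks <- normalize_tokens(span_text)
    if (length(span_toks) == 0) return(NULL)
    # locate the span's token sequence in the sentence tokens
    for (i in seq_len(length(toks) - length(span_toks) + 1L)) {
      if (all(toks[i:(i + length(span_toks) - 1L)] == span_toks)) {
        return(tibble(doc_id = doc_id,
                      sentence_index = as.integer(sentence_index),
                      token_start = i - 1L,
                      token_end = i - 1L + length(span_toks),
                      surface = paste(span_toks, collapse = " "),
                      entity_type = "disease", normalized_id = id))
      }
    }
    NULL
  })
  bind_rows(rows)
}

#' Tag every sentence of a corpus
#'
#' Segments each abstract, tokenizes each sentence, and runs both the
#' spice and the disease tagger, returning one combined mention table.
#'
#' @param records Abstract record tibble ([parse_medline()]).
#' @param spice_matcher `token_matcher` over the spice lexicon surfaces.
#' @param disease_matcher `token_matcher` over ontology names (or the
#'   ontology tibble itself).
#' @param reserved Reserved token set.
#' @return Mention tibble over all sentences of all records.
#' @export
tag_corpus <- function(records, spice_matcher, disease_matcher,
                       reserved = reserved_tokens()) {
  stopifnot(is.data.frame(records))
  if (!inherits(disease_matcher, "token_matcher")) {
    disease_matcher <- build_matcher(
      distinct(disease_matcher, .data$id, surface = .data$name),
      id_col = "id")
  }
  rows <- pmap(list(records$pmid, records$abstract_text),
               function(pmid, text) {
    sents <- segment_sentences(text)
    imap(sents, function(s, idx) {
      toks <- normalize_tokens(s, reserved = reserved)
      bind_rows(
        tag_spices(toks, spice_matcher, doc_id = pmid,
                   sentence_index = idx - 1L),
        tag_diseases(toks, disease_matcher, doc_id = pmid,
                     sentence_index = idx - 1L)
      )
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  assert_no_overlap(out)
  out
}

# invariant: mentions of one entity type within a sentence never overlap
assert_no_overlap <- function(mentions) {
  if (nrow(mentions) == 0) return(invisible(mentions))
  bad <- mentions |>
    group_by(.data$doc_id, .data$sentence_index, .data$entity_type) |>
    arrange(.data$token_start, .by_group = TRUE) |>
    summarise(ov = any(.data$token_start[-1] < head(.data$token_end, -1)),
              .groups = "drop") |>
    filter(.data$ov)
  if (nrow(bad) > 0) abort("internal error: overlapping mentions emitted")
  invisible(mentions)
}
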