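#' Split abstract text into sentences
#'
#' Rule-based segmentation: a sentence ends at `.`, `!` or `?` followed by
#' whitespace, unless the terminator belongs to a known abbreviation
#' (`i.e.`, `e.g.`, `etc.`, `vs.`, `var.`, `subsp.`, `cv.`, `sp.`, `spp.`,
#' `cf.`, `al.`, `fig.`, `no.`) or to a decimal number. The concatenation of
#' the returned sentences equals the input up to inter-sentence whitespace.
#'
#' @param text A single nonempty string.
#' @param abbreviations Character vector of dotted abbreviations that never
#'   end a sentence (matched case-insensitively, without their final dot).
#' @return Character vector of nonempty sentences.
#' @examples
#' segment_sentences("Ginger helps. Turmeric, i.e. curcuma, is studied.")
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(str_trim(text))) abort("text must be nonempty")
  ends <- gregexpr("[.!?](?=[[:space:]])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (ends[1] != -1) {
    for (pos in ends) {
      prefix <- substr(text, 1, pos)
      tail_word <- str_replace(prefix, "^.*[[:space:]]", "")
      word_l <- str_to_lower(str_replace(tail_word, "\\.$", ""))
      if (word_l %in% abbreviations) next
      if (str_detect(tail_word, "^[0-9]+\\.$")) next   # decimal split "2. 5"? keep
      cuts <- c(cuts, pos)
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  out <- str_trim(substring(text, starts, stops))
  out[nzchar(out)]
}

#' @rdname segment_sentences
#' @export
default_abbreviations <- function() {
  c("i.e", "e.g", "etc", "vs", "cf", "al", "fig", "var", "subsp",
    "cv", "sp", "spp", "no")
}

#' Normalize and tokenize a sentence
#'
#' Characters outside letters, digits, whitespace and the retained
#' punctuation set `! , . : ;` are removed, the text is split into word and
#' punctuation tokens, words are lowercased, and purely numeric tokens
#' (integers and decimals) are replaced by the reserved number token.
#' Reserved placeholder tokens already present pass through unchanged, so
#' the operation is idempotent.
#'
#' @param sentence A single string.
#' @param reserved Reserved token set, see [reserved_tokens()].
#' @return Character vector of tokens.
#' @examples
#' normalize_tokens("Ginger reduced glucose by 25%!")
#' @export
normalize_tokens <- function(sentence, reserved = reserved_tokens()) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  txt <- gsub("[^A-Za-z0-9[:space:]!,.:;]", "", sentence)
  chunks <- strsplit(str_trim(txt), "[[:space:]]+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  out <- character(0)
  for (ch in chunks) {
    if (ch %in% reserved) {
      out <- c(out, ch)
      next
    }
    toks <- regmatches(
      ch, gregexpr("[0-9]+\\.[0-9]+|[A-Za-z0-9]+|[!,.:;]", ch))[[1]]
    for (tk in toks) {
      out <- c(out, if (grepl("^[0-9]+(\\.[0-9]+)?$", tk)) {
        unname(reserved[["number"]])
      } else {
        tolower(tk)
      })
    }
  }
  out
}

#' Is a sentence a relation-extraction candidate?
#'
#' A sentence qualifies iff it mentions at least one spice and at least one
#' disease.
#'
#' @param mentions Mention tibble for one sentence (columns as produced by
#'   [tag_spices()] / [tag_diseases()], including `entity_type`).
#' @return Single logical.
#' @export
select_candidates <- function(mentions) {
  stopifnot(is.data.frame(mentions))
  any(mentions$entity_type == "spice") && any(mentions$entity_type == "disease")
}

#' Enumerate masked spice-disease candidate instances for one sentence
#'
#' A sentence with m spice and n disease mentions yields m x n instances:
#' the sentence is duplicated once per pair, the focal spice span is
#' replaced by the reserved spice token, the focal disease span by the
#' reserved disease token, and every non-focal entity span by the reserved
#' mask token. Each mention span collapses to exactly one token, so all
#' instances from one sentence have identical length.
#'
#' @param tokens Normalized token vector of the sentence.
#' @param mentions Mention tibble for this sentence (both entity types).
#' @param doc_id,sentence_index Provenance of the sentence.
#' @param reserved Reserved token set.
#' @return Tibble with one row per pair: `instance_id`, `doc_id`,
#'   `sentence_index`, `spice_id`, `disease_id`, and list columns `tokens`,
#'   `spice_pos`, `disease_pos` (0-based token index of the focal tokens).
#' @export
enumerate_pairs <- function(tokens, mentions, doc_id = "doc",
                            sentence_index = 0L,
                            reserved = reserved_tokens()) {
  stopifnot(is.character(tokens), is.data.frame(mentions))
  if (!select_candidates(mentions)) {
    abort("sentence is not a candidate (needs >= 1 spice and >= 1 disease mention)")
  }
  mentions <- arrange(mentions, .data$token_start)
  spices <- filter(mentions, .data$entity_type == "spice")
  diseases <- filter(mentions, .data$entity_type == "disease")
  pairs <- tidyr::expand_grid(si = seq_len(nrow(spices)),
                              di = seq_len(nrow(diseases)))
  rows <- pmap(pairs, function(si, di) {
    focal_spice <- spices[si, ]
    focal_disease <- diseases[di, ]
    out <- tokens
    spice_pos <- disease_pos <- NA_integer_
    # replace spans right-to-left so earlier offsets stay valid
    ord <- order(mentions$token_start, decreasing = TRUE)
    for (j in ord) {
      m <- mentions[j, ]
      repl <- if (m$entity_type == "spice" &&
                  m$token_start == focal_spice$token_start) {
        reserved[["spice"]]
      } else if (m$entity_type == "disease" &&
                 m$token_start == focal_disease$token_start) {
        reserved[["disease"]]
      } else {
        reserved[["masked"]]
      }
      out <- c(head(out, m$token_start), repl,
               out[seq_len(length(out)) > m$token_end])
    }
    spice_pos <- which(out == reserved[["spice"]]) - 1L
    disease_pos <- which(out == reserved[["disease"]]) - 1L
    tibble(
      instance_id = sprintf("%s:%d:%d:%d", doc_id, sentence_index, si, di),
      doc_id = doc_id,
      sentence_index = as.integer(sentence_index),
      spice_id = focal_spice$normalized_id,
      disease_id = focal_disease$normalized_id,
      tokens = list(unname(out)),
      spice_pos = spice_pos,
      disease_pos = disease_pos
    )
  })
  bind_rows(rows)
}

#' Attach linguistic and positional features to candidate instances
#'
#' Part-of-speech and chunk tags come from a pluggable tagger (a function
#' `tokens -> list(pos = ..., chunk = ...)`, defaulting to the bundled
#' rule-based tagger); signed token distances to the focal spice and
#' disease token are computed as `i - index(focal)`.
#'
#' @param instances Instance tibble from [enumerate_pairs()].
#' @param tagger Tagger function; see [default_tagger()].
#' @return The instance tibble with list columns `pos_tags`, `chunk_tags`,
#'   `dist_spice`, `dist_disease` added.
#' @export
attach_features <- function(instances, tagger = default_tagger) {
  stopifnot(is.data.frame(instances))
  feats <- map(instances$tokens, function(toks) {
    tags <- tagger(toks)
    if (!is.list(tags) || !all(c("pos", "chunk") %in% names(tags)) ||
        length(tags$pos) != length(toks) ||
        length(tags$chunk) != length(toks)) {
      abort("tagger contract violation: must return list(pos, chunk) of token length")
    }
    tags
  })
  n <- lengths(instances$tokens)
  instances |>
    mutate(
      pos_tags = map(feats, "pos"),
      chunk_tags = map(feats, "chunk"),
      dist_spice = map2(n, .data$spice_pos,
                        ~ seq_len(.x) - 1L - .y),
      dist_disease = map2(n, .data$disease_pos,
                          ~ seq_len(.x) - 1L - .y)
    )
}

#' Bundled rule-based part-of-speech and chunk tagger
#'
#' A deterministic suffix/lexicon heuristic standing behind the pluggable
#' tagger contract: punctuation tags as itself, the reserved number token
#' as `CD`, a small function-word list as `DT`/`IN`/`CC`, `-ed`/`-ing`
#' verb suffixes as `VBD`/`VBG`, `-ly` as `RB`, everything else as `NN`.
#' Chunks follow a naive noun-phrase rule (`DT`/`JJ`/`NN` runs become
#' `B-NP`/`I-NP`, verbs `B-VP`, the rest `O`).
#'
#' @param tokens Character vector of normalized tokens.
#' @param reserved Reserved token set.
#' @return `list(pos = <chr>, chunk = <chr>)`, both token-length.
#' @export
default_tagger <- function(tokens, reserved = reserved_tokens()) {
  det <- c("the", "a", "an", "this", "these", "that", "those")
  prep <- c("of", "in", "on", "by", "with", "against", "from", "to",
            "for", "at", "during", "after", "between")
  conj <- c("and", "or", "but", "while", "whereas")
  pos <- map_chr(tokens, function(tk) {
    if (tk %in% c("!", ",", ".", ":", ";")) tk
    else if (tk == reserved[["number"]]) "CD"
    else if (tk %in% reserved) "NN"
    else if (tk %in% det) "DT"
    else if (tk %in% prep) "IN"
    else if (tk %in% conj) "CC"
    else if (str_detect(tk, "ed$")) "VBD"
    else if (str_detect(tk, "ing$")) "VBG"
    else if (str_detect(tk, "ly$")) "RB"
    else "NN"
  })
  nounish <- pos %in% c("DT", "JJ", "NN", "CD")
  chunk <- character(length(tokens))
  for (i in seq_along(tokens)) {
    chunk[i] <- if (nounish[i]) {
      if (i > 1 && nounish[i - 1]) "I-NP" else "B-NP"
    } else if (pos[i] %in% c("VBD", "VBG")) "B-VP" else "O"
  }
  list(pos = pos, chunk = chunk)
}

#' Build featurized candidate instances for a whole corpus
#'
#' Convenience wrapper running segmentation, tokenization, candidate
#' selection, pair enumeration and feature attachment over a record table
#' and its mention table.
#'
#' @param records Abstract records ([parse_medline()]).
#' @param mentions Corpus mention tibble ([tag_corpus()]).
#' @param tagger Linguistic tagger, see [attach_features()].
#' @param reserved Reserved token set.
#' @return Instance tibble over all candidate sentences.
#' @export
build_candidates <- function(records, mentions, tagger = default_tagger,
                             reserved = reserved_tokens()) {
  stopifnot(is.data.frame(records), is.data.frame(mentions))
  by_sentence <- mentions |>
    group_by(.data$doc_id, .data$sentence_index) |>
    group_split()
  rows <- map(by_sentence, function(ms) {
    if (!select_candidates(ms)) return(NULL)
    rec <- records[records$pmid == ms$doc_id[1], ]
    sents <- segment_sentences(rec$abstract_text)
    toks <- normalize_tokens(sents[ms$sentence_index[1] + 1L],
                             reserved = reserved)
    enumerate_pairs(toks, ms, doc_id = ms$doc_id[1],
                    sentence_index = ms$sentence_index[1],
                    reserved = reserved)
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) out <- attach_features(out, tagger = tagger)
  out
}
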