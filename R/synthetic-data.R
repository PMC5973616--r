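# Synthetic study generator: every pipeline input with planted ground
# truth, so downstream stages are testable without any external download.

canonical_labels <- function() c("no-association", "negative", "positive")

template_banks <- function() {
  read_bank <- function(stem) {
    path <- system.file("extdata", paste0("templates_", stem, ".txt"),
                        package = "spicemine", mustWork = TRUE)
    readLines(path, warn = FALSE)
  }
  list(positive = read_bank("positive"),
       negative = read_bank("negative"),
       `no-association` = read_bank("neutral"),
       filler = read_bank("filler"))
}

template_vocabulary <- function() {
  words <- unlist(strsplit(unlist(template_banks()), "[^a-z]+"))
  unique(words[nzchar(words)])
}

leaf_suffixes <- function() c("osis", "itis", "emia", "oma", "opathy")

#' Generate a three-level synthetic disease ontology
#'
#' Builds a MeSH-like hierarchy: categories (`C01`, ...), subcategories
#' (`C01.050`, ...) and leaf diseases (`C01.050.101`, ...). Subcategory
#' and leaf counts are drawn per parent from the configured ranges. Leaf
#' names are unique single-token pseudo-words (with a disease-like
#' suffix), disjoint from the sentence template vocabulary, so they are
#' directly usable as dictionary surfaces.
#'
#' @param cfg A [synthetic_config()].
#' @return Ontology tibble: `id`, `name`, `tree_number`, `level` (1-3).
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed + 101L, {
    wf <- new_word_factory(blocked = template_vocabulary())
    rows <- list()
    node <- 0L
    for (i in seq_len(cfg$n_categories)) {
      node <- node + 1L
      cat_tn <- sprintf("C%02d", i)
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("MSH%06d", node),
        name = paste(wf(), "diseases"), tree_number = cat_tn, level = 1L)
      n_sub <- sample_range(1, cfg$subcats_per_category)
      for (j in seq_len(n_sub)) {
        node <- node + 1L
        sub_tn <- sprintf("%s.%03d", cat_tn, 50L * j)
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("MSH%06d", node),
          name = paste(wf(), "disorders"), tree_number = sub_tn, level = 2L)
        n_leaf <- sample_range(1, cfg$diseases_per_subcat)
        for (k in seq_len(n_leaf)) {
          node <- node + 1L
          rows[[length(rows) + 1L]] <- tibble(
            id = sprintf("MSH%06d", node),
            name = paste0(wf(), sample(leaf_suffixes(), 1)),
            tree_number = sprintf("%s.%03d", sub_tn, 100L + k), level = 3L)
        }
      }
    }
    bind_rows(rows)
  })
}

#' Generate a synthetic spice lexicon
#'
#' Produces one entry row per (species, common name). The generator
#' plants, within the configured synonym budget, (a) a multi-word synonym
#' of one species that contains another species' single-word synonym as a
#' token (exercising longest-match tagging), (b) a plural common-name
#' form, and (c) an infraspecific `var.` qualifier on the first scientific
#' name (exercising [standardize_variety()]).
#'
#' @param cfg A [synthetic_config()].
#' @return Entry tibble: `species_id`, `scientific_name`, `common_name`,
#'   `provenance`.
#' @export
generate_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed + 202L, {
    wf <- new_word_factory(blocked = c(template_vocabulary(), "black"))
    n <- cfg$n_spices
    k <- sample_range(n, cfg$synonyms_per_spice)
    cap <- function(w) paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    sci <- map_chr(seq_len(n), ~ paste(cap(wf()), wf()))
    syn <- map(seq_len(n), function(i) map_chr(seq_len(k[i]), ~ wf()))
    sci[1] <- paste(sci[1], "var.", wf())
    extra <- NULL
    if (n >= 2) syn[[2]][1] <- paste("black", syn[[1]][1])
    pl <- function(w) expand_plurals(w)[2]
    cand <- setdiff(which(k >= 2), 2L)
    if (length(cand) > 0) {
      t <- if (any(cand > 2)) min(cand[cand > 2]) else min(cand)
      syn[[t]][2] <- pl(syn[[t]][1])
    } else if (n >= 3) {
      syn[[3]][1] <- pl(syn[[3]][1])
    } else {
      extra <- tibble(species_id = sprintf("TAX%05d", 1000L + 1L),
                      scientific_name = sci[1],
                      common_name = pl(syn[[1]][1]))
    }
    out <- bind_rows(map(seq_len(n), function(i) {
      tibble(species_id = sprintf("TAX%05d", 1000L + i),
             scientific_name = sci[i], common_name = syn[[i]])
    }))
    bind_rows(out, extra) |> mutate(provenance = "synthetic")
  })
}

realize_profiles <- function(cfg, ontology) {
  if (is.null(cfg$planted_profiles)) return(NULL)
  subcats <- filter(ontology, .data$level == 2L) |>
    mutate(category = tree_prefix(.data$tree_number, 1L))
  leaves <- filter(ontology, .data$level == 3L) |>
    mutate(subcat = tree_prefix(.data$tree_number, 2L))
  cats <- unique(subcats$category)
  bind_rows(map(cfg$planted_profiles, function(p) {
    sel_cats <- sort(sample(cats, ceiling(p$category_coverage * length(cats))))
    bind_rows(map(sel_cats, function(cc) {
      subs <- subcats$tree_number[subcats$category == cc]
      sel_subs <- sort(sample(subs,
                              ceiling(p$subcategory_coverage * length(subs))))
      bind_rows(map(sel_subs, function(ss) {
        lv <- leaves[leaves$subcat == ss, ]
        pick <- lv[sample(nrow(lv), 1L), ]
        tibble(spice_index = p$spice,
               spice_id = sprintf("TAX%05d", 1000L + p$spice),
               category = cc, subcategory = ss,
               disease_id = pick$id, disease_name = pick$name,
               polarity = p$polarity)
      }))
    }))
  }))
}

flip_label <- function(label, rate) {
  if (rate <= 0) return(label)
  flip <- runif(length(label)) < rate
  for (i in which(flip)) {
    label[i] <- sample(setdiff(canonical_labels(), label[i]), 1L)
  }
  label
}

#' Generate a labeled synthetic abstract corpus
#'
#' Assembles `n_abstracts` abstracts whose sentences are drawn from fixed
#' label-keyed template banks (distinct cue-phrase vocabularies for
#' positive / negative / no-association assertions, plus entity-free
#' filler). Every planted pair sentence embeds one spice surface and one
#' disease leaf name; its gold class is the template's class, flipped to a
#' uniformly random different class with probability `label_noise_rate`.
#' Spices carrying a planted profile appear only in sentences realizing
#' that profile's (category, subcategory) cells, which makes
#' spectrum-score recovery exact.
#'
#' @param cfg A [synthetic_config()].
#' @param ontology Ontology from [generate_ontology()].
#' @param lexicon Entry tibble from [generate_lexicon()].
#' @return List with elements `records` (abstract tibble as from
#'   [parse_medline()]) and `truth` (list: `labels` tibble keyed by
#'   `(pmid, sentence_index, spice_id, disease_id)` with `template_class`
#'   and recorded `label`; `profile_cells` tibble of realized planted
#'   coverage or `NULL`).
#' @export
generate_corpus <- function(cfg, ontology, lexicon) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (nrow(ontology) == 0) abort("ontology must be nonempty")
  if (nrow(lexicon) == 0) abort("lexicon must be nonempty")
  withr::with_seed(cfg$seed + 303L, {
    banks <- template_banks()
    leaves <- filter(ontology, .data$level == 3L)
    surf <- lexicon |>
      group_by(.data$species_id) |>
      summarise(surfaces = list(unique(c(
        str_to_lower(standardize_variety(.data$scientific_name[1])),
        str_to_lower(.data$common_name)))), .groups = "drop")
    surfaces <- setNames(surf$surfaces, surf$species_id)
    cells <- realize_profiles(cfg, ontology)
    profiled <- unique(cells$spice_id)
    free_spices <- setdiff(names(surfaces), profiled)

    n_sent <- sample_range(cfg$n_abstracts, cfg$sentences_per_abstract)
    total <- sum(n_sent)
    mandatory <- if (is.null(cells)) cells else
      mutate(cells, class = .data$polarity)
    n_mand <- if (is.null(mandatory)) 0L else nrow(mandatory)
    if (n_mand > total) {
      abort("planted profiles need more sentences than the corpus holds; increase n_abstracts")
    }
    mand_slots <- if (n_mand > 0) sort(sample(total, n_mand)) else integer(0)

    slot_abs <- rep(seq_len(cfg$n_abstracts), n_sent)
    slot_idx <- unlist(map(n_sent, seq_len)) - 1L
    sentences <- character(total)
    gold <- vector("list", total)

    make_pair_sentence <- function(spice_id, disease, class) {
      bank <- banks[[class]]
      two <- str_detect(bank, stringr::fixed("{SPICE2}"))
      pool2 <- setdiff(free_spices, spice_id)   # never a profiled spice
      # two-entity templates fire at a fixed rate independent of the
      # class, so pair-level class marginals stay at the priors
      needs2 <- length(pool2) > 0 && any(two) && runif(1) < 1 / 6
      tmpl <- if (needs2) sample(bank[two], 1L) else sample(bank[!two], 1L)
      s1 <- sample(surfaces[[spice_id]], 1L)
      txt <- str_replace(tmpl, stringr::fixed("{SPICE}"), s1)
      rows <- tibble(spice_id = spice_id, disease_id = disease$id,
                     template_class = class)
      if (needs2) {
        sp2 <- sample(pool2, 1L)
        txt <- str_replace(txt, stringr::fixed("{SPICE2}"),
                           sample(surfaces[[sp2]], 1L))
        rows <- bind_rows(rows, tibble(spice_id = sp2,
                                       disease_id = disease$id,
                                       template_class = class))
      }
      txt <- str_replace(txt, stringr::fixed("{DISEASE}"), disease$name)
      list(text = txt, gold = rows)
    }

    mi <- 0L
    for (s in seq_len(total)) {
      if (s %in% mand_slots) {
        mi <- mi + 1L
        row <- mandatory[mi, ]
        out <- make_pair_sentence(row$spice_id,
                                  list(id = row$disease_id,
                                       name = row$disease_name),
                                  row$class)
      } else if (runif(1) < 0.25 || length(free_spices) + n_mand == 0) {
        sentences[s] <- sample(banks$filler, 1L)
        next
      } else {
        cls <- sample(c("positive", "negative", "no-association"), 1L,
                      prob = unname(cfg$label_priors[c("positive", "negative",
                                                       "neutral")]))
        if (length(free_spices) > 0) {
          sp <- sample(free_spices, 1L)
          leaf <- leaves[sample(nrow(leaves), 1L), ]
          out <- make_pair_sentence(sp, list(id = leaf$id, name = leaf$name),
                                    cls)
        } else {
          # every spice is profiled: draw a profile cell with its polarity
          row <- cells[sample(nrow(cells), 1L), ]
          out <- make_pair_sentence(row$spice_id,
                                    list(id = row$disease_id,
                                         name = row$disease_name),
                                    row$polarity)
        }
      }
      sentences[s] <- out$text
      gold[[s]] <- mutate(out$gold, slot = s)
    }

    labels <- bind_rows(gold)
    if (nrow(labels) > 0) {
      labels <- labels |>
        mutate(pmid = as.character(100000L + slot_abs[.data$slot]),
               sentence_index = slot_idx[.data$slot],
               label = flip_label(.data$template_class,
                                  cfg$label_noise_rate)) |>
        select("pmid", "sentence_index", "spice_id", "disease_id",
               "template_class", "label")
    }

    journals <- c("annals of synthetic nutrition",
                  "journal of culinary evidence",
                  "archives of dietary studies")
    wf <- new_word_factory(blocked = template_vocabulary())
    records <- bind_rows(map(seq_len(cfg$n_abstracts), function(a) {
      idx <- which(slot_abs == a)
      cap <- function(w) paste0(toupper(substr(w, 1, 1)),
                                substr(w, 2, nchar(w)))
      tibble(
        pmid = as.character(100000L + a),
        date = as.character(sample(1990:2020, 1L)),
        title = sprintf("Observational report %d on dietary ingredients", a),
        abstract_text = paste(sentences[idx], collapse = " "),
        journal = sample(journals, 1L),
        authors = list(map_chr(seq_len(sample(1:3, 1L)),
                               ~ paste(cap(wf()), "A")))
      )
    }))
    list(records = records,
         truth = list(labels = labels, profile_cells = cells))
  })
}

#' Generate synthetic phytochemical tables with planted explanations
#'
#' Given the positive spice-disease associations, plants a supporting
#' spice -> bioactive compound -> therapeutic compound-disease path for
#' exactly `round(explainable_fraction * nrow(positives))` of them
#' (selected without replacement) and guarantees that no other positive
#' association gains a path: decoy compounds are either non-bioactive or
#' carry only `marker`/`inferred` disease links.
#'
#' @param cfg A [synthetic_config()].
#' @param lexicon Entry tibble ([generate_lexicon()]).
#' @param ontology Ontology tibble ([generate_ontology()]).
#' @param positives Tibble of positive associations with columns
#'   `spice_id`, `disease_id` (a `polarity` column, if present, is
#'   filtered to `"positive"`).
#' @return List: `compounds` (`compound_id`, `name`, `bioactive`),
#'   `spice_compound` (`spice_id`, `compound_id`, `bioactive`),
#'   `compound_disease` (`compound_id`, `disease_id`, `association_type`),
#'   `truth` (planted explainable triples `spice_id`, `disease_id`,
#'   `compound_id`).
#' @export
generate_phytochem_tables <- function(cfg, lexicon, ontology, positives) {
  stopifnot(inherits(cfg, "synthetic_config"), is.data.frame(positives))
  if ("polarity" %in% names(positives)) {
    positives <- filter(positives, .data$polarity == "positive")
  }
  positives <- distinct(positives, .data$spice_id, .data$disease_id)
  if (nrow(positives) == 0) abort("`positives` must be nonempty")
  withr::with_seed(cfg$seed + 404L, {
    wf <- new_word_factory(blocked = template_vocabulary())
    n_exp <- round(cfg$explainable_fraction * nrow(positives))
    sel <- if (n_exp > 0) sort(sample(nrow(positives), n_exp)) else integer(0)
    planted <- positives[sel, ]
    cmp_id <- function(i) sprintf("CMP%05d", i)
    n_planted <- nrow(planted)
    planted_cmp <- tibble(
      compound_id = cmp_id(seq_len(n_planted)),
      name = map_chr(seq_len(n_planted), ~ paste0(wf(), "in")),
      bioactive = TRUE)
    truth <- tibble(spice_id = planted$spice_id,
                    disease_id = planted$disease_id,
                    compound_id = planted_cmp$compound_id)
    leaves <- filter(ontology, .data$level == 3L)
    species <- unique(lexicon$species_id)
    n_dec <- sample(1:3, length(species), replace = TRUE)
    decoy_cmp <- tibble(
      compound_id = cmp_id(n_planted + seq_len(sum(n_dec))),
      name = map_chr(seq_len(sum(n_dec)), ~ paste0(wf(), "in")),
      bioactive = runif(sum(n_dec)) < cfg$bioactive_fraction,
      spice_id = rep(species, n_dec))
    decoy_links <- decoy_cmp |>
      mutate(disease_id = sample(leaves$id, n(), replace = TRUE),
             association_type = ifelse(
               .data$bioactive,
               sample(c("marker", "inferred"), n(), replace = TRUE),
               sample(c("therapeutic", "marker", "inferred"), n(),
                      replace = TRUE)))
    compounds <- bind_rows(planted_cmp,
                           select(decoy_cmp, "compound_id", "name",
                                  "bioactive"))
    spice_compound <- bind_rows(
      tibble(spice_id = planted$spice_id,
             compound_id = planted_cmp$compound_id, bioactive = TRUE),
      select(decoy_cmp, "spice_id", "compound_id", "bioactive"))
    compound_disease <- bind_rows(
      tibble(compound_id = planted_cmp$compound_id,
             disease_id = planted$disease_id,
             association_type = "therapeutic"),
      select(decoy_links, "compound_id", "disease_id", "association_type"))
    list(compounds = compounds, spice_compound = spice_compound,
         compound_disease = compound_disease, truth = truth)
  })
}

#' Generate and write a complete synthetic study to disk
#'
#' Runs every generator and serializes the pipeline inputs: the corpus as
#' PubMed-dialect XML, the lexicon / ontology / phytochemical tables as
#' TSV, and the ground truth (pair labels, profile cells, explainable
#' triples) as TSV.
#'
#' @param cfg A [synthetic_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ontology <- generate_ontology(cfg)
  lexicon <- generate_lexicon(cfg)
  corpus <- generate_corpus(cfg, ontology, lexicon)
  positives <- corpus$truth$labels |>
    filter(.data$label == "positive") |>
    distinct(.data$spice_id, .data$disease_id)
  phyto <- if (nrow(positives) > 0) {
    generate_phytochem_tables(cfg, lexicon, ontology, positives)
  } else NULL
  p <- function(f) file.path(outdir, f)
  write_medline(corpus$records, p("corpus.xml"))
  readr::write_tsv(lexicon, p("lexicon.tsv"))
  readr::write_tsv(select(ontology, "id", "name", "tree_number"),
                   p("ontology.tsv"))
  readr::write_tsv(corpus$truth$labels, p("truth_labels.tsv"))
  if (!is.null(corpus$truth$profile_cells)) {
    readr::write_tsv(corpus$truth$profile_cells, p("truth_profiles.tsv"))
  }
  if (!is.null(phyto)) {
    readr::write_tsv(phyto$compounds, p("compounds.tsv"))
    readr::write_tsv(phyto$spice_compound, p("spice_compound.tsv"))
    readr::write_tsv(phyto$compound_disease, p("compound_disease.tsv"))
    readr::write_tsv(phyto$truth, p("truth_explainable.tsv"))
  }
  invisible(list(ontology = ontology, lexicon = lexicon, corpus = corpus,
                 phytochem = phyto))
}
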