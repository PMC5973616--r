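test_that("ontology generation respects configured counts and levels", {
  cfg <- synthetic_config(seed = 5, n_categories = 27,
                          subcats_per_category = c(1, 1),
                          diseases_per_subcat = c(1, 1))
  ont <- generate_ontology(cfg)
  expect_equal(sum(ont$level == 1), 27)
  expect_equal(sum(ont$level == 2), 27)
  expect_equal(sum(ont$level == 3), 27)

  cfg2 <- synthetic_config(seed = 5, n_categories = 4,
                           subcats_per_category = c(2, 2),
                           diseases_per_subcat = c(3, 3))
  ont2 <- generate_ontology(cfg2)
  expect_equal(nrow(ont2), 4 + 8 + 24)
  # verified by traversal: every level-2/3 tree number has its parent
  parents2 <- tree_prefix(ont2$tree_number[ont2$level == 2], 1)
  parents3 <- tree_prefix(ont2$tree_number[ont2$level == 3], 2)
  expect_true(all(parents2 %in% ont2$tree_number))
  expect_true(all(parents3 %in% ont2$tree_number))
  expect_false(anyDuplicated(ont2$tree_number) > 0)
  expect_false(anyDuplicated(ont2$name[ont2$level == 3]) > 0)
})

test_that("generation is deterministic for identical configs", {
  cfg <- synthetic_config(seed = 99, n_abstracts = 15, n_spices = 6,
                          n_categories = 4)
  a <- generate_ontology(cfg); b <- generate_ontology(cfg)
  expect_identical(a, b)
  la <- generate_lexicon(cfg); lb <- generate_lexicon(cfg)
  expect_identical(la, lb)
  ca <- generate_corpus(cfg, a, la); cb <- generate_corpus(cfg, a, la)
  expect_identical(ca, cb)
  pos <- dplyr::distinct(
    dplyr::filter(ca$truth$labels, label == "positive"),
    spice_id, disease_id)
  pa <- generate_phytochem_tables(cfg, la, a, pos)
  pb <- generate_phytochem_tables(cfg, la, a, pos)
  expect_identical(pa, pb)
})

test_that("lexicon generator plants overlap, plural and variety within budget", {
  cfg <- synthetic_config(seed = 3, n_spices = 5,
                          synonyms_per_spice = c(2, 2))
  lex <- generate_lexicon(cfg)
  expect_equal(nrow(lex), 10)                       # 2 synonyms x 5 species
  expect_equal(dplyr::n_distinct(lex$scientific_name), 5)
  # a multi-word synonym of one species contains another species'
  # single-word synonym as a token
  multi <- lex$common_name[grepl(" ", lex$common_name)]
  expect_gte(length(multi), 1)
  inner <- strsplit(multi[1], " ")[[1]][2]
  owner_multi <- lex$species_id[lex$common_name == multi[1]]
  owner_inner <- lex$species_id[lex$common_name == inner]
  expect_length(owner_inner, 1)
  expect_false(owner_multi == owner_inner)
  # a plural form is planted
  singulars <- setdiff(lex$common_name, multi)
  expect_true(any(paste0(singulars, "s") %in% singulars |
                    sub("y$", "ies", singulars) %in% singulars))
  # a variety-qualified scientific name is planted
  expect_true(any(grepl(" var\\. ", lex$scientific_name)))

  cfg2 <- synthetic_config(seed = 3, n_spices = 2,
                           synonyms_per_spice = c(1, 1))
  lex2 <- generate_lexicon(cfg2)
  multi2 <- lex2$common_name[grepl(" ", lex2$common_name)]
  inner2 <- strsplit(multi2[1], " ")[[1]][2]
  expect_true(inner2 %in% lex2$common_name)
})

test_that("corpus labels follow templates, priors, and noise settings", {
  cfg <- synthetic_config(seed = 21, n_abstracts = 40, n_spices = 8,
                          n_categories = 5, label_noise_rate = 0)
  ont <- generate_ontology(cfg)
  lex <- generate_lexicon(cfg)
  corp <- generate_corpus(cfg, ont, lex)
  expect_true(all(corp$truth$labels$label == corp$truth$labels$template_class))

  cfg_pos <- synthetic_config(seed = 21, n_abstracts = 20, n_spices = 8,
                              n_categories = 5,
                              label_priors = c(positive = 1, negative = 0,
                                               neutral = 0))
  corp_pos <- generate_corpus(cfg_pos, ont, lex)
  expect_true(all(corp_pos$truth$labels$label == "positive"))

  cfg_pri <- synthetic_config(seed = 77, n_abstracts = 200, n_spices = 10,
                              n_categories = 6,
                              label_priors = c(positive = 0.4,
                                               negative = 0.05,
                                               neutral = 0.55))
  ont2 <- generate_ontology(cfg_pri)
  lex2 <- generate_lexicon(cfg_pri)
  labs <- generate_corpus(cfg_pri, ont2, lex2)$truth$labels
  freq <- table(labs$template_class) / nrow(labs)
  expect_lt(abs(freq[["positive"]] - 0.4), 0.06)
  expect_lt(abs(freq[["negative"]] - 0.05), 0.06)
  expect_lt(abs(freq[["no-association"]] - 0.55), 0.06)

  cfg_noise <- synthetic_config(seed = 21, n_abstracts = 40, n_spices = 8,
                                n_categories = 5, label_noise_rate = 0.5)
  labs_n <- generate_corpus(cfg_noise, ont, lex)$truth$labels
  expect_gt(sum(labs_n$label != labs_n$template_class), 0)
})

test_that("phytochemical planting is exact in the explainable count", {
  cfg <- synthetic_config(seed = 13, n_spices = 10, n_categories = 6)
  ont <- generate_ontology(cfg)
  lex <- generate_lexicon(cfg)
  leaves <- dplyr::filter(ont, level == 3)
  positives <- tidyr::expand_grid(spice_id = unique(lex$species_id),
                                  disease_id = leaves$id)[1:100, ]

  for (frac in c(0, 1, 0.37)) {
    cfg_f <- synthetic_config(seed = 13, n_spices = 10, n_categories = 6,
                              explainable_fraction = frac)
    phy <- generate_phytochem_tables(cfg_f, lex, ont, positives)
    sc <- dplyr::semi_join(phy$spice_compound,
                           filter_bioactive(phy$compounds),
                           by = "compound_id")
    cd <- therapeutic_links(phy$compound_disease)
    explained <- oracle_explained(positives, sc, cd)
    expect_equal(sum(explained), round(frac * nrow(positives)))
    expect_equal(nrow(phy$truth), round(frac * nrow(positives)))
  }
})

test_that("generated XML round-trips through the ingest parser", {
  cfg <- synthetic_config(seed = 31, n_abstracts = 12, n_spices = 5,
                          n_categories = 4)
  ont <- generate_ontology(cfg)
  lex <- generate_lexicon(cfg)
  corp <- generate_corpus(cfg, ont, lex)
  path <- withr::local_tempfile(fileext = ".xml")
  write_medline(corp$records, path)
  parsed <- parse_medline(path)
  attr(parsed, "dropped") <- NULL
  expect_equal(as.data.frame(parsed), as.data.frame(corp$records))
})

test_that("generator rejects invalid configurations", {
  expect_error(synthetic_config(n_categories = 0), "integer >= 1")
  expect_error(synthetic_config(label_noise_rate = 1.5), "probability")
  expect_error(synthetic_config(explainable_fraction = -0.1), "probability")
  expect_error(synthetic_config(label_priors = c(positive = 0.5,
                                                 negative = 0.5,
                                                 neutral = 0.5)),
               "sum to 1")
  cfg <- synthetic_config(seed = 1, n_abstracts = 5)
  expect_error(generate_corpus(cfg, tibble::tibble(), generate_lexicon(cfg)),
               "nonempty")
  expect_error(
    generate_phytochem_tables(cfg, generate_lexicon(cfg),
                              generate_ontology(cfg),
                              tibble::tibble(spice_id = character(0),
                                             disease_id = character(0))),
    "nonempty")
})
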