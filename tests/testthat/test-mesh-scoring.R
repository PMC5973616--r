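assoc_tbl <- function(spice, disease_ids, polarity = "positive") {
  tibble::tibble(spice_id = spice, disease_id = disease_ids,
                 polarity = polarity)
}

test_that("rollup collects level prefixes and truncates deep numbers", {
  ont <- toy_ontology(c("C19", "C19.246", "C19.246.300"),
                      c("CAT", "SUB", "T2D"))
  r <- rollup("T2D", ont)
  expect_equal(r$categories, "C19")
  expect_equal(r$subcategories, "C19.246")
  expect_equal(r$diseases, "C19.246.300")

  r1 <- rollup("CAT", ont)
  expect_equal(r1$categories, "C19")
  expect_length(r1$subcategories, 0)
  expect_length(r1$diseases, 0)

  multi <- toy_ontology(c("C01.100.200", "C05.300.400"), c("M", "M"))
  rm_ <- rollup("M", multi)
  expect_setequal(rm_$categories, c("C01", "C05"))

  deep <- toy_ontology("C02.100.200.300.400", "DEEP")
  rd <- rollup("DEEP", deep)
  expect_equal(rd$diseases, "C02.100.200")

  expect_error(rollup("missing", ont), "unknown disease id")
})

test_that("aggregation groups polarities and applies overrides", {
  classified <- tibble::tibble(
    instance_id = paste0("i", 1:5),
    doc_id = c("a", "a", "b", "b", "c"),
    spice_id = "S1", disease_id = "D1",
    label = c("positive", "positive", "positive", "negative",
              "no-association"))
  expect_message(tab <- aggregate_associations(classified), "no manual")
  expect_equal(nrow(tab), 2)
  pos <- tab[tab$polarity == "positive", ]
  expect_equal(pos$n_instances, 3)
  expect_equal(pos$n_abstracts, 2)

  none <- classified |>
    dplyr::mutate(label = "no-association")
  expect_message(empty <- aggregate_associations(none))
  expect_equal(nrow(empty), 0)

  ov <- tibble::tibble(spice_id = "S1", disease_id = "D1",
                       polarity = "negative", action = "drop")
  tab2 <- aggregate_associations(classified, ov)
  expect_equal(tab2$polarity, "positive")

  flip <- tibble::tibble(spice_id = "S1", disease_id = "D1",
                         polarity = "negative", action = "flip")
  tab3 <- aggregate_associations(classified, flip)
  expect_setequal(tab3$polarity, "positive")

  badov <- tibble::tibble(spice_id = "SX", disease_id = "D9",
                          polarity = "positive", action = "drop")
  expect_warning(aggregate_associations(classified, badov), "unknown")
})

test_that("spectrum score matches direct formula evaluation", {
  # D = 4 categories with 2 subcategories each, one leaf per subcategory
  tns <- unlist(lapply(1:4, function(i) {
    unlist(lapply(1:2, function(j) {
      c(sprintf("C%02d.%03d", i, j), sprintf("C%02d.%03d.100", i, j))
    }))
  }))
  cats <- sprintf("C%02d", 1:4)
  ont <- toy_ontology(c(cats, tns),
                      c(paste0("CAT", 1:4), paste0("N", seq_along(tns))))
  leaf_ids <- ont$id[tree_level(ont$tree_number) == 3]

  # no associations -> 0
  expect_equal(spectrum_score(assoc_tbl("S", character(0)), ont, "S"), 0)

  # all subcats of 2 categories: D_hat = 2, sum = 2 -> 4
  two_full <- leaf_ids[1:4]
  expect_equal(spectrum_score(assoc_tbl("S", two_full), ont, "S"), 4)

  # half the subcats of all 4 categories: D_hat = 4, sum = 2 -> 8 (higher)
  half_all <- leaf_ids[c(1, 3, 5, 7)]
  expect_equal(spectrum_score(assoc_tbl("S", half_all), ont, "S"), 8)

  # full coverage of a D-category ontology gives D^2
  expect_equal(spectrum_score(assoc_tbl("S", leaf_ids), ont, "S"), 16)
})

test_that("27-category full coverage attains the 0-729 spectrum bounds", {
  cfg <- synthetic_config(seed = 4, n_categories = 27)
  ont <- generate_ontology(cfg)
  leaves <- ont$id[ont$level == 3]
  expect_equal(spectrum_score(assoc_tbl("S", leaves), ont, "S"), 729)
  expect_equal(spectrum_score(assoc_tbl("S", character(0)), ont, "S"), 0)
})

test_that("category spectrum matches direct formula evaluation", {
  # one category, subcat sizes (2, 4, 5)
  sizes <- c(2, 4, 5)
  tns <- c("C01", unlist(lapply(seq_along(sizes), function(j) {
    c(sprintf("C01.%03d", j),
      sprintf("C01.%03d.%03d", j, seq_len(sizes[j])))
  })))
  ont <- toy_ontology(tns, paste0("N", seq_along(tns)))
  leaf <- function(j, k) ont$id[ont$tree_number == sprintf("C01.%03d.%03d", j, k)]

  expect_equal(category_spectrum(assoc_tbl("S", character(0)), ont, "S",
                                 "C01"), 0)
  # 1 of 2 in subcat 1 and 5 of 5 in subcat 3 -> 2 * (0.5 + 1.0) = 3.0
  hits <- c(leaf(1, 1), vapply(1:5, function(k) leaf(3, k), character(1)))
  expect_equal(category_spectrum(assoc_tbl("S", hits), ont, "S", "C01"), 3.0)
  # full coverage -> (d_i)^2 = 9
  all_leaves <- ont$id[tree_level(ont$tree_number) == 3]
  expect_equal(category_spectrum(assoc_tbl("S", all_leaves), ont, "S",
                                 "C01"), 9)
  expect_error(category_spectrum(assoc_tbl("S", all_leaves), ont, "S",
                                 "C99"), "unknown category")
})

test_that("spectrum invariants hold on random association tables", {
  set.seed(808)
  cfg <- synthetic_config(seed = 44, n_categories = 6)
  ont <- generate_ontology(cfg)
  leaves <- ont$id[ont$level == 3]
  D <- 6
  for (trial in 1:15) {
    ids <- sample(leaves, sample(1:length(leaves), 1))
    tab <- assoc_tbl("S", ids)
    omega <- spectrum_score(tab, ont, "S")
    expect_gte(omega, 0)
    expect_lte(omega, D^2)
    # monotone under row insertion
    extra <- sample(setdiff(leaves, ids), 1)
    if (length(extra) == 1 && !is.na(extra)) {
      omega2 <- spectrum_score(dplyr::bind_rows(
        tab, assoc_tbl("S", extra)), ont, "S")
      expect_gte(omega2, omega)
    }
    # invariant to duplicate evidence
    omega3 <- spectrum_score(dplyr::bind_rows(tab, tab[1, ]), ont, "S")
    expect_equal(omega3, omega)
  }
  # equality at D^2 iff full presence
  expect_equal(spectrum_score(assoc_tbl("S", leaves), ont, "S"), D^2)
})

test_that("scores from a depth-5 ontology equal its depth-3 truncation", {
  base <- c("C01", "C01.050", "C01.050.101", "C01.050.102",
            "C02", "C02.050", "C02.050.101")
  deep <- toy_ontology(
    c(base, "C01.050.101.200.300", "C02.050.101.900"),
    c(paste0("N", seq_along(base)), "DEEP1", "DEEP2"))
  shallow <- toy_ontology(c(base, "C01.050.101", "C02.050.101"),
                          c(paste0("N", seq_along(base)), "DEEP1", "DEEP2"))
  for (ids in list("DEEP1", c("DEEP1", "DEEP2"), c("N3", "DEEP2"))) {
    expect_equal(spectrum_score(assoc_tbl("S", ids), deep, "S"),
                 spectrum_score(assoc_tbl("S", ids), shallow, "S"))
    expect_equal(category_spectrum(assoc_tbl("S", ids), deep, "S", "C01"),
                 category_spectrum(assoc_tbl("S", ids), shallow, "S", "C01"))
  }
})

test_that("recommendations rank by tradeoff with deterministic tie-breaks", {
  tns <- c("C01", "C01.001", "C01.002",
           "C01.001.101", "C01.001.102", "C01.002.101")
  ont <- toy_ontology(tns, paste0("N", seq_along(tns)))
  tab <- dplyr::bind_rows(
    assoc_tbl("A", c("N4", "N5", "N6")),            # full coverage
    assoc_tbl("B", "N4"),                           # partial
    assoc_tbl("C", "N4"),                           # tie with B
    assoc_tbl("C", "N6", polarity = "negative"))    # C penalized
  rec <- recommend_spices(tab, "C01", ont)
  expect_equal(rec$spice_id[1], "A")
  expect_equal(rec$rank, 1:3)
  # B and C tie on omega_pos but C has adverse load -> B first
  expect_lt(which(rec$spice_id == "B"), which(rec$spice_id == "C"))
  expect_false(any(rec$flagged[rec$tradeoff > 0]))

  single <- recommend_spices(assoc_tbl("A", "N4"), "C01", ont)
  expect_equal(single$rank, 1L)
  expect_error(recommend_spices(tab, "C77", ont), "unknown category")
})

test_that("spectrum report recovers planted broad-vs-narrow profiles", {
  profiles <- list(
    list(spice = 1, category_coverage = 1.0, subcategory_coverage = 0.5,
         polarity = "positive"),
    list(spice = 2, category_coverage = 0.5, subcategory_coverage = 1.0,
         polarity = "positive"),
    list(spice = 3, category_coverage = 0.25, subcategory_coverage = 0.5,
         polarity = "positive"))
  cfg <- synthetic_config(seed = 62, n_abstracts = 120, n_spices = 3,
                          n_categories = 8,
                          subcats_per_category = c(2, 2),
                          diseases_per_subcat = c(2, 3),
                          label_noise_rate = 0,
                          planted_profiles = profiles)
  ont <- generate_ontology(cfg)
  lex <- generate_lexicon(cfg)
  corp <- generate_corpus(cfg, ont, lex)
  tab <- corp$truth$labels |>
    dplyr::filter(label %in% c("positive", "negative")) |>
    dplyr::transmute(spice_id, disease_id, polarity = label) |>
    dplyr::distinct()
  rep_ <- spectrum_report(tab, dplyr::select(ont, id, name, tree_number))
  # broad coverage (all categories, half subcats) must outrank narrow
  expect_equal(rep_$spice_id,
               c("TAX01001", "TAX01002", "TAX01003"))
  # planted coverage makes the scores exact: spice 1 hits all 8 categories
  # at half their subcategories -> 8 * 8 * 0.5 = 32
  expect_equal(rep_$omega_pos[1], 8 * sum(rep(1 / 2, 8)))
  expect_equal(rep_$delta_omega, rep_$omega_pos - rep_$omega_neg)
})
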