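#' Run the full literature-mining pipeline on in-memory inputs
#'
#' Convenience wrapper chaining every stage: lexicon build, corpus
#' tagging, candidate construction, classifier training on labeled
#' instances, classification, association aggregation, spectrum and
#' tradeoff scoring, and (when phytochemical tables are supplied)
#' explanation of positive associations.
#'
#' @param records Abstract records ([parse_medline()] /
#'   [generate_corpus()]).
#' @param lexicon_entries Lexicon entry tibble.
#' @param ontology Ontology tibble (`id`, `name`, `tree_number`).
#' @param gold_labels Tibble keyed by `(pmid, sentence_index, spice_id,
#'   disease_id)` with a `label` column; instances matching a key are
#'   labeled, the rest are dropped from training. Split into train/test by
#'   `test_fraction`.
#' @param phytochem Optional list with `compounds`, `spice_compound`,
#'   `compound_disease` tables.
#' @param test_fraction Held-out fraction for evaluation (default 0.2).
#' @param cost SVM cost.
#' @param seed Seed for the split and training.
#' @return List: `instances`, `split`, `model`, `metrics`,
#'   `associations`, `spectrum`, `tradeoffs`, `explanation` (or `NULL`).
#' @export
run_pipeline <- function(records, lexicon_entries, ontology, gold_labels,
                         phytochem = NULL, test_fraction = 0.2, cost = 1,
                         seed = 1L) {
  surfaces <- build_lexicon(lexicon_entries)
  spice_matcher <- build_matcher(surfaces)
  disease_matcher <- build_matcher(
    distinct(ontology, .data$id, surface = .data$name), id_col = "id")
  mentions <- tag_corpus(records, spice_matcher, disease_matcher)
  instances <- build_candidates(records, mentions)
  labeled <- instances |>
    inner_join(rename(gold_labels, doc_id = "pmid"),
               by = c("doc_id", "sentence_index", "spice_id", "disease_id"))
  if (nrow(labeled) < 10) abort("too few labeled instances to train on")
  withr::with_seed(seed, {
    test_idx <- sample(nrow(labeled), round(test_fraction * nrow(labeled)))
  })
  train <- labeled[-test_idx, ]
  test <- labeled[test_idx, ]
  model <- train_relation_svm(train, cost = cost, seed = seed)
  metrics <- evaluate_relations(predict(model, test), test$label)
  classified <- bind_cols(
    select(instances, "instance_id", "doc_id", "spice_id", "disease_id"),
    select(predict(model, instances), ".pred"))
  associations <- aggregate_associations(classified)
  spectrum <- spectrum_report(associations, ontology)
  tradeoffs <- tradeoff_report(associations, ontology)
  explanation <- NULL
  if (!is.null(phytochem)) {
    sc <- phytochem$spice_compound |>
      semi_join(filter_bioactive(phytochem$compounds), by = "compound_id")
    cd <- therapeutic_links(phytochem$compound_disease)
    explanation <- explain_positive_associations(
      filter(associations, .data$polarity == "positive"),
      sc, cd, ontology = ontology)
  }
  list(instances = instances,
       split = list(train = train$instance_id, test = test$instance_id),
       model = model, metrics = metrics, associations = associations,
       spectrum = spectrum, tradeoffs = tradeoffs,
       explanation = explanation)
}
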