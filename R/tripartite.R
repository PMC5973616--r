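# Tripartite integration: spice -> phytochemical -> disease.

#' Keep only bioactive compounds
#'
#' @param compounds Tibble with a logical `bioactive` column.
#' @return The bioactive subset, original order preserved.
#' @export
filter_bioactive <- function(compounds) {
  stopifnot(is.data.frame(compounds), "bioactive" %in% names(compounds))
  compounds[which(compounds$bioactive), , drop = FALSE]
}

#' Keep only therapeutic compound-disease links
#'
#' Rows with an association type outside
#' \{therapeutic, marker, inferred\} are skipped with a warning.
#'
#' @param links Tibble with an `association_type` column.
#' @return The therapeutic subset, original order preserved.
#' @export
therapeutic_links <- function(links) {
  stopifnot(is.data.frame(links), "association_type" %in% names(links))
  known <- c("therapeutic", "marker", "inferred")
  bad <- !(links$association_type %in% known)
  if (any(bad)) {
    warn(sprintf("%d link row(s) with unknown association type skipped",
                 sum(bad)))
    links <- links[!bad, , drop = FALSE]
  }
  links[links$association_type == "therapeutic", , drop = FALSE]
}

#' Explain positive spice-disease associations via phytochemicals
#'
#' A positive association (spice `s`, disease `d`) is explained iff some
#' compound `c` is contained in `s` (spice-compound table) and carries a
#' link to the same disease ID `d` (compound-disease table). The input
#' tables are expected pre-filtered to bioactive compounds and
#' therapeutic links (see [filter_bioactive()], [therapeutic_links()]).
#' When an ontology is supplied, positives are restricted to rows whose
#' disease has a level-3 tree number; unresolvable disease IDs are
#' excluded and logged.
#'
#' @param positives Tibble of positive associations (`spice_id`,
#'   `disease_id`; a `polarity` column is filtered to `"positive"`).
#' @param spice_compound Tibble `spice_id`, `compound_id`.
#' @param compound_disease Tibble `compound_id`, `disease_id`.
#' @param ontology Optional ontology tibble for the level-3 restriction.
#' @return Object of class `explanation_report`: list with
#'   `associations` (per-row `explained` flag + `compounds` list column),
#'   `coverage` (explained / total), `hypotheses` (unexplained rows with
#'   the spice's candidate compounds).
#' @export
explain_positive_associations <- function(positives, spice_compound,
                                          compound_disease,
                                          ontology = NULL) {
  stopifnot(is.data.frame(positives), is.data.frame(spice_compound),
            is.data.frame(compound_disease))
  if ("polarity" %in% names(positives)) {
    positives <- filter(positives, .data$polarity == "positive")
  }
  positives <- distinct(positives, .data$spice_id, .data$disease_id)
  if (!is.null(ontology)) {
    leaf_ids <- ontology |>
      filter(tree_level(.data$tree_number) >= 3L) |>
      pull(.data$id) |>
      unique()
    unknown <- !(positives$disease_id %in% ontology$id)
    if (any(unknown)) {
      inform(sprintf("%d positive row(s) with unresolvable disease ids excluded",
                     sum(unknown)))
    }
    positives <- filter(positives, .data$disease_id %in% leaf_ids)
  }
  paths <- spice_compound |>
    distinct(.data$spice_id, .data$compound_id) |>
    inner_join(distinct(compound_disease, .data$compound_id,
                        .data$disease_id),
               by = "compound_id", relationship = "many-to-many")
  assoc <- positives |>
    left_join(
      paths |>
        group_by(.data$spice_id, .data$disease_id) |>
        summarise(compounds = list(sort(unique(.data$compound_id))),
                  .groups = "drop"),
      by = c("spice_id", "disease_id")) |>
    mutate(explained = !map_lgl(.data$compounds, is.null),
           compounds = map(.data$compounds, ~ .x %||% character(0)))
  by_spice <- spice_compound |>
    group_by(.data$spice_id) |>
    summarise(candidate_compounds = list(sort(unique(.data$compound_id))),
              .groups = "drop")
  hypotheses <- assoc |>
    filter(!.data$explained) |>
    select("spice_id", "disease_id") |>
    left_join(by_spice, by = "spice_id") |>
    mutate(candidate_compounds = map(.data$candidate_compounds,
                                     ~ .x %||% character(0)))
  structure(
    list(associations = select(assoc, "spice_id", "disease_id",
                               "explained", "compounds"),
         coverage = if (nrow(assoc) == 0) NA_real_ else
           mean(assoc$explained),
         hypotheses = hypotheses),
    class = "explanation_report"
  )
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(sprintf(
    "<explanation_report: %d positive associations, %.1f%% explained, %d hypotheses>\n",
    nrow(x$associations), 100 * x$coverage, nrow(x$hypotheses)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.explanation_report <- function(x, ...) x$associations

#' @exportS3Method generics::glance
glance.explanation_report <- function(x, ...) {
  tibble(n_positive = nrow(x$associations),
         n_explained = sum(x$associations$explained),
         coverage = x$coverage)
}
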