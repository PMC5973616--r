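# Hierarchy rollup and spectrum / tradeoff scoring.
#
# The disease hierarchy is analysed at three levels: category (1 dotted
# segment), sub-category (2 segments) and disease (3 segments). Presence
# is binary at each level: evidence counts never change a score.

#' Tree-number helpers
#'
#' `tree_level()` returns the dotted-segment count of a tree number;
#' `tree_prefix()` truncates tree numbers to their first `level` segments
#' (`NA` where the number is shallower than `level`).
#'
#' @param tree_number Character vector of dotted tree numbers.
#' @param level Target depth (1, 2 or 3).
#' @return Integer vector / character vector of the same length.
#' @examples
#' tree_level("C19.246.300")
#' tree_prefix("C19.246.300", 2)
#' @export
tree_level <- function(tree_number) {
  stringr::str_count(tree_number, stringr::fixed(".")) + 1L
}

#' @rdname tree_level
#' @export
tree_prefix <- function(tree_number, level) {
  parts <- str_split(tree_number, stringr::fixed("."))
  map_chr(parts, function(p) {
    if (length(p) < level) NA_character_
    else paste(p[seq_len(level)], collapse = ".")
  })
}

#' Roll a disease up the hierarchy
#'
#' For every tree number of the node, its level-1, level-2 and level-3
#' prefixes (where they exist) are collected; tree numbers deeper than
#' three segments are truncated to their three-segment ancestor.
#'
#' @param disease_id A single ontology ID.
#' @param ontology Ontology tibble (`id`, `name`, `tree_number`; one row
#'   per tree number).
#' @return List with character-vector elements `categories`,
#'   `subcategories`, `diseases` (distinct truncated tree numbers).
#' @examples
#' ont <- tibble::tibble(id = "D1", name = "x", tree_number = "C19.246.300")
#' rollup("D1", ont)
#' @export
rollup <- function(disease_id, ontology) {
  stopifnot(length(disease_id) == 1L)
  tns <- ontology$tree_number[ontology$id == disease_id]
  if (length(tns) == 0) abort(sprintf("unknown disease id `%s`", disease_id))
  up <- function(level) {
    out <- tree_prefix(tns, level)
    sort(unique(out[!is.na(out)]))
  }
  list(categories = up(1L), subcategories = up(2L), diseases = up(3L))
}

# presence sets of one spice at one polarity: distinct truncated tree
# numbers at each level reachable from its associated diseases
presence_sets <- function(associations, ontology, spice, polarity) {
  ids <- associations |>
    filter(.data$spice_id == spice, .data$polarity == !!polarity) |>
    pull(.data$disease_id) |>
    unique()
  known <- ids %in% ontology$id
  if (any(!known)) {
    warn(sprintf("%d associated disease id(s) not in ontology ignored",
                 sum(!known)))
    ids <- ids[known]
  }
  rolled <- map(ids, rollup, ontology = ontology)
  list(categories = sort(unique(unlist(map(rolled, "categories")))),
       subcategories = sort(unique(unlist(map(rolled, "subcategories")))),
       diseases = sort(unique(unlist(map(rolled, "diseases")))))
}

# ontology shape: subcategory count per category, disease count per
# subcategory (computed from distinct truncated tree numbers)
ontology_shape <- function(ontology) {
  tns <- unique(ontology$tree_number)
  cats <- sort(unique(tree_prefix(tns, 1L)))
  subs <- tree_prefix(tns, 2L)
  subs <- sort(unique(subs[!is.na(subs)]))
  lvl3 <- tree_prefix(tns, 3L)
  lvl3 <- sort(unique(lvl3[!is.na(lvl3)]))
  list(
    categories = cats,
    subcats_by_cat = split(subs, tree_prefix(subs, 1L))[cats] |>
      setNames(cats),
    leaves_by_subcat = split(lvl3, tree_prefix(lvl3, 2L))
  )
}

#' Aggregate classified instances into an association table
#'
#' Instances predicted (or annotated) positive / negative are grouped into
#' distinct `(spice_id, disease_id, polarity)` rows with their supporting
#' evidence; no-association instances are discarded. An optional override
#' table mirrors the manual cleaning of predicted negative associations:
#' rows can be dropped (`action = "drop"`) or have their polarity flipped
#' (`action = "flip"`). Without overrides, all predictions are accepted
#' and a notice is emitted.
#'
#' @param classified Tibble with columns `instance_id`, `doc_id`,
#'   `spice_id`, `disease_id` and `label` (or `.pred`).
#' @param overrides Optional tibble `spice_id`, `disease_id`, `polarity`,
#'   `action`.
#' @return Association tibble: `spice_id`, `disease_id`, `polarity`,
#'   `n_instances`, `n_abstracts`, `instance_ids` (list column).
#' @export
aggregate_associations <- function(classified, overrides = NULL) {
  stopifnot(is.data.frame(classified))
  lab <- if ("label" %in% names(classified)) "label" else ".pred"
  tab <- classified |>
    mutate(polarity = .data[[lab]]) |>
    filter(.data$polarity %in% c("positive", "negative")) |>
    group_by(.data$spice_id, .data$disease_id, .data$polarity) |>
    summarise(n_instances = n(),
              n_abstracts = n_distinct(.data$doc_id),
              instance_ids = list(.data$instance_id), .groups = "drop")
  if (is.null(overrides)) {
    inform("no manual overrides supplied; accepting all classified associations")
    return(tab)
  }
  stopifnot(all(c("spice_id", "disease_id", "polarity", "action") %in%
                  names(overrides)))
  key <- function(d) paste(d$spice_id, d$disease_id, d$polarity)
  unknown <- !(key(overrides) %in% key(tab))
  if (any(unknown)) {
    warn(sprintf("%d override row(s) reference unknown associations",
                 sum(unknown)))
  }
  drop <- overrides |> filter(.data$action == "drop")
  flip <- overrides |> filter(.data$action == "flip")
  tab <- tab[!(key(tab) %in% key(drop)), ]
  hit <- key(tab) %in% key(flip)
  tab$polarity[hit] <- ifelse(tab$polarity[hit] == "positive",
                              "negative", "positive")
  tab
}

#' Spectrum score of one spice
#'
#' The spectrum score is `Omega = D_hat * sum_i(d_hat_i / d_i)`, where
#' `D_hat` is the number of disease categories the spice is associated
#' with at the given polarity, `d_i` the total number of subcategories of
#' category `i`, and `d_hat_i` the number of distinct subcategories of
#' category `i` associated with the spice. Presence is binary, so the
#' score ranges from 0 (no associations) to `D^2` (every subcategory of
#' every category covered); with 27 categories the maximum is 729.
#' Degenerate categories without subcategories contribute nothing and are
#' excluded from `D_hat`.
#'
#' @param associations Association tibble ([aggregate_associations()]).
#' @param ontology Ontology tibble.
#' @param spice Species identifier.
#' @param polarity `"positive"` (benevolence) or `"negative"` (adverse).
#' @return Single numeric score.
#' @export
spectrum_score <- function(associations, ontology, spice,
                           polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  shape <- ontology_shape(ontology)
  pres <- presence_sets(associations, ontology, spice, polarity)
  d_tot <- lengths(shape$subcats_by_cat)
  degenerate <- names(d_tot)[d_tot == 0]
  if (length(degenerate) > 0) {
    inform(sprintf("%d categor(ies) without subcategories excluded",
                   length(degenerate)))
  }
  present_cats <- setdiff(pres$categories, degenerate)
  if (length(present_cats) == 0) return(0)
  d_hat <- map_dbl(present_cats, function(cc) {
    sum(tree_prefix(pres$subcategories, 1L) == cc, na.rm = TRUE)
  })
  d_i <- d_tot[present_cats]
  length(present_cats) * sum(d_hat / d_i)
}

#' Relative benevolence
#'
#' The exact difference between the benevolence and adverse spectrum
#' scores of a spice.
#'
#' @param omega_pos,omega_neg Spectrum scores at positive / negative
#'   polarity.
#' @return `omega_pos - omega_neg`.
#' @export
relative_benevolence <- function(omega_pos, omega_neg) {
  omega_pos - omega_neg
}

#' Category-specific spectrum score
#'
#' Within category `i`, `Omega_i = d_hat_i * sum_k(a_hat_k / a_k)` over
#' the subcategories `k` of `i`: `a_k` is the total number of level-3
#' diseases in subcategory `k` and `a_hat_k` the number of distinct
#' level-3 diseases of `k` associated with the spice. Ranges from 0 to
#' `d_i^2`. Subcategories without level-3 diseases contribute nothing and
#' are excluded from `d_hat_i`.
#'
#' @inheritParams spectrum_score
#' @param category Level-1 tree number (e.g. `"C19"`).
#' @return Single numeric score.
#' @export
category_spectrum <- function(associations, ontology, spice, category,
                              polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  shape <- ontology_shape(ontology)
  if (!category %in% shape$categories) {
    abort(sprintf("unknown category `%s`", category))
  }
  pres <- presence_sets(associations, ontology, spice, polarity)
  subs <- shape$subcats_by_cat[[category]]
  a_tot <- lengths(shape$leaves_by_subcat[subs]) |> setNames(subs)
  a_tot[is.na(a_tot)] <- 0L
  live <- subs[a_tot[subs] > 0]
  if (length(live) < length(subs)) {
    inform(sprintf("%d subcategor(ies) without diseases excluded",
                   length(subs) - length(live)))
  }
  present_subs <- intersect(pres$subcategories, live)
  if (length(present_subs) == 0) return(0)
  a_hat <- map_dbl(present_subs, function(ss) {
    sum(tree_prefix(pres$diseases, 2L) == ss, na.rm = TRUE)
  })
  length(present_subs) * sum(a_hat / a_tot[present_subs])
}

#' Per-spice spectrum report
#'
#' Computes the benevolence spectrum, adverse spectrum and relative
#' benevolence for every spice in the association table.
#'
#' @param associations Association tibble.
#' @param ontology Ontology tibble.
#' @return Tibble of class `spectrum_report`: `spice_id`, `omega_pos`,
#'   `omega_neg`, `delta_omega`, sorted by `delta_omega` descending.
#' @export
spectrum_report <- function(associations, ontology) {
  spices <- sort(unique(associations$spice_id))
  out <- tibble(
    spice_id = spices,
    omega_pos = map_dbl(spices, ~ spectrum_score(associations, ontology,
                                                 .x, "positive")),
    omega_neg = map_dbl(spices, ~ spectrum_score(associations, ontology,
                                                 .x, "negative"))
  ) |>
    mutate(delta_omega = relative_benevolence(.data$omega_pos,
                                              .data$omega_neg)) |>
    arrange(desc(.data$delta_omega), .data$spice_id)
  class(out) <- c("spectrum_report", class(out))
  out
}

#' Per-(spice, category) therapeutic tradeoff scores
#'
#' Computes category-specific benevolence and adverse spectra and their
#' difference (the therapeutic tradeoff score) for every spice and every
#' category.
#'
#' @inheritParams spectrum_report
#' @return Tibble of class `tradeoff_report`: `spice_id`, `category`,
#'   `omega_pos`, `omega_neg`, `tradeoff`.
#' @export
tradeoff_report <- function(associations, ontology) {
  shape <- ontology_shape(ontology)
  grid <- tidyr::expand_grid(spice_id = sort(unique(associations$spice_id)),
                             category = shape$categories)
  out <- grid |>
    mutate(
      omega_pos = map2_dbl(.data$spice_id, .data$category,
                           ~ category_spectrum(associations, ontology,
                                               .x, .y, "positive")),
      omega_neg = map2_dbl(.data$spice_id, .data$category,
                           ~ category_spectrum(associations, ontology,
                                               .x, .y, "negative")),
      tradeoff = .data$omega_pos - .data$omega_neg
    )
  class(out) <- c("tradeoff_report", class(out))
  out
}

#' Rank spices for culinary recommendation against one disease category
#'
#' Spices are sorted by therapeutic tradeoff score descending, ties broken
#' by category benevolence spectrum descending, then by spice ID. Spices
#' whose tradeoff is not positive are flagged.
#'
#' @param tradeoffs A `tradeoff_report` (or association table plus
#'   `ontology` to compute one).
#' @param category Level-1 tree number.
#' @param ontology Required only when `tradeoffs` is an association table.
#' @return Tibble: `rank`, `spice_id`, `omega_pos`, `omega_neg`,
#'   `tradeoff`, `flagged` (TRUE when `tradeoff <= 0`).
#' @export
recommend_spices <- function(tradeoffs, category, ontology = NULL) {
  if (!inherits(tradeoffs, "tradeoff_report")) {
    if (is.null(ontology)) {
      abort("supply a tradeoff_report, or an association table plus `ontology`")
    }
    tradeoffs <- tradeoff_report(tradeoffs, ontology)
  }
  if (!category %in% tradeoffs$category) {
    abort(sprintf("unknown category `%s`", category))
  }
  tradeoffs |>
    filter(.data$category == !!category) |>
    arrange(desc(.data$tradeoff), desc(.data$omega_pos), .data$spice_id) |>
    mutate(rank = row_number(), flagged = .data$tradeoff <= 0) |>
    select("rank", "spice_id", "omega_pos", "omega_neg", "tradeoff",
           "flagged")
}

#' @exportS3Method generics::tidy
tidy.spectrum_report <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("omega_pos", "omega_neg", "delta_omega"),
                        names_to = "score", values_to = "value")
}

#' @exportS3Method generics::glance
glance.spectrum_report <- function(x, ...) {
  tibble(n_spices = nrow(x),
         n_benevolent = sum(x$delta_omega > 0),
         prop_benevolent = mean(x$delta_omega > 0),
         max_delta = max(x$delta_omega),
         min_delta = min(x$delta_omega))
}

#' Plot a spectrum report
#'
#' Bar chart of relative benevolence per spice, ranked, mirroring the
#' broad-spectrum benevolence ranking view.
#'
#' @param object A `spectrum_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum_report <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(spice_id = stats::reorder(.data$spice_id, .data$delta_omega))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spice_id,
                                   y = .data$delta_omega,
                                   fill = .data$delta_omega > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#d95f02")) +
    ggplot2::labs(x = NULL, y = "relative benevolence (delta omega)",
                  title = "Spice ranking by relative benevolence")
}
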