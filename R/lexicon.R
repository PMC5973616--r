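#' Standardize a scientific name to its species binomial
#'
#' Infraspecific qualifiers (`var.`, `subsp.`, `ssp.`, `cv.`, `f.`) and
#' everything after them are dropped so that varieties collapse onto their
#' parent species, e.g. `"Capsicum baccatum var. pendulum"` becomes
#' `"Capsicum baccatum"`. Names without a recognised qualifier are returned
#' unchanged; the operation is idempotent.
#'
#' @param name Character vector of scientific names.
#' @return Character vector of the same length.
#' @examples
#' standardize_variety("Capsicum baccatum var. pendulum")
#' standardize_variety("Curcuma longa")
#' @export
standardize_variety <- function(name) {
  stopifnot(is.character(name))
  if (any(!nzchar(str_trim(name)))) abort("scientific names must be nonempty")
  out <- str_replace(
    name,
    "\\s+(var\\.|subsp\\.|ssp\\.|cv\\.|f\\.)\\s+.*$",
    ""
  )
  str_trim(out)
}

#' Add English plural forms to a set of names
#'
#' Each input name is kept and a rule-based plural is added: `-y` after a
#' consonant becomes `-ies`; names ending in `s`, `x`, `z`, `ch` or `sh`
#' gain `es`; everything else gains `s`. For multi-word names the last word
#' is pluralized. Applying the function to its own output is a no-op
#' (names already ending in a plural suffix are not re-pluralized into
#' forms like `"clovess"`).
#'
#' @param names Character vector of (typically lowercase) common names.
#' @return Character vector: the union of inputs and their plural forms,
#'   in first-appearance order.
#' @examples
#' expand_plurals(c("clove", "berry"))
#' @export
expand_plurals <- function(names) {
  stopifnot(is.character(names))
  if (any(!nzchar(names))) abort("names must be nonempty")
  plural_one <- function(nm) {
    if (str_detect(nm, "(ies|es|[^sxz]s)$")) return(nm)  # already plural
    if (str_detect(nm, "[^aeiou]y$")) {
      str_replace(nm, "y$", "ies")
    } else if (str_detect(nm, "(s|x|z|ch|sh)$")) {
      paste0(nm, "es")
    } else {
      paste0(nm, "s")
    }
  }
  plurals <- map_chr(names, plural_one)
  unique(c(rbind(names, plurals)))
}

#' Remove common names shared by several species
#'
#' A common name that maps to two or more species identifiers is ambiguous
#' and removed from every species carrying it. Scientific names are kept
#' as matchable surfaces regardless, so a species whose common-name set
#' becomes empty is still taggable.
#'
#' @param entries Lexicon tibble with columns `species_id`,
#'   `scientific_name`, `common_name` (one row per common name; `NA`
#'   allowed for species without common names) and optionally `provenance`.
#' @return Tibble of the same shape with ambiguous common-name rows
#'   dropped; every input species keeps at least a `scientific_name` row
#'   (with `common_name = NA`).
#' @export
dedupe_ambiguous <- function(entries) {
  stopifnot(is.data.frame(entries))
  entries <- as_tibble(entries)
  named <- filter(entries, !is.na(.data$common_name))
  ambiguous <- named |>
    distinct(.data$species_id, .data$common_name) |>
    count(.data$common_name) |>
    filter(.data$n >= 2) |>
    pull(.data$common_name)
  kept <- filter(entries,
                 is.na(.data$common_name) |
                   !(.data$common_name %in% ambiguous))
  # species stripped of every common name keep a scientific-name-only row
  lost <- setdiff(unique(entries$species_id), unique(kept$species_id))
  if (length(lost) > 0) {
    stubs <- entries |>
      filter(.data$species_id %in% lost) |>
      distinct(.data$species_id, .keep_all = TRUE) |>
      mutate(common_name = NA_character_)
    kept <- bind_rows(kept, stubs)
  }
  arrange(kept, .data$species_id)
}

#' Build the matchable surface table of a spice lexicon
#'
#' Applies the dictionary-construction pipeline: scientific names are
#' standardized to species binomials, common names are lowercased and
#' (optionally) expanded with plural forms, ambiguous common names are
#' removed, and scientific names are added as matchable surfaces (abstracts
#' routinely cite Latin binomials). Matching downstream is case-insensitive,
#' so all surfaces are stored lowercase.
#'
#' @param entries Lexicon tibble as in [dedupe_ambiguous()].
#' @param plurals Add plural forms of common names? Default `TRUE`.
#' @return Tibble with columns `species_id`, `surface`, `surface_type`
#'   (`"scientific"` or `"common"`); one row per distinct surface per
#'   species, no surface mapping to two species.
#' @export
build_lexicon <- function(entries, plurals = TRUE) {
  stopifnot(is.data.frame(entries))
  entries <- as_tibble(entries) |>
    mutate(scientific_name = standardize_variety(.data$scientific_name))
  entries <- dedupe_ambiguous(entries)
  common <- entries |>
    filter(!is.na(.data$common_name)) |>
    mutate(common_name = str_to_lower(.data$common_name))
  if (plurals && nrow(common) > 0) {
    common <- common |>
      group_by(.data$species_id) |>
      reframe(surface = expand_plurals(.data$common_name)) |>
      mutate(surface_type = "common")
  } else {
    common <- common |>
      transmute(species_id = .data$species_id,
                surface = .data$common_name,
                surface_type = "common")
  }
  sci <- entries |>
    distinct(.data$species_id, .data$scientific_name) |>
    transmute(species_id = .data$species_id,
              surface = str_to_lower(.data$scientific_name),
              surface_type = "scientific")
  surf <- bind_rows(sci, common) |>
    distinct(.data$species_id, .data$surface, .keep_all = TRUE)
  # plural expansion can re-introduce cross-species ambiguity; drop it too
  amb <- surf |> count(.data$surface) |> filter(.data$n >= 2) |> pull(.data$surface)
  surf <- filter(surf, .data$surface_type == "scientific" |
                   !(.data$surface %in% amb))
  arrange(surf, .data$species_id, desc(.data$surface_type), .data$surface)
}

#' Read / write a lexicon entry table as TSV
#'
#' Columns: `species_id`, `scientific_name`, `common_name`, `provenance`.
#'
#' @param path File path.
#' @param entries Lexicon entry tibble.
#' @return `read_lexicon()` returns the entry tibble; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(entries, path) {
  readr::write_tsv(entries, path)
  invisible(path)
}
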