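#' Parse MEDLINE-style PubMed XML into abstract records
#'
#' Reads the PubMed XML dialect
#' (`PubmedArticle/MedlineCitation/PMID/Article/ArticleTitle/Abstract/AbstractText`)
#' and returns one row per citation that carries abstract text. Multi-part
#' abstracts (several `AbstractText` sections) are concatenated with single
#' spaces. Citations without abstract text are dropped (their number is
#' reported via a message and the `dropped` attribute); citations without a
#' PMID are skipped with a warning.
#'
#' @param xml Path/connection to a PubMed XML file (plain or gzip), or an
#'   `xml2` document.
#' @return Tibble with columns `pmid`, `date` (year or ISO date as a
#'   string), `title`, `abstract_text`, `journal`, `authors` (list column
#'   of character vectors), plus attribute `dropped` (count of abstract-less
#'   citations).
#' @export
parse_medline <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  cits <- xml2::xml_find_all(doc, ".//MedlineCitation")
  first_text <- function(node, xpath) {
    hit <- xml2::xml_find_first(node, xpath)
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  dropped <- 0L
  rows <- vector("list", length(cits))
  for (i in seq_along(cits)) {
    node <- cits[[i]]
    parts <- xml2::xml_text(
      xml2::xml_find_all(node, ".//Abstract/AbstractText"))
    parts <- parts[nzchar(str_trim(parts))]
    if (length(parts) == 0) {
      dropped <- dropped + 1L
      next
    }
    pmid <- first_text(node, "./PMID")
    if (is.na(pmid) || !nzchar(str_trim(pmid))) {
      warn(sprintf("citation %d has no PMID; record skipped", i))
      next
    }
    year <- first_text(node, ".//DateCompleted/Year")
    if (is.na(year)) year <- first_text(node, ".//Journal//PubDate/Year")
    authors <- xml2::xml_find_all(node, ".//AuthorList/Author")
    author_names <- map_chr(authors, function(a) {
      ln <- first_text(a, "./LastName")
      fn <- first_text(a, "./ForeName")
      str_trim(paste(ln[!is.na(ln)], fn[!is.na(fn)], collapse = " "))
    })
    rows[[i]] <- tibble(
      pmid = str_trim(pmid),
      date = year,
      title = first_text(node, ".//ArticleTitle") %||% NA_character_,
      abstract_text = paste(str_trim(parts), collapse = " "),
      journal = first_text(node, ".//Journal/Title"),
      authors = list(author_names)
    )
  }
  out <- bind_rows(rows)
  if (dropped > 0) {
    inform(sprintf("dropped %d citation(s) without abstract text", dropped))
  }
  if (nrow(out) > 0 && anyDuplicated(out$pmid) > 0) {
    abort("duplicate PMIDs in corpus")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Write abstract records as PubMed-dialect XML
#'
#' Serializes a record tibble (columns as returned by [parse_medline()])
#' into the XML dialect [parse_medline()] accepts, so that
#' `parse_medline(write_medline(records, path))` reproduces the records
#' field for field.
#'
#' @param records Record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(records, path) {
  stopifnot(is.data.frame(records))
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(records))) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", records$pmid[i])
    dc <- xml2::xml_add_child(cit, "DateCompleted")
    xml2::xml_add_child(dc, "Year", records$date[i])
    article <- xml2::xml_add_child(cit, "Article")
    jr <- xml2::xml_add_child(article, "Journal")
    xml2::xml_add_child(jr, "Title", records$journal[i])
    xml2::xml_add_child(article, "ArticleTitle", records$title[i])
    ab <- xml2::xml_add_child(article, "Abstract")
    xml2::xml_add_child(ab, "AbstractText", records$abstract_text[i])
    al <- xml2::xml_add_child(article, "AuthorList")
    for (a in records$authors[[i]]) {
      parts <- strsplit(a, " ", fixed = TRUE)[[1]]
      au <- xml2::xml_add_child(al, "Author")
      xml2::xml_add_child(au, "LastName", parts[1])
      if (length(parts) > 1) {
        xml2::xml_add_child(au, "ForeName",
                            paste(parts[-1], collapse = " "))
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
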