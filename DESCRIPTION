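Package: spicemine
Title: Mining Spice-Disease Associations from Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for assessing the health impact of culinary
    spices and herbs from biomedical literature. Parses MEDLINE-style
    abstract records, recognises spice and disease mentions with a
    token-level longest-match dictionary tagger, builds masked
    spice-disease candidate instances, classifies each pair as a positive,
    negative or no-association assertion with a TF-IDF one-vs-all linear
    support vector machine, rolls classified associations up a
    MeSH-like three-level disease hierarchy, and computes benevolence and
    adverse spectrum scores, relative benevolence, and per-category
    therapeutic tradeoff scores for culinary recommendations. Positive
    associations are linked to bioactive phytochemicals with therapeutic
    compound-disease evidence to quantify mechanistic explanation
    coverage. A synthetic-data module generates every pipeline input with
    planted ground truth so the full analysis is exercisable and testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
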