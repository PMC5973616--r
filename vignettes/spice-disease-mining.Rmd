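---
title: "Mining spice-disease associations: models, scores and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining spice-disease associations: models, scores and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spicemine)
library(dplyr)
```

# The analysis

`spicemine` quantifies the health impact of culinary spices and herbs
from biomedical abstracts. The unit of inference is a sentence-level
spice-disease pair: a sentence mentioning ginger and gout asserts, in
context, a positive effect, a negative effect, or no association at all.
Classified pairs are aggregated into an association table, rolled up a
three-level disease hierarchy, and condensed into per-spice breadth
scores; positive associations are then cross-referenced against
phytochemical evidence for mechanistic hypotheses.

This vignette documents the models and the design decisions; every
number it mentions is computed by the package's test suite or the
chunks below, not asserted from memory.

# Dictionary and ingest

The spice dictionary maps surfaces (scientific names and common names)
to species identifiers. Construction applies three rules:

* **Variety standardization** (`standardize_variety()`): infraspecific
  qualifiers (`var.`, `subsp.`, `ssp.`, `cv.`, `f.`) and what follows are
  dropped, so *Capsicum baccatum* var. *pendulum* collapses onto
  *Capsicum baccatum*. Unrecognized names pass through; the rule is
  idempotent.
* **Plural expansion** (`expand_plurals()`): rule-based English plurals
  (+`s`; consonant+`y` to `ies`; +`es` after sibilants) are added so both
  "clove" and "cloves" are matchable. Names already carrying a plural
  suffix are left alone, which makes the expansion a closure operator.
* **Ambiguity removal** (`dedupe_ambiguous()`): a common name claimed by
  two species identifies neither and is removed from all of them; a
  species stripped of every common name remains matchable through its
  scientific name.

Surfaces are lowercased at build time and matching is case-insensitive
throughout. The hierarchy of choices here trades a little precision
(case distinctions could disambiguate in rare cases) for recall on
title/abstract prose, where capitalization is typographic.

Abstract records come from the PubMed XML dialect
(`parse_medline()` / `write_medline()`): one record per citation with
abstract text, multi-part abstracts joined with single spaces,
abstract-less citations dropped (counted), PMID-less citations skipped
with a warning. The writer emits exactly the dialect the parser accepts,
and the synthetic corpus round-trips through it field for field.

# Entity recognition

Both entity types are tagged by a token-level dictionary matcher
(`build_matcher()`, `tag_spices()`, `tag_diseases()`): surfaces are
tokenized with the pipeline tokenizer, and scanning is greedy left to
right - at each position the longest surface starting there wins, and
scanning resumes after an emitted match, so mentions of one type never
overlap. Two properties are worth stating precisely:

* At one start position there can be no tie: two patterns spanning the
  same tokens are the same pattern (duplicates are removed at build
  time, keeping the lexicographically smallest identifier should a
  surface pathologically map to two species).
* The result is independent of lexicon row order; the test suite checks
  both properties against an exhaustive O(n^2 |dict|) scan.

Disease recognition in the original protocol is delegated to an
external statistical tagger; that tool is a dependency, not a
contribution, so the package ships a dictionary fallback over ontology
node names with identical longest-match semantics, plus an adapter
(`adapt_external_mentions()`) that converts a character-offset tagger
output into token-level mentions and drops records whose IDs do not
resolve. On the synthetic corpus the fallback recovers every planted
mention, which is the correct ceiling for a dictionary corpus and says
nothing about recall on real prose - see Limitations.

# Candidate construction

Sentences are segmented by a rule-based splitter (terminators `.!?`
followed by whitespace, with an abbreviation list - `i.e.`, `e.g.`,
`var.`, etc. - and decimal guards). Token normalization removes all
characters outside letters, digits, whitespace and the retained
punctuation `! , . : ;`, keeps that punctuation as standalone tokens,
lowercases words, and replaces numeric tokens (integers and decimals)
with the reserved `NUM` token. Reserved tokens pass through unchanged,
making normalization idempotent.

A sentence qualifies as a candidate iff it mentions at least one spice
and one disease. A sentence with *m* spice and *n* disease mentions
becomes *m x n* instances: per instance, the focal spice span collapses
to the reserved `SPICE` token, the focal disease span to `DISEASE`, and
every non-focal entity span to `MASKED`. Masking-with-placeholder (as
opposed to deletion) was chosen because it preserves token positions:
every instance from one sentence has the same length, and the signed
distance features `dist[i] = i - index(focal)` remain comparable across
instances. Distances are signed, not absolute, because left and right
context carry different evidential weight. Part-of-speech and chunk
tags come from a pluggable tagger contract (`tokens ->
list(pos, chunk)`); the bundled default is a deterministic
suffix/lexicon heuristic, and any tagger returning wrong-length vectors
is rejected as a contract violation.

# Relation classification

The default engine is a one-vs-all linear SVM over TF-IDF features:

* `tf(t, s) = f_ts` (raw count), `idf(t) = log(N / n_t)` with natural
  logarithm, feature `f_ts * idf(t)`; vocabulary is unigrams plus
  bigrams of the normalized, masked tokens. No sublinear tf damping and
  no row normalization are applied - the plain product is the stated
  weighting, and the linear SVM absorbs scale.
* One binary linear SVM per class (cost 1 by default, exposed);
  prediction is the argmax of decision values.
* Class imbalance is addressed by oversampling inside training data
  only: a class of size *m* with factor *f* grows to `round(m * f)` -
  `floor(f)` copies of everything plus a seeded sample without
  replacement for the remainder. The defaults (negative 12, positive
  1.35) mirror the imbalance treatment of the original protocol; the
  rounding rule is this package's choice since only the factors are
  stated.
* `cross_validate()` builds stratified folds, applies oversampling
  strictly inside training folds (the suite audits that duplicated
  instances never cross a fold boundary) and scores a cost grid by mean
  validation macro-F1.
* A manual-override hook on `aggregate_associations()` can drop or flip
  classified rows before scoring, mirroring a manual cleaning pass over
  predicted negative associations; by default all predictions are
  accepted and a notice is logged.

A convolutional architecture (word/position/PoS/chunk embeddings) is a
documented alternative engine in the source protocol; this package
standardizes on the SVM, which is desk-scale, dependency-light and
reaches the synthetic corpus' separability ceiling. Evaluation
(`evaluate_relations()`) reports per-class precision, recall and F1
from one-vs-rest confusion tables, accuracy, and macro averages as
unweighted class means; 0/0 ratios are reported as 0 with a warning.

# Hierarchy rollup and spectrum scores

Disease identifiers carry dotted tree numbers; depth is the segment
count (1 = category, 2 = sub-category, 3 = disease; deeper numbers are
truncated to their three-segment ancestor, and scores computed on a
depth-5 ontology provably equal those on its depth-3 truncation). For a
spice *s* and polarity (positive or negative):

* **Spectrum score** `Omega_s = D_hat_s * sum_i(d_hat_si / d_i)` over
  categories *i*; presence is binary at each level, so evidence volume
  never changes a score - only coverage does. Bounds: 0 (no
  associations) to D^2 (full coverage); 729 at D = 27.
* **Relative benevolence** `Delta Omega_s = Omega_s(+) - Omega_s(-)`.
* **Category spectrum** `Omega_si = d_hat_si * sum_k(alpha_hat_sk /
  alpha_k)` over sub-categories *k* of *i*, with `alpha_hat_sk` the
  count of associated level-3 diseases in *k* - the denominator's
  companion count, which the source formula's prose garbles
  (it re-uses the sub-category wording for what must be a disease
  count; the dimensional reading implemented here reproduces the
  `(d_i)^2` bound that parallels the global 729).
* **Tradeoff** `Delta Omega_si` ranks spices for recommendation against
  category *i*; ties break by category benevolence, then spice ID, and
  non-positive tradeoffs are flagged rather than hidden.

Two interpretation decisions, both open in the source description:
an association whose deepest tree number stops at level 1 or 2 counts
toward category/sub-category presence but not level-3 sums; and a pair
carrying both polarities contributes to both spectra, since the two
scores are computed independently. Degenerate structures (a category
with no sub-categories, a sub-category with no diseases) contribute
nothing and are excluded from the presence multiplier, with a log
message.

The intuition the score encodes: a spice associated with half the
diseases in *every* category is broader - and scores higher - than one
associated with all diseases in half the categories:

```{r spectrum-intuition}
cfg <- synthetic_config(seed = 4, n_categories = 4,
                        subcats_per_category = c(2, 2),
                        diseases_per_subcat = c(1, 1))
ont <- generate_ontology(cfg)
leaves <- ont$id[ont$level == 3]
tab <- function(ids) tibble(spice_id = "S", disease_id = ids,
                            polarity = "positive")
c(all_of_half = spectrum_score(tab(leaves[1:4]), ont, "S"),
  half_of_all = spectrum_score(tab(leaves[c(1, 3, 5, 7)]), ont, "S"))
```

# Tripartite explanation

`explain_positive_associations()` joins positive (spice, disease) rows
against spice-compound and compound-disease tables: a row is explained
iff some compound is contained in the spice *and* linked to the same
disease identifier. The join is by normalized ontology ID at level 3,
never by name. Upstream filters are explicit operations:
`filter_bioactive()` (bioactivity flag) and `therapeutic_links()`
(association type `therapeutic`, with `marker`/`inferred` discarded and
unknown types skipped with a warning). Coverage is the explained
fraction over distinct level-3 positive pairs; unexplained rows are
returned as a hypotheses list with each spice's candidate compounds,
because an unexplained association is a research lead, not a failure.

# The synthetic study generator

All pipeline inputs can be generated with planted ground truth
(`synthetic_config()`, `generate_ontology()`, `generate_lexicon()`,
`generate_corpus()`, `generate_phytochem_tables()`,
`simulate_study()`). Defaults are the study conditions the analysis is
modelled on:

| parameter | default | rationale |
|---|---|---|
| `label_priors` | (0.398, 0.045, 0.557) | empirical class frequencies of the 6712-pair annotated corpus (2669 / 301 / 3742) |
| `n_categories` | 27 | the disease-category count under which the 0-729 spectrum bound holds |
| `explainable_fraction` | 0.37 | the reported share of positive associations with phytochemical support |
| `label_noise_rate` | 0 | noiseless by default; noise flips a gold label to a uniformly random different class |
| `n_abstracts` | 200 | desk-scale corpus; 200 abstracts x 3-8 sentences yields roughly a thousand candidate pairs, enough for stable held-out evaluation in seconds |
| `subcats_per_category`, `diseases_per_subcat` | 2-4, 2-5 | small but non-degenerate hierarchy: every score denominator varies across categories |
| `n_spices`, `synonyms_per_spice` | 30, 1-3 | enough species for ambiguity and overlap planting without bloating the corpus |
| `bioactive_fraction` | 0.6 | decoy compounds are a mixed population, so the bioactive filter does real work |

Design points that make the generator a test instrument rather than a
data simulator:

* **Template banks** are fixed string lists shipped as data files, one
  bank per class plus entity-free filler, with disjoint cue
  vocabularies. This bounds realism but gives a known Bayes-optimal
  ceiling of 1.0 - a classifier failing on this corpus is broken, full
  stop. Each bank contains one two-entity template fired at a fixed
  rate independent of the class draw, so pair-level class marginals
  equal the priors exactly while masking still gets exercised.
* **Gold labels** attach per (sentence, spice, disease) pair - the unit
  the classifier sees.
* **Planted traps**: one species' multi-word synonym contains another
  species' single-word synonym as a token (longest-match must win), a
  plural common-name form is planted, and one scientific name carries a
  `var.` qualifier.
* **Planted spectrum profiles** realize a target (category,
  sub-category) coverage per spice by emitting one sentence per covered
  cell; profiled spices appear nowhere else, so recovered spectrum
  scores are exact rational numbers and ranking recovery is an equality
  test, not a tolerance test.
* **Planted explanations** support exactly
  `round(explainable_fraction * n)` positive rows; decoy compounds are
  either non-bioactive or carry only non-therapeutic links, so the
  planted count is exact by construction.
* **Determinism**: every generator runs under its own seed derived from
  `cfg$seed`, so identical configs give byte-identical outputs and the
  XML round-trips through the parser.

What the generator does *not* emulate - and what passing tests
therefore do not show: real biomedical prose (hedging, negation scope,
coordination like "ginger and garlic extracts", abbreviations),
ambiguous or misspelled mentions, cross-sentence relations, citation
metadata beyond the parsed fields, and realistic disease co-occurrence
structure. Perfect synthetic accuracy is a correctness statement about
the pipeline, not a performance claim about MEDLINE.

# Numerical choices and degenerate inputs

* idf uses the natural logarithm; terms present in every sentence get
  weight 0 everywhere.
* SVM cost defaults to 1 and is exposed (`cost`, and a grid in
  `cross_validate()`); features are not re-scaled (`scale = FALSE`)
  since TF-IDF columns are sparse and nonnegative.
* Recommendation ties break deterministically: tradeoff desc, category
  benevolence desc, spice ID.
* Empty association tables score 0; unknown disease IDs in an
  association table are ignored with a warning; unknown override rows
  warn; single-class training data and classes smaller than *k* in
  cross-validation are errors with actionable messages.
* The permuted-label null control in the acceptance suite trains
  without oversampling: rebalancing a rare class of permuted labels
  would measure the rebalancing, not the absence of label signal.

# Problem sizes used by the test suite

The suite validates the tagger against a brute-force scan on 1,000
random sentences, classifier recovery on a ~1,000-instance noiseless
corpus with an 80/20 split (accuracy must exceed the majority baseline
by at least 0.3; a permuted-label control must stay within 0.1 of it),
exact ranking and coverage recovery on planted profiles, and an
end-to-end run on a 200-abstract study. These sizes were chosen so the
full suite completes in about two minutes on one CPU while leaving each
property statistically meaningful.

# Limitations

* Dictionary NER cannot find surface forms it has never seen; recall on
  real text is bounded by dictionary completeness, which is why the
  external-tagger adapter exists.
* The spectrum score is coverage-based by design: one well-replicated
  association and one stray sentence contribute equally. Evidence
  counts are carried in the association table for downstream weighting
  but deliberately do not enter the score.
* Compound identifiers are assumed pre-standardized; no potency, dose
  or direction-of-effect modeling is attempted in the tripartite join.
* Sentence-level classification cannot see cross-sentence or
  document-level assertions.
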