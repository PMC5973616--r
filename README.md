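# spicemine

Culinary spices and herbs are discussed in tens of thousands of biomedical
abstracts, both as therapeutic agents and as triggers of adverse
reactions. `spicemine` implements a complete, tested literature-mining
pipeline for turning such abstracts into quantitative statements about the
health impact of spices:

1. **Ingest** — parse MEDLINE-style PubMed XML into abstract records and
   build a normalized spice dictionary (variety standardization, plural
   expansion, removal of ambiguous common names).
2. **NER** — locate spice and disease mentions with a token-level,
   non-overlapping, longest-match dictionary tagger (an external disease
   tagger can be plugged in through a character-offset adapter).
3. **Candidates** — segment sentences, normalize tokens (numbers become a
   reserved `NUM` token; only `! , . : ;` punctuation is retained), keep
   sentences mentioning at least one spice and one disease, and expand
   each sentence into one masked instance per spice–disease pair.
4. **Classify** — a TF-IDF (unigram + bigram, `tfidf(t,s) = f_ts ·
   log(N/n_t)`) one-vs-all linear SVM labels each pair *positive*,
   *negative* or *no-association*, with class oversampling (factors 12
   and 1.35 for the negative and positive classes) and stratified
   cross-validation; evaluation reports per-class and macro-averaged
   precision, recall and F1.
5. **Score** — classified associations are rolled up a MeSH-like
   three-level disease hierarchy (category / sub-category / disease) and
   summarized per spice *s* by the **spectrum score**

   Ω_s = D̂\_s · Σ_i ( d̂\_si / d_i ),

   where D̂\_s is the number of disease categories the spice is associated
   with, d_i the number of sub-categories of category *i* and d̂\_si the
   number of those associated with the spice. With 27 categories Ω ranges
   from 0 to 729. The **relative benevolence** ΔΩ_s = Ω_s⁺ − Ω_s⁻
   contrasts the benevolence and adverse spectra, and the per-category
   analogue Ω_si = d̂\_si · Σ_k ( α̂\_sk / α_k ) yields a **therapeutic
   tradeoff score** ΔΩ_si used to rank spices for culinary recommendation
   against a disease category.
6. **Explain** — positive associations are linked to bioactive
   phytochemicals carrying therapeutic compound–disease evidence
   (spice → compound → same disease ID), reporting the explanation
   coverage and a hypotheses list for the rest.

A first-class **synthetic-data module** generates every pipeline input —
a three-level disease ontology, a spice lexicon with planted longest-match
and plural traps, a template-based labeled corpus serialized as PubMed
XML, and phytochemical tables with an exactly planted explainable
fraction — so the whole analysis is exercisable with known ground truth
and no downloads.

## Worked example

```r
library(spicemine)
library(dplyr)

cfg <- synthetic_config(seed = 42, n_abstracts = 120, n_spices = 10,
                        n_categories = 8)
sim <- simulate_study(cfg, "demo")          # writes XML + TSV inputs
res <- run_pipeline(sim$corpus$records, sim$lexicon,
                    select(sim$ontology, id, name, tree_number),
                    sim$corpus$truth$labels,
                    phytochem = sim$phytochem, seed = 1)

res$metrics
#> accuracy 1.0000 | macro P 1.0000 R 1.0000 F1 1.0000
```

On this noiseless template corpus the classifier separates the three
classes perfectly (the cue-phrase banks are disjoint by construction, so
the Bayes-optimal ceiling is 1). The spectrum report ranks spices by
relative benevolence:

```r
head(as_tibble(res$spectrum), 5)
#> # A tibble: 5 × 4
#>   spice_id omega_pos omega_neg delta_omega
#>   <chr>        <dbl>     <dbl>       <dbl>
#> 1 TAX01002      52        0.5         51.5
#> 2 TAX01004      51.3      1.17        50.2
#> 3 TAX01008      48.7      1.5         47.2
#> 4 TAX01007      48.7      3.75        44.9
#> 5 TAX01001      45.3      0.5         44.8

glance(res$spectrum)
#> # A tibble: 1 × 5
#>   n_spices n_benevolent prop_benevolent max_delta min_delta
#>      <int>        <int>           <dbl>     <dbl>     <dbl>
#> 1       10           10               1      51.5      22.5
```

Every generated spice here is net-benevolent (`delta_omega > 0`): its
positive associations span more of the hierarchy than its negative ones.
`omega_pos = 52` means that spice's positive associations cover all 8
categories at, on average, 81% of their sub-categories (8 × 6.5). Ranked
recommendations against one disease category, and the phytochemical
explanation of positive associations:

```r
head(recommend_spices(res$tradeoffs, "C01"), 3)
#> # A tibble: 3 × 6
#>    rank spice_id omega_pos omega_neg tradeoff flagged
#>   <int> <chr>        <dbl>     <dbl>    <dbl> <lgl>
#> 1     1 TAX01007      2.13       0.2     1.93 FALSE
#> 2     2 TAX01008      1.47       0.4     1.07 FALSE
#> 3     3 TAX01001      1.07       0       1.07 FALSE

res$explanation
#> <explanation_report: 209 positive associations, 36.8% explained, 132 hypotheses>
```

The generator planted supporting compound paths for 37% of the positive
associations; the pipeline recovers that coverage on the classified
associations (36.8% here, since predictions rather than gold labels feed
the tripartite join). `autoplot(res$spectrum)` draws the benevolence
ranking; `tidy()` / `glance()` methods return tibbles for all result
objects.

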