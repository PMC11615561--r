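# mesheval

Do Medical Subject Headings (MeSH) terms still earn their place in the
PubMed search strategies of systematic reviews? `mesheval` is an R
package for answering that question quantitatively. It takes a
review's mixed boolean query, derives a free-text-only variant (every
`[MeSH Terms]` tag becomes `[Title/Abstract]`) and a MeSH-only variant
(every free-text tag becomes `[MeSH Terms]`, with terms absent from
the thesaurus deleted), runs all three against a corpus, and scores
each arm against the review's gold standard — the articles the review
actually included.

The package is aimed at information specialists and meta-researchers
studying search-strategy performance. It covers the full pipeline:

* **Query machinery** — a parser/serializer for the PubMed boolean
  dialect (field tags, quoted phrases, left-to-right `AND`/`OR`/`NOT`,
  date ranges), an automatic-term-mapping emulation for untagged
  terms, and the V2/V3 rewrites with the 14 check-tag filter terms
  (`humans`, `female`, …) preserved.
* **A MeSH-style vocabulary** — descriptors with entry terms and
  dotted tree numbers, case-insensitive normalization, and explosion
  to narrower descriptors.
* **A local retrieval engine** — MEDLINE flat-file and JSONL corpora,
  tokenized phrase matching over titles/abstracts, heading matching
  with/without explosion and major-topic restriction, date filters,
  a deterministic ranking surrogate and the 10,000-record cap.
* **Evaluation and aggregation** — sensitivity, PPV, F1, reading
  cost, per-review odds ratios with continuity correction, and pooled
  random-effects odds ratios (REML or DerSimonian–Laird, via
  `metafor`).
* **A synthetic world generator** — corpora with controllable
  text-mention and MeSH-indexing probabilities, so the whole pipeline
  is testable offline and the effect of indexing completeness on each
  arm is measurable.

For one review with gold standard GS, an arm retrieving `items`
records of which `TP` are in GS is scored as

    Se = TP / |GS|      PPV = TP / items      F1 = 2·Se·PPV / (Se + PPV)

and two arms are compared through odds ratios, e.g. for sensitivity

    OR = (TP_2 / FN_2) / (TP_1 / FN_1),

with 0.5 added to all four cells of any table containing a zero. Log
odds ratios are pooled across reviews under a random-effects model
with REML between-review variance; by default reviews are weighted
equally (see the vignette for why, and for the inverse-variance
alternative).

The package ships, as `inst/extdata/table1.csv`, the per-review count
table of a published comparative evaluation of 59 systematic-review
search strategies, and reproduces its summary statistics and pooled
odds ratios from those counts.

## Worked example

```r
library(mesheval)

rows <- load_table1()           # 59 reviews: counts per arm + gold sizes
headline_stats(rows)[c("total_items_v1", "total_found_v1",
                       "total_items_v2", "total_found_v2", "n_impacted")]
#> $total_items_v1
#> [1] 206095
#> $total_found_v1
#> [1] 1628
#> $total_items_v2
#> [1] 157698
#> $total_found_v2
#> [1] 1473
#> $n_impacted
#> [1] 24

pool_log_odds_ratios(or_tables(rows, "v2_vs_v1", "sensitivity"))
#> Pooled OR 0.547 (95% CI 0.383-0.780), tau2 = 0.459, k = 59 [REML, equal weights]
pool_log_odds_ratios(or_tables(rows, "v2_vs_v1", "ppv"))
#> Pooled OR 1.257 (95% CI 1.026-1.540), tau2 = 0.050, k = 59 [REML, equal weights]
```

Reading: the mixed queries returned 206,095 records containing 1628
gold articles; the free-text-only rewrites returned 48,397 fewer
records but missed 155 of those articles, and removing MeSH terms
changed the relevant yield for 24 of 59 reviews. Pooled across
reviews, dropping the MeSH terms roughly halves the sensitivity odds
(OR 0.55) while modestly improving the precision odds (OR 1.26): the
thesaurus channel finds articles the free-text channel misses, at the
price of more screening.

The same machinery runs end to end on generated data:

```r
w <- generate_world(synthetic_spec(p_index = 0.7, seed = 1))
v3 <- to_mesh_only(w$v1_query, w$vocab)
score(evaluate_query(w$docs, v3, w$vocab)$pmids, w$gold)[, c("se", "ppv")]
```

and `run_study()` orchestrates parse → rewrite → retrieve → score →
aggregate for a whole collection of reviews from a JSON configuration,
logging every transformation decision (check tags preserved, terms
deleted as non-thesaurus).

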