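---
title: "Quantifying the added value of MeSH terms in search strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the added value of MeSH terms in search strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesheval)
```

## The question and the design

Search strategies for systematic reviews typically mix two retrieval
channels: free-text terms matched against titles and abstracts, and
Medical Subject Headings (MeSH) matched against the descriptors that
human indexers assign to MEDLINE records. The thesaurus buys
vocabulary control — one descriptor per concept, with entry-term
synonyms and hierarchical *explosion* to narrower descriptors — but
indexing lags behind publication and thesaurus updates lag behind new
topics. Whether the MeSH channel still earns its keep is an empirical
question.

`mesheval` implements a three-arm comparison that answers it at the
level of a single review and across a collection of reviews:

* **V1** — the review's original query, as formatted by the search
  engine's automatic term mapping (ATM), mixing both channels;
* **V2** — the same query with every MeSH-tagged term re-tagged
  `[Title/Abstract]`, so only the free-text channel remains;
* **V3** — the same query with every free-text term re-tagged
  `[MeSH Terms]`, so only the thesaurus channel remains.

Fourteen *check tags* (`humans`, `female`, `adult`, …) are exempt from
the V1→V2 rewrite: they act as population/species filters rather than
topic terms, and converting them to free text would change their
meaning (`mesh_filter_terms()` lists them). In the V3 direction, a
re-tagged term that does not exist in the thesaurus is ignored by the
search engine, which is equivalent to deleting it; `to_mesh_only()`
performs that deletion and simplifies the query, so a query whose
every content term misses the thesaurus collapses to the empty query
and returns zero records — a *nonviable* MeSH-only query. Deletion
semantics (the surviving siblings of an `AND` carry on) is the
default because it mirrors engine behaviour; strict empty-set
propagation is available behind `empty_set = TRUE` for sensitivity
analysis. We also apply the check-tag exemption only in the V1→V2
direction: in the V3 direction every free-text term, check tag or
not, is re-tagged, because a check tag appearing as free text was
functioning as a topic term there.

Each arm is scored against the review's **gold standard** — the set of
MEDLINE-indexed articles its authors actually included — giving
sensitivity (recall) `Se = TP/|GS|`, positive predictive value
(precision) `PPV = TP/items`, their harmonic mean F1, and the *reading
cost* `items/TP`, the number of records screened per relevant article
found.

## Comparing arms: odds ratios and pooling

For one review, the odds of version *i* for sensitivity are
`TP_i/FN_i` and for PPV `TP_i/FP_i`; the comparison of two versions is
the ratio of those odds. Zero cells get the standard continuity
treatment — 0.5 added to all four cells of any table containing a zero
(`correction = "if_any_zero"`, the common default of meta-analysis
software; `"always"` and `"none"` are selectable).

Across reviews, log odds ratios are pooled under a random-effects
model (`pool_log_odds_ratios()`, fitted by `metafor::rma`), with the
between-review variance estimated by REML (DerSimonian–Laird
selectable) and a Wald 95% interval. Two weighting conventions are
exposed:

* `weights = "equal"` (default): every review counts the same; the
  pooled log OR is the plain mean of the per-review log ORs, with the
  random-effects variance entering the interval. This is the
  convention under which the pooled estimates *and* interval bounds of
  the published evaluation shipped with the package reproduce to all
  printed decimals (0.547 ≈ 0.55 and 1.257 ≈ 1.26, with matching CIs).
* `weights = "inverse_variance"`: the textbook `1/(v_i + τ²)`
  weighting. On the shipped table it gives 0.68 for the sensitivity
  contrast — reviews with tiny gold standards carry enormous log-OR
  variances and are shrunk — which is a defensible analysis but not
  the one whose results the fixture reproduces.

Both estimators and both weightings are one argument away; the
package takes no position beyond making the default reproduce the
shipped reference analysis.

## The shipped count table and its conventions

`load_table1()` returns the per-review counts of a published
comparative evaluation of 59 systematic-review search strategies
(items returned and gold items found per arm, plus the published
3-decimal metrics). Reproducing its summary statistics pinned down
three conventions, now defaults:

* **Summaries of proportions** (`summarize_versions()`) are computed
  from the published *rounded* 3-decimal per-row metrics, not from raw
  counts — that is how the published summary table was evidently
  produced (several F1 quartiles only reproduce this way). Quantiles
  are the linear-interpolation order statistics (`quantile(type = 7)`);
  `metrics_from = "counts"` switches to raw counts.
* **Reading cost** keeps `items/0 = Inf` rows *inside* the quantiles
  (a query that found nothing relevant has infinite cost, which
  rightly pushes the upper quantiles) but drops the degenerate `0/0`
  rows of nonviable queries. All nine published reading-cost cells
  reproduce exactly under this rule and under no other we examined.
* **Found-ratio conventions** (`gs_ratio()`): `0/0` counts as 1,
  `x/0` as `+Inf`, matching the published distribution's caption.

`verify_table1()` recomputes every metric cell from its counts. On the
shipped table it flags 8 of 531 cells, confined to two rows (32479176,
31727627) whose published metrics are internally inconsistent with
their own published counts — no assignment of counts reconciles them,
since the column totals pin the counts. The fixture ships the values
as printed; the discrepancy report is the honest summary of that
disagreement, and the regression test over all cells is expected to
flag exactly those two rows.

One published headline number is likewise not reachable by standard
rounding: the mean extra relevant articles per review is
`155/59 = 2.6271`, printed as 2.62 (truncated; it rounds to 2.63), and
the printed screening cost 313.09 is `820.29/2.62` with that truncated
value. `headline_stats()` reports conventionally rounded values.

## The local retrieval engine

`evaluate_query()` stands in for the search engine at desk scale, with
documented divergences:

* Tokenization is case-folding on non-alphanumeric boundaries; phrases
  must appear as contiguous token runs. No stemming and no
  British/American normalization — conservative and reproducible.
* `[MeSH Terms]` explodes to narrower descriptors via tree-number
  prefixes; `[Mesh:NoExp]` does not; `[Majr]` additionally requires
  the major-topic flag. Explosion follows tree numbers only (a
  descriptor reached through one hierarchy does not drag in narrower
  terms it has only in another hierarchy).
* `[All Fields]` is title/abstract ∪ MeSH ∪ journal; real engines also
  search author and affiliation fields, which the record schema omits.
* Relevance ranking is irreproducible ("Best Match" is proprietary),
  so the engine orders results by number of distinct query terms
  matched, then PMID — a deterministic surrogate that only matters
  when the 10,000-record extraction cap truncates a result list. Gold
  items are then counted within the retained list only, deliberately
  replicating the extraction constraint the reference evaluation
  worked under.
* Publication-date windows compare calendar dates; a year or
  year/month bound widens to the first day on the start side and the
  last day on the end side; records with unparseable dates fail every
  date filter.

Correctness of the boolean semantics is established against an
independent oracle — per-document recursive truth evaluation — on
hundreds of random corpus/query pairs, alongside monotonicity
(adding an `OR` branch never shrinks a result set, an `AND` branch
never grows it) and metamorphic checks (free-text results are blind
to heading perturbations; MeSH-only results are blind to text
perturbations).

## The synthetic world generator

No corpus accompanies the shipped count table, so
`generate_world()` builds one in which the two retrieval channels can
be manipulated independently. Concepts live in a small tree; the
target concept is an internal node with narrower descendants, and
distractor concepts sit outside its subtree. Each gold document
surfaces each target synonym in its text with probability `p_text`,
and is indexed with probability `p_index` — **indexing completeness**,
the generator's stand-in for indexing lag (an unindexed record is
exactly what a not-yet-indexed record looks like to a MeSH search).
With probability `p_broader` an indexed record carries a *narrower*
(child) descriptor instead of the exact one, which is what gives
thesaurus explosion something to do: search the target, find the
child-indexed records. Distractors occasionally mention a target
synonym (`p_distractor_text`), creating text false positives; without
them PPV would degenerate at 1 in the text arms.

The generated mixed query is
`OR(target[MeSH Terms], target[tiab], synonym1[tiab], …)`, optionally
AND-ed with a `humans[MeSH Terms]` check-tag clause. Because its V2
and V3 rewrites search subsets of the same clauses, the mixed arm's
result set provably contains both rewrites' result sets — the
union-dominance property that mirrors the headline finding (mixed
queries are the most sensitive and never more precise). The defaults
(200 documents, 30 gold, 8 concepts, `p_text = 0.9`,
`p_index = 0.7`, `p_broader = 0.2`, `p_distractor_text = 0.05`)
describe a realistic single-topic literature: most relevant papers
name the concept in the abstract, most records are indexed, a
minority are indexed at finer granularity. `sweep_indexing()` varies
`p_index` over a grid with replicate-coupled seeds, so the
monotone response of MeSH-only sensitivity to indexing completeness
is visible through the Monte-Carlo noise.

What the generator does **not** emulate: natural language (synonyms
are inserted as whole phrases into template sentences, so phrase
matching is exact by construction), ATM translation tables, qualifier
(subheading) indexing, and correlated indexing errors. Passing tests
on synthetic worlds therefore certify the machinery — parsing,
rewriting, retrieval, scoring, aggregation — not the linguistic
behaviour of real abstracts.

## Worked example

```{r}
rows <- load_table1()
headline_stats(rows)[c("total_items_v1", "total_found_v1", "n_impacted",
                       "n_v3_zero_items")]

pool_log_odds_ratios(or_tables(rows, "v2_vs_v1", "sensitivity"))
pool_log_odds_ratios(or_tables(rows, "v2_vs_v1", "ppv"))
```

Dropping the MeSH terms costs sensitivity (pooled OR well below 1)
and buys a little precision (pooled OR modestly above 1): the
thesaurus channel still earns its keep for exhaustive reviews, at a
screening price the headline statistics quantify.

```{r}
w <- generate_world(synthetic_spec(seed = 1))
res <- lapply(list(v1 = w$v1_query,
                   v2 = to_free_text(w$v1_query),
                   v3 = to_mesh_only(w$v1_query, w$vocab)),
              function(q) {
                r <- evaluate_query(w$docs, q, w$vocab)
                score(r$pmids, w$gold)[, c("items", "gs_found", "se", "ppv")]
              })
do.call(rbind, res)
```

## Problem sizes, determinism and limitations

The test suite exercises the retrieval oracle on 500 random corpora of
up to 50 documents with query trees up to depth 3, 500 parse/serialize
round trips, and an indexing sweep of 3 grid points × 20 replicates of
200-document worlds — sizes at which every property is checked exactly
or with comfortable Monte-Carlo margins while the whole suite stays
fast. All randomness flows through explicit seeds
(`withr::with_seed`); a spec is a pure function from seed to world.

Known limitations: the V3-vs-V1 pooled odds ratios published in the
reference evaluation's supplement are not reproduced by any
convention we examined (its sensitivity contrast in particular), so
the package makes no claim about them; qualifiers, supplementary
concept records, proximity operators, truncation and multi-part query
history syntax are out of scope; and journal matching is by full
title, not abbreviation tables.
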