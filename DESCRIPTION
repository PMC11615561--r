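Package: mesheval
Title: Evaluating the Added Value of MeSH Terms in Systematic-Review Search Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying what Medical Subject Headings (MeSH) terms
    contribute to PubMed search strategies for systematic reviews. Parses
    PubMed boolean queries into an expression tree, rewrites a mixed query
    into free-text-only and MeSH-only variants, executes queries against a
    local MEDLINE-like corpus with thesaurus explosion, scores result lists
    against a gold standard (sensitivity, positive predictive value, F1,
    odds ratios, reading cost), and aggregates across reviews with medians,
    interquartile ranges, and random-effects pooled odds ratios. Ships the
    per-review count table of a published comparative evaluation of 59
    systematic-review search strategies as a fixture, and includes a
    synthetic corpus generator with controllable MeSH-indexing completeness
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    metafor,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
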