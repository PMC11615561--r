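# Local boolean retrieval over a corpus: a desk-scale stand-in for the
# PubMed engine with documented divergences (no author/affiliation fields
# behind [All Fields]; journal matching by full-title equality; a
# deterministic surrogate for "Best Match" ranking).

# Tokenization: case-fold, split on non-alphanumerics. No stemming, no
# spelling normalization — reproducible and conservative.
tokenize_text <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# contiguous token-subsequence match (phrases must appear whole)
.tokens_contain <- function(haystack, needle) {
  nh <- length(haystack); nn <- length(needle)
  if (nn == 0L || nh < nn) return(FALSE)
  for (i in seq_len(nh - nn + 1L)) {
    if (all(haystack[i:(i + nn - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

#' Match a single term node against one document
#'
#' Field semantics: `TITLE_ABSTRACT` is a case-insensitive contiguous
#' token-sequence match in title or abstract (`TITLE`: title only;
#' `TEXT_WORD` is treated like `TITLE_ABSTRACT`); `MESH` resolves the term
#' to a descriptor and tests whether any document heading normalizes into
#' its exploded subtree (`MESH_NOEXP`: the descriptor itself;
#' `MESH_MAJOR`: exploded, and the heading must be flagged major); a MeSH
#' term absent from the thesaurus matches nothing; `ALL_FIELDS` is the
#' disjunction of the title/abstract, MeSH and journal matches; `JOURNAL`
#' is case-insensitive equality with the journal title; `FILTER` and
#' `PUBLICATION_TYPE` test membership in the record's filter set.
#'
#' @param doc One-row `corpus` slice (a document record).
#' @param node A `pm_term`.
#' @param vocab A `mesh_vocabulary`.
#' @return Logical.
#' @export
match_term <- function(doc, node, vocab) {
  stopifnot(inherits(node, "pm_term"))
  .term_match_vector(doc, node, vocab)[1]
}

# precompute what a term needs once per (term, vocabulary): its token
# sequence and, for thesaurus tags, the accepted descriptor set
.term_plan <- function(node, vocab) {
  plan <- list(tag = node$tag, needle = tokenize_text(node$text),
               text = tolower(trimws(node$text)), accept = character(0))
  if (node$tag %in% c(.mesh_tags, "ALL_FIELDS")) {
    d <- normalize_term(vocab, node$text)
    if (!is.na(d))
      plan$accept <- if (node$tag == "MESH_NOEXP") d else mesh_explode(vocab, d)
  }
  plan
}

.match_with_plan <- function(plan, title_tokens, abstract_tokens, journal,
                             headings, filters, vocab) {
  tiab <- function() .tokens_contain(title_tokens, plan$needle) ||
    .tokens_contain(abstract_tokens, plan$needle)
  mesh <- function(major_only) {
    if (length(plan$accept) == 0L || nrow(headings) == 0L) return(FALSE)
    for (j in seq_len(nrow(headings))) {
      hd <- normalize_term(vocab, headings$term[[j]])
      if (is.na(hd) || !hd %in% plan$accept) next
      if (!major_only || headings$major[[j]]) return(TRUE)
    }
    FALSE
  }
  journal_eq <- function() identical(tolower(trimws(journal)), plan$text)
  switch(plan$tag,
    TITLE_ABSTRACT = tiab(),
    TEXT_WORD = tiab(),
    TITLE = .tokens_contain(title_tokens, plan$needle),
    MESH = mesh(FALSE),
    MESH_NOEXP = mesh(FALSE),
    MESH_MAJOR = mesh(TRUE),
    ALL_FIELDS = tiab() || mesh(FALSE) || journal_eq(),
    JOURNAL = journal_eq(),
    FILTER = plan$text %in% tolower(filters),
    PUBLICATION_TYPE = plan$text %in% tolower(filters),
    FALSE)
}

# logical match vector over the whole corpus for one term node;
# title_tokens/abstract_tokens may be passed in to reuse tokenization
.term_match_vector <- function(docs, node, vocab,
                               title_tokens = NULL, abstract_tokens = NULL) {
  plan <- .term_plan(node, vocab)
  if (is.null(title_tokens)) title_tokens <- lapply(docs$title, tokenize_text)
  if (is.null(abstract_tokens)) abstract_tokens <- lapply(docs$abstract, tokenize_text)
  vapply(seq_len(nrow(docs)), function(i) {
    .match_with_plan(plan, title_tokens[[i]], abstract_tokens[[i]],
                     docs$journal[[i]], docs$mesh_headings[[i]],
                     docs$filters[[i]], vocab)
  }, logical(1))
}

#' Evaluate a query tree against a corpus
#'
#' Set semantics: a term selects its matching documents, `AND` intersects,
#' `OR` unites, `NOT` is the left-minus-right difference, `DATE_RANGE`
#' selects documents whose publication date falls inside the window
#' (records with a sentinel date fail every date filter), and `EMPTY`
#' selects nothing. The result is ordered by a deterministic surrogate for
#' relevance ranking — number of distinct term leaves matched, descending,
#' then PMID ascending — and truncated to `cap` (the engine's extraction
#' limit of 10,000 records).
#'
#' @param docs A `corpus`.
#' @param expr A simplified `pm_query`.
#' @param vocab A `mesh_vocabulary`.
#' @param cap Maximum number of PMIDs retained (default 10000).
#' @return A `retrieval_result`: list with `pmids` (ordered, truncated),
#'   `total_matched` and `capped`.
#' @export
evaluate_query <- function(docs, expr, vocab, cap = 10000L) {
  stopifnot(inherits(docs, "corpus"), inherits(expr, "pm_query"),
            inherits(vocab, "mesh_vocabulary"), cap >= 1)
  n <- nrow(docs)
  tt <- lapply(docs$title, tokenize_text)
  at <- lapply(docs$abstract, tokenize_text)
  leaf_hits <- list()  # per-term match vectors, kept for the ranking
  sel <- function(node) {
    switch(node$kind,
      term = {
        v <- .term_match_vector(docs, node, vocab, tt, at)
        leaf_hits[[length(leaf_hits) + 1L]] <<- v
        v
      },
      bool = {
        kids <- lapply(node$children, sel)
        if (node$op == "AND") Reduce(`&`, kids)
        else if (node$op == "OR") Reduce(`|`, kids)
        else kids[[1]] & !kids[[2]]
      },
      date_range = !is.na(docs$pub_date) &
        docs$pub_date >= node$start & docs$pub_date <= node$end,
      rep(FALSE, n))
  }
  hit <- if (n == 0L) logical(0) else sel(expr)
  total <- sum(hit)
  idx <- which(hit)
  if (length(idx)) {
    n_leaves <- if (length(leaf_hits))
      Reduce(`+`, lapply(leaf_hits, as.integer))[idx] else rep(0L, length(idx))
    ord <- order(-n_leaves, docs$pmid[idx])
    idx <- idx[ord]
  }
  pmids <- docs$pmid[idx]
  capped <- total > cap
  if (capped) pmids <- pmids[seq_len(cap)]
  structure(list(pmids = pmids, total_matched = total, capped = capped),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat("<retrieval_result>", x$total_matched, "matched",
      if (x$capped) paste0("(capped to ", length(x$pmids), ")"), "\n")
  invisible(x)
}
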