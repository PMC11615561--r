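#' Rewrite a mixed query to free text only
#'
#' Every term tagged into the thesaurus (`MESH`, `MESH_NOEXP`,
#' `MESH_MAJOR`) is re-tagged `TITLE_ABSTRACT`, except the 14 check-tag
#' filter terms ([mesh_filter_terms()]), which keep their MeSH tag so they
#' can still act as population/species filters. Journal, filter, date and
#' publication-type nodes, and the tree shape, are unchanged. Idempotent.
#'
#' @param expr A parsed `pm_query` (the mixed, ATM-resolved original).
#' @return The free-text-only variant.
#' @export
to_free_text <- function(expr) {
  stopifnot(inherits(expr, "pm_query"))
  map_terms(expr, function(t) {
    if (t$tag %in% .mesh_tags && !is_filter_term(t$text))
      pm_term(t$text, "TITLE_ABSTRACT", quoted = t$quoted)
    else t
  })
}

#' Rewrite a mixed query to MeSH only
#'
#' Free-text terms (`TITLE_ABSTRACT`, `TITLE`, `TEXT_WORD`, `ALL_FIELDS`)
#' are re-tagged `MESH`; then every MeSH-tagged term that does not resolve
#' in the vocabulary is deleted, because the search engine ignores headings
#' absent from the thesaurus — equivalent to deleting the terms. The tree is
#' simplified afterwards; a query whose every content term misses the
#' thesaurus collapses to `EMPTY` (a nonviable query returning zero items).
#' Journal, filter, date and publication-type nodes are unchanged.
#'
#' The deleted and kept term texts are attached as attributes
#' `"deleted_terms"` and `"kept_terms"` for logging.
#'
#' @param expr A parsed `pm_query`.
#' @param vocab A `mesh_vocabulary`.
#' @param empty_set If `TRUE`, a deleted term behaves as the empty set
#'   (an `AND` containing it collapses to `EMPTY`) instead of being removed
#'   from its clause; off by default, matching engine behaviour.
#' @return The MeSH-only variant, simplified.
#' @export
to_mesh_only <- function(expr, vocab, empty_set = FALSE) {
  stopifnot(inherits(expr, "pm_query"), inherits(vocab, "mesh_vocabulary"))
  deleted <- character(0)
  kept <- character(0)
  out <- map_terms(expr, function(t) {
    if (t$tag %in% .free_text_tags)
      t <- pm_term(t$text, "MESH", quoted = t$quoted)
    if (t$tag %in% .mesh_tags) {
      if (is.na(normalize_term(vocab, t$text))) {
        deleted <<- c(deleted, t$text)
        return(pm_empty())
      }
      kept <<- c(kept, t$text)
    }
    t
  })
  out <- simplify_query(out, empty_set = empty_set)
  attr(out, "deleted_terms") <- deleted
  attr(out, "kept_terms") <- kept
  out
}

#' Simplify a query tree after term deletion
#'
#' Removes `EMPTY` children from boolean nodes (deletion semantics: under
#' `AND` as well as `OR`, the surviving siblings carry on), collapses
#' single-child booleans, and applies the set identities for difference:
#' `NOT(x, EMPTY) = x` and `NOT(EMPTY, x) = EMPTY`. A boolean node left with
#' no children becomes `EMPTY`. Idempotent.
#'
#' @param expr A `pm_query`.
#' @param empty_set If `TRUE`, an `EMPTY` child of an `AND` node collapses
#'   the whole conjunction to `EMPTY` (strict set semantics) instead of
#'   being dropped.
#' @return The simplified tree.
#' @export
simplify_query <- function(expr, empty_set = FALSE) {
  stopifnot(inherits(expr, "pm_query"))
  simp <- function(node) {
    if (node$kind != "bool") return(node)
    kids <- lapply(node$children, simp)
    if (node$op == "NOT") {
      l <- kids[[1]]; r <- kids[[2]]
      if (is_empty_query(l)) return(pm_empty())
      if (is_empty_query(r)) return(l)
      return(pm_bool("NOT", list(l, r)))
    }
    empties <- vapply(kids, is_empty_query, logical(1))
    if (empty_set && node$op == "AND" && any(empties)) return(pm_empty())
    kids <- kids[!empties]
    if (length(kids) == 0L) return(pm_empty())
    if (length(kids) == 1L) return(kids[[1]])
    pm_bool(node$op, kids)
  }
  simp(expr)
}
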