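#' Emulate PubMed's automatic term mapping
#'
#' PubMed expands a bare, untagged term into a clause that searches both the
#' thesaurus and all fields. This emulation is deliberately minimal: each
#' untagged term becomes `OR(term[MeSH Terms], term[All Fields])` when the
#' term resolves in the vocabulary, and `term[All Fields]` alone when it
#' does not. Tagged terms pass through unchanged, so the operation is
#' idempotent and its output carries no untagged flags.
#'
#' @param expr A parsed `pm_query`.
#' @param vocab A `mesh_vocabulary` used to decide whether a MeSH branch
#'   applies.
#' @return The expanded tree.
#' @export
atm_expand <- function(expr, vocab) {
  stopifnot(inherits(expr, "pm_query"), inherits(vocab, "mesh_vocabulary"))
  map_terms(expr, function(t) {
    if (!t$untagged) return(t)
    all_fields <- pm_term(t$text, "ALL_FIELDS", quoted = t$quoted)
    if (is.na(normalize_term(vocab, t$text))) return(all_fields)
    pm_bool("OR", list(pm_term(t$text, "MESH", quoted = t$quoted), all_fields))
  })
}
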