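#' @title PubMed query expression trees
#' @description
#' A PubMed search string is represented as a tree of nodes: `TERM` leaves
#' (a term with a field tag), `BOOL` nodes (`AND`/`OR` with two or more
#' children, `NOT` with exactly two, read as left-minus-right set
#' difference), `DATE_RANGE` nodes (a publication-date window), and `EMPTY`
#' (matches nothing; the result of deleting every term from a branch).
#' Constructors build canonical nodes so that structurally equal queries
#' compare equal with [identical()].
#' @name query_ast
NULL

# Field tag classes and their accepted spellings (case-insensitive).
# Each surface spelling maps to exactly one class; serialization uses one
# canonical spelling per class.
.tag_spellings <- c(
  "mesh terms" = "MESH", "mesh" = "MESH", "mh" = "MESH",
  "mesh:noexp" = "MESH_NOEXP", "mh:noexp" = "MESH_NOEXP",
  "majr" = "MESH_MAJOR", "mesh major topic" = "MESH_MAJOR",
  "title/abstract" = "TITLE_ABSTRACT", "tiab" = "TITLE_ABSTRACT",
  "title" = "TITLE", "ti" = "TITLE",
  "text word" = "TEXT_WORD", "tw" = "TEXT_WORD",
  "all fields" = "ALL_FIELDS", "all" = "ALL_FIELDS",
  "journal" = "JOURNAL", "ta" = "JOURNAL",
  "filter" = "FILTER", "sb" = "FILTER",
  "publication type" = "PUBLICATION_TYPE", "pt" = "PUBLICATION_TYPE",
  "date - publication" = "DATE_PUBLICATION", "dp" = "DATE_PUBLICATION"
)

.tag_canonical <- c(
  MESH = "MeSH Terms", MESH_NOEXP = "Mesh:NoExp", MESH_MAJOR = "Majr",
  TITLE_ABSTRACT = "Title/Abstract", TITLE = "Title",
  TEXT_WORD = "Text Word", ALL_FIELDS = "All Fields",
  JOURNAL = "Journal", FILTER = "Filter",
  PUBLICATION_TYPE = "Publication Type", DATE_PUBLICATION = "Date - Publication"
)

#' Field tag classes
#'
#' @return Character vector of the tag classes understood by the parser.
#' @export
field_tags <- function() unname(unique(.tag_spellings))

# tag classes whose terms address the MeSH thesaurus
.mesh_tags <- c("MESH", "MESH_NOEXP", "MESH_MAJOR")
# tag classes whose terms are free text
.free_text_tags <- c("TITLE_ABSTRACT", "TITLE", "TEXT_WORD", "ALL_FIELDS")

#' Resolve a bracketed tag spelling to its tag class
#'
#' @param spelling Tag text without brackets, e.g. `"MeSH Terms"` or `"tiab"`.
#' @return The tag class (see [field_tags()]).
#' @export
resolve_tag <- function(spelling) {
  key <- tolower(trimws(spelling))
  if (!key %in% names(.tag_spellings)) {
    stop("unknown field tag '[", spelling, "]'; known tags: ",
         paste0("[", names(.tag_spellings), "]", collapse = " "),
         call. = FALSE)
  }
  unname(.tag_spellings[[key]])
}

#' @rdname query_ast
#' @param text Term text. Case is preserved for display; matching downstream
#'   is case-insensitive.
#' @param tag A tag class from [field_tags()].
#' @param quoted Was the term written as a quoted phrase?
#' @param untagged `TRUE` for a bare term that carried no bracketed tag in
#'   the source string (eligible for automatic term mapping).
#' @export
pm_term <- function(text, tag = "ALL_FIELDS", quoted = FALSE, untagged = FALSE) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  if (!tag %in% names(.tag_canonical)) stop("unknown tag class: ", tag)
  structure(
    list(kind = "term", text = text, tag = tag,
         quoted = isTRUE(quoted), untagged = isTRUE(untagged)),
    class = c("pm_term", "pm_query"))
}

#' @rdname query_ast
#' @param op One of `"AND"`, `"OR"`, `"NOT"`.
#' @param children List of child queries; at least two for `AND`/`OR`,
#'   exactly two for `NOT`.
#' @export
pm_bool <- function(op, children) {
  op <- toupper(op)
  stopifnot(op %in% c("AND", "OR", "NOT"), is.list(children))
  if (op == "NOT" && length(children) != 2L)
    stop("NOT takes exactly two operands (left minus right)")
  if (op != "NOT" && length(children) < 2L)
    stop(op, " needs at least two children")
  if (!all(vapply(children, inherits, logical(1), "pm_query")))
    stop("all children must be pm_query nodes")
  structure(list(kind = "bool", op = op, children = children),
            class = c("pm_bool", "pm_query"))
}

#' @rdname query_ast
#' @param start,end Calendar dates (`Date` or `"YYYY/MM/DD"` strings)
#'   bounding the publication window, inclusive.
#' @export
pm_date_range <- function(start, end) {
  start <- as.Date(start, tryFormats = c("%Y/%m/%d", "%Y-%m-%d"))
  end <- as.Date(end, tryFormats = c("%Y/%m/%d", "%Y-%m-%d"))
  stopifnot(!is.na(start), !is.na(end))
  if (start > end) stop("date range start is after its end")
  structure(list(kind = "date_range", start = start, end = end),
            class = c("pm_date_range", "pm_query"))
}

#' @rdname query_ast
#' @export
pm_empty <- function() {
  structure(list(kind = "empty"), class = c("pm_empty", "pm_query"))
}

is_empty_query <- function(x) inherits(x, "pm_empty")

#' Count TERM leaves in a query tree
#'
#' `DATE_RANGE` and `EMPTY` nodes contribute nothing; this counts search
#' terms, optionally restricted to one tag class.
#'
#' @param expr A `pm_query`.
#' @param tag A tag class from [field_tags()], or `NULL` for all terms.
#' @return Non-negative integer.
#' @export
count_terms <- function(expr, tag = NULL) {
  stopifnot(inherits(expr, "pm_query"))
  if (!is.null(tag) && !identical(tag, "ANY") && !tag %in% names(.tag_canonical))
    stop("unknown tag class: ", tag)
  n_of <- function(node) {
    switch(node$kind,
      term = if (is.null(tag) || identical(tag, "ANY") || node$tag == tag) 1L else 0L,
      bool = sum(vapply(node$children, n_of, integer(1))),
      0L)
  }
  n_of(expr)
}

#' Walk a query tree, rewriting TERM leaves
#'
#' Applies `f` to every `TERM` node and rebuilds the tree; all other node
#' kinds pass through unchanged. `f` may return any `pm_query` node
#' (including [pm_empty()] to delete the term).
#'
#' @param expr A `pm_query`.
#' @param f Function of one `pm_term`, returning a `pm_query`.
#' @return The rewritten tree (not simplified; see [simplify_query()]).
#' @export
map_terms <- function(expr, f) {
  stopifnot(inherits(expr, "pm_query"))
  switch(expr$kind,
    term = f(expr),
    bool = pm_bool(expr$op, lapply(expr$children, map_terms, f = f)),
    expr)
}

#' Convert a query tree to plain lists (for JSON output)
#'
#' @param expr A `pm_query`.
#' @return Nested named lists mirroring the tree.
#' @export
query_to_list <- function(expr) {
  switch(expr$kind,
    term = list(kind = "term", text = expr$text, tag = expr$tag,
                quoted = expr$quoted, untagged = expr$untagged),
    bool = list(kind = "bool", op = expr$op,
                children = lapply(expr$children, query_to_list)),
    date_range = list(kind = "date_range",
                      start = format(expr$start), end = format(expr$end)),
    list(kind = "empty"))
}

#' @export
print.pm_query <- function(x, ...) {
  cat(format_query_tree(x), sep = "\n")
  invisible(x)
}

format_query_tree <- function(x, indent = 0L) {
  pad <- strrep("  ", indent)
  switch(x$kind,
    term = paste0(pad, "TERM ", if (x$quoted) dQuote(x$text, '"') else x$text,
                  " [", x$tag, if (x$untagged) ", untagged" else "", "]"),
    bool = c(paste0(pad, x$op),
             unlist(lapply(x$children, format_query_tree, indent = indent + 1L))),
    date_range = paste0(pad, "DATE ", format(x$start), "..", format(x$end)),
    paste0(pad, "EMPTY"))
}
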