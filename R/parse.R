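# Tokenizer and recursive-descent parser for the PubMed search dialect used
# by systematic-review strategies: quoted phrases, bracketed field tags,
# AND/OR/NOT processed left to right with equal precedence (PubMed
# semantics), parentheses overriding, and colon-separated publication-date
# ranges. Proximity operators, truncation and history (#1 AND #2) syntax are
# out of scope.

.tokenize_query <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value, pos) toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (ch == '"') {
      j <- i + 1L
      while (j <= n && chars[j] != '"') j <- j + 1L
      if (j > n) stop("unbalanced quote opened at position ", i, call. = FALSE)
      push("quoted", paste(chars[(i + 1L):(j - 1L)][seq_len(max(0L, j - i - 1L))], collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket opened at position ", i, call. = FALSE)
      push("tag", paste(chars[(i + 1L):(j - 1L)][seq_len(max(0L, j - i - 1L))], collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch == "]") stop("unmatched ']' at position ", i, call. = FALSE)
    j <- i
    while (j <= n && !grepl('[][()"[:space:]]', chars[j])) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    if (toupper(word) %in% c("AND", "OR", "NOT")) push("op", toupper(word), i)
    else push("word", word, i)
    i <- j
  }
  toks
}

#' Parse a PubMed search string into a query tree
#'
#' Boolean operators are case-insensitive and are applied left to right with
#' equal precedence, as PubMed does; parentheses override. `NOT` is the
#' binary set difference (left minus right). A bracketed tag attaches to the
#' immediately preceding term or quoted phrase; consecutive bare words form
#' a single multi-word term. Bare terms without a tag are assigned the
#' `ALL_FIELDS` class and flagged as untagged (see [atm_expand()]). A
#' colon-separated date pair tagged `[Date - Publication]` becomes a
#' `DATE_RANGE` node; a year or year/month resolves to the first day on the
#' start side and the last day on the end side.
#'
#' @param text A non-empty PubMed search string (newlines are treated as
#'   spaces).
#' @return A `pm_query` tree.
#' @examples
#' parse_query('"JAMA"[Journal] AND systematic review[Filter]')
#' @seealso [serialize_query()], [count_terms()]
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty query string", call. = FALSE)
  toks <- .tokenize_query(text)
  if (length(toks) == 0L) stop("empty query string", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_not_end <- function(what) {
    if (pos > length(toks)) stop("unexpected end of query, expected ", what, call. = FALSE)
  }

  parse_expr <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "op" && t$value == "NOT")
      stop("unary NOT at position ", t$pos,
           ": NOT is binary (left operand minus right operand)", call. = FALSE)
    left <- parse_atom()
    from_chain <- FALSE
    repeat {
      t <- peek()
      if (is.null(t) || t$type != "op") break
      op <- advance()$value
      expect_not_end(paste("operand after", op))
      right <- parse_atom()
      if (op == "NOT") {
        left <- pm_bool("NOT", list(left, right))
        from_chain <- FALSE
      } else if (from_chain && inherits(left, "pm_bool") && left$op == op) {
        left <- pm_bool(op, c(left$children, list(right)))
        from_chain <- TRUE
      } else {
        left <- pm_bool(op, list(left, right))
        from_chain <- TRUE
      }
    }
    left
  }

  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of query", call. = FALSE)
    if (t$type == "lparen") {
      open <- advance()
      inner <- parse_expr()
      t2 <- peek()
      if (is.null(t2) || t2$type != "rparen")
        stop("unbalanced parenthesis opened at position ", open$pos, call. = FALSE)
      advance()
      return(inner)
    }
    if (t$type == "rparen")
      stop("unmatched ')' at position ", t$pos, call. = FALSE)
    if (t$type == "tag")
      stop("field tag at position ", t$pos, " has no preceding term", call. = FALSE)
    parse_term()
  }

  parse_term <- function() {
    t <- advance()
    if (t$type == "quoted") {
      text <- t$value
      quoted <- TRUE
    } else {
      words <- t$value
      while (!is.null(peek()) && peek()$type == "word")
        words <- c(words, advance()$value)
      text <- paste(words, collapse = " ")
      quoted <- FALSE
    }
    if (!nzchar(text)) stop("empty term at position ", t$pos, call. = FALSE)
    nxt <- peek()
    if (!is.null(nxt) && nxt$type == "tag") {
      tag <- resolve_tag(advance()$value)
      if (tag == "DATE_PUBLICATION") return(.date_term_to_range(text, t$pos))
      return(pm_term(text, tag, quoted = quoted))
    }
    pm_term(text, "ALL_FIELDS", quoted = quoted, untagged = TRUE)
  }

  out <- parse_expr()
  t <- peek()
  if (!is.null(t))
    stop("unexpected '", t$value, "' at position ", t$pos, call. = FALSE)
  out
}

# "2012/01/01:2021/12/31" -> DATE_RANGE; partial dates widen to the period:
# a bare year or year/month resolves to its first day as a start bound and
# its last day as an end bound.
.date_term_to_range <- function(text, pos) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% 1:2)
    stop("cannot read publication date '", text, "' at position ", pos, call. = FALSE)
  lo <- .resolve_partial_date(parts[1], side = "start", pos = pos)
  hi <- .resolve_partial_date(parts[length(parts)], side = "end", pos = pos)
  pm_date_range(lo, hi)
}

.resolve_partial_date <- function(s, side, pos) {
  s <- trimws(s)
  bits <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (!length(bits) %in% 1:3 || anyNA(suppressWarnings(as.integer(bits))))
    stop("cannot read publication date '", s, "' at position ", pos, call. = FALSE)
  y <- as.integer(bits[1])
  m <- if (length(bits) >= 2) as.integer(bits[2]) else if (side == "start") 1L else 12L
  if (length(bits) == 3) {
    d <- as.integer(bits[3])
  } else if (side == "start") {
    d <- 1L
  } else {
    # last day of month: first day of next month minus one
    nxt <- as.Date(sprintf("%04d-%02d-01", y + (m == 12L), (m %% 12L) + 1L))
    return(nxt - 1L)
  }
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d))
  if (is.na(out)) stop("invalid calendar date '", s, "' at position ", pos, call. = FALSE)
  out
}

#' Serialize a query tree back to a PubMed search string
#'
#' Uses one canonical spelling per tag class and the minimal parentheses
#' needed to preserve the tree under left-to-right reparsing: boolean
#' children of boolean nodes are parenthesized, same-operator runs built by
#' the parser stay flat. `parse_query(serialize_query(e))` is structurally
#' identical to `e` for canonical trees.
#'
#' @param expr A `pm_query` (simplify first if it may hold `EMPTY` children;
#'   see [simplify_query()]).
#' @return A single search string; the `EMPTY` query serializes to `""` with
#'   a warning.
#' @export
serialize_query <- function(expr) {
  stopifnot(inherits(expr, "pm_query"))
  if (is_empty_query(expr)) {
    warning("serializing the EMPTY query (matches nothing)")
    return("")
  }
  ser <- function(node) {
    switch(node$kind,
      term = {
        txt <- if (node$quoted) paste0('"', node$text, '"') else node$text
        if (node$untagged) txt
        else paste0(txt, "[", .tag_canonical[[node$tag]], "]")
      },
      date_range = paste0(format(node$start, "%Y/%m/%d"), ":",
                          format(node$end, "%Y/%m/%d"),
                          "[", .tag_canonical[["DATE_PUBLICATION"]], "]"),
      bool = {
        kids <- vapply(node$children, function(k) {
          s <- ser(k)
          if (inherits(k, "pm_bool")) paste0("(", s, ")") else s
        }, character(1))
        paste(kids, collapse = paste0(" ", node$op, " "))
      },
      stop("cannot serialize EMPTY inside a boolean node; simplify first"))
  }
  ser(expr)
}
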