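#' Build a document corpus
#'
#' A corpus is a tibble of MEDLINE-like records: `pmid` (unique positive
#' integer), `title`, `abstract`, `journal`, `pub_date` (`Date`; `NA` marks
#' an unparseable date and fails every date filter), `mesh_headings` (list
#' column of data frames with columns `term` and `major`; empty for
#' unindexed records, which emulates indexing lag), and `filters` (list
#' column of character vectors, e.g. `"systematic review"`).
#'
#' @param pmid,title,abstract,journal,pub_date,mesh_headings,filters Record
#'   fields; scalars are recycled.
#' @return A `corpus` tibble.
#' @export
corpus <- function(pmid, title = "", abstract = "", journal = "",
                   pub_date = as.Date(NA), mesh_headings = list(),
                   filters = list()) {
  n <- length(pmid)
  pmid <- as.integer(pmid)
  if (anyNA(pmid) || any(pmid <= 0)) stop("pmid must be positive integers")
  if (anyDuplicated(pmid)) stop("duplicate pmid in corpus")
  if (length(mesh_headings) == 0) mesh_headings <- rep(list(empty_headings()), n)
  if (length(filters) == 0) filters <- rep(list(character(0)), n)
  out <- tibble::tibble(
    pmid = pmid,
    title = rep_len(as.character(title), n),
    abstract = rep_len(as.character(abstract), n),
    journal = rep_len(as.character(journal), n),
    pub_date = rep(as.Date(pub_date), length.out = n),
    mesh_headings = mesh_headings,
    filters = filters)
  class(out) <- c("corpus", class(out))
  out
}

empty_headings <- function() {
  data.frame(term = character(0), major = logical(0), stringsAsFactors = FALSE)
}

#' Read a MEDLINE flat file
#'
#' Line-oriented records with 4-character field prefixes (`PMID- `,
#' `TI  - `, `AB  - `, `MH  - `, `JT  - `, `DP  - `, `PT  - `),
#' continuation lines indented by six spaces, records separated by blank
#' lines. `MH` values are split on `/` (qualifiers are dropped) and a
#' leading `*` marks a major topic. `PT` values are collected, lower-cased,
#' into the record's filter set. `DP` accepts `YYYY`, `YYYY Mon`,
#' `YYYY Mon DD`; a missing month or day maps to January 1. A record
#' without a PMID is an error; an unparseable `DP` keeps the record with a
#' warning and a sentinel (`NA`) date.
#'
#' @param path Path to the flat file.
#' @return A `corpus`.
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) stop("MEDLINE file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  last_field <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur) > 0) recs[[length(recs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (grepl("^      ", ln) && !is.null(last_field)) {
      k <- length(cur[[last_field]])
      cur[[last_field]][k] <- paste(cur[[last_field]][k], trimws(ln))
      next
    }
    if (!grepl("^[A-Z]{2,4} *-", ln)) next  # tolerate stray lines
    field <- trimws(substr(ln, 1, 4))
    value <- sub("^[A-Z]{2,4} *- ?", "", ln)
    if (is.null(cur)) cur <- list()
    cur[[field]] <- c(cur[[field]], value)
    last_field <- field
  }
  flush()
  if (length(recs) == 0) return(corpus(integer(0)))

  parse_one <- function(r) {
    if (is.null(r$PMID)) stop("MEDLINE record without PMID")
    mh <- r$MH %||% character(0)
    headings <- if (length(mh)) {
      data.frame(term = sub("/.*$", "", sub("^\\*", "", mh)),
                 major = grepl("\\*", mh), stringsAsFactors = FALSE)
    } else empty_headings()
    list(pmid = as.integer(r$PMID[1]),
         title = paste(r$TI %||% "", collapse = " "),
         abstract = paste(r$AB %||% "", collapse = " "),
         journal = trimws(paste(r$JT %||% "", collapse = " ")),
         pub_date = .parse_medline_date(r$DP, r$PMID[1]),
         headings = headings,
         filters = tolower(trimws(r$PT %||% character(0))))
  }
  parsed <- lapply(recs, parse_one)
  corpus(pmid = vapply(parsed, `[[`, integer(1), "pmid"),
         title = vapply(parsed, `[[`, character(1), "title"),
         abstract = vapply(parsed, `[[`, character(1), "abstract"),
         journal = vapply(parsed, `[[`, character(1), "journal"),
         pub_date = as.Date(vapply(parsed, function(p) as.character(p$pub_date), character(1))),
         mesh_headings = lapply(parsed, `[[`, "headings"),
         filters = lapply(parsed, `[[`, "filters"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_medline_date <- function(dp, pmid) {
  if (is.null(dp) || !nzchar(trimws(dp[1]))) return(as.Date(NA))
  s <- trimws(dp[1])
  m <- regmatches(s, regexec("^(\\d{4})(?: ([A-Za-z]{3}))?(?: (\\d{1,2}))?", s))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) {
    warning("record ", pmid, ": cannot parse DP '", s, "'; using sentinel date")
    return(as.Date(NA))
  }
  mon <- if (nzchar(m[3])) match(tolower(m[3]), tolower(month.abb)) else 1L
  if (is.na(mon)) {
    warning("record ", pmid, ": cannot parse DP '", s, "'; using sentinel date")
    return(as.Date(NA))
  }
  day <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  out <- as.Date(sprintf("%s-%02d-%02d", m[2], mon, day))
  if (is.na(out)) warning("record ", pmid, ": invalid DP '", s, "'; using sentinel date")
  out
}

#' Read and write the JSON-lines corpus format
#'
#' One record per line with keys `pmid`, `title`, `abstract`, `journal`,
#' `pub_date` (ISO date or null), `mesh_headings` (array of
#' `{term, major}`), and `filters` (array of strings). The round trip
#' preserves all fields.
#'
#' @param path File path.
#' @return `read_corpus_jsonl()` returns a `corpus`;
#'   `write_corpus_jsonl()` returns `path` invisibly.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(corpus(integer(0)))
  recs <- lapply(lines, jsonlite::fromJSON, simplifyDataFrame = FALSE)
  headings <- lapply(recs, function(r) {
    hs <- r$mesh_headings
    if (length(hs) == 0) return(empty_headings())
    data.frame(term = vapply(hs, function(h) as.character(h$term), character(1)),
               major = vapply(hs, function(h) isTRUE(h$major), logical(1)),
               stringsAsFactors = FALSE)
  })
  corpus(
    pmid = vapply(recs, function(r) as.integer(r$pmid), integer(1)),
    title = vapply(recs, function(r) as.character(r$title %||% ""), character(1)),
    abstract = vapply(recs, function(r) as.character(r$abstract %||% ""), character(1)),
    journal = vapply(recs, function(r) as.character(r$journal %||% ""), character(1)),
    pub_date = as.Date(vapply(recs, function(r)
      if (is.null(r$pub_date)) NA_character_ else as.character(r$pub_date), character(1))),
    mesh_headings = headings,
    filters = lapply(recs, function(r) as.character(unlist(r$filters))))
}

#' @rdname read_corpus_jsonl
#' @param docs A `corpus`.
#' @export
write_corpus_jsonl <- function(docs, path) {
  stopifnot(inherits(docs, "corpus"))
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    h <- docs$mesh_headings[[i]]
    jsonlite::toJSON(list(
      pmid = docs$pmid[[i]], title = docs$title[[i]],
      abstract = docs$abstract[[i]], journal = docs$journal[[i]],
      pub_date = if (is.na(docs$pub_date[[i]])) NULL else format(docs$pub_date[[i]]),
      mesh_headings = if (nrow(h)) lapply(seq_len(nrow(h)), function(j)
        list(term = h$term[[j]], major = h$major[[j]])) else list(),
      filters = as.list(docs$filters[[i]])), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gold-standard PMID list
#'
#' Plain text, one PMID per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Integer vector of PMIDs.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("gold-standard file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- suppressWarnings(as.integer(lines))
  if (anyNA(out)) stop("non-numeric PMID in ", path)
  out
}
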