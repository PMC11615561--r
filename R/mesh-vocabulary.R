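#' Build a MeSH-style vocabulary
#'
#' A vocabulary holds descriptors, each with a preferred term, optional
#' entry terms (synonyms), and one or more dotted tree numbers placing it in
#' the poly-hierarchy. Preferred and entry terms must be unique across the
#' vocabulary after case-folding; lookups are case-insensitive.
#'
#' @param descriptors A data frame with columns `descriptor_id`,
#'   `preferred_term`, `entry_terms` (list column of character vectors, may
#'   be empty), and `tree_numbers` (list column, at least one per
#'   descriptor).
#' @return A `mesh_vocabulary` object.
#' @export
mesh_vocabulary <- function(descriptors) {
  stopifnot(is.data.frame(descriptors),
            all(c("descriptor_id", "preferred_term", "entry_terms", "tree_numbers")
                %in% names(descriptors)))
  descriptors <- tibble::as_tibble(descriptors)
  if (anyDuplicated(descriptors$descriptor_id))
    stop("duplicate descriptor_id in vocabulary")
  n_tree <- vapply(descriptors$tree_numbers, length, integer(1))
  if (nrow(descriptors) > 0 && any(n_tree == 0))
    stop("descriptor(s) without a tree number: ",
         paste(descriptors$descriptor_id[n_tree == 0], collapse = ", "))
  terms <- character(0)
  owners <- character(0)
  for (i in seq_len(nrow(descriptors))) {
    tt <- tolower(trimws(c(descriptors$preferred_term[[i]],
                           descriptors$entry_terms[[i]])))
    terms <- c(terms, tt)
    owners <- c(owners, rep(descriptors$descriptor_id[[i]], length(tt)))
  }
  dup <- duplicated(terms)
  if (any(dup)) {
    t0 <- terms[dup][1]
    stop("term '", t0, "' maps to more than one descriptor: ",
         paste(unique(owners[terms == t0]), collapse = " and "))
  }
  index <- stats::setNames(owners, terms)
  structure(list(descriptors = descriptors, term_index = index),
            class = "mesh_vocabulary")
}

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cat("<mesh_vocabulary>", nrow(x$descriptors), "descriptors,",
      length(x$term_index), "indexed terms\n")
  invisible(x)
}

#' Load a vocabulary file
#'
#' Two plain-text formats are supported: TSV with columns `descriptor_id`,
#' `preferred_term`, `entry_terms` (pipe-separated, may be blank), and
#' `tree_numbers` (pipe-separated), or a JSON array of objects with the same
#' keys. An empty file yields an empty vocabulary (all lookups miss).
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return A `mesh_vocabulary`.
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (length(rows) == 0) return(.empty_vocabulary())
    descriptors <- tibble::tibble(
      descriptor_id = vapply(rows, function(r) as.character(r$descriptor_id), character(1)),
      preferred_term = vapply(rows, function(r) as.character(r$preferred_term), character(1)),
      entry_terms = lapply(rows, function(r) as.character(unlist(r$entry_terms))),
      tree_numbers = lapply(rows, function(r) as.character(unlist(r$tree_numbers))))
    return(mesh_vocabulary(descriptors))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(.empty_vocabulary())
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("descriptor_id", "preferred_term", "entry_terms", "tree_numbers")
  if (!identical(header[seq_along(need)], need))
    stop("vocabulary TSV header must be: ", paste(need, collapse = ", "))
  body <- lines[-1]
  split_pipe <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) character(0) else trimws(strsplit(s, "|", fixed = TRUE)[[1]])
  }
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    length(f) <- 4L
    if (is.na(f[1]) || !nzchar(f[1]) || is.na(f[2]) || !nzchar(f[2]))
      stop("malformed vocabulary row at line ", i + 1L, ": ", body[i])
    rows[[i]] <- tibble::tibble(
      descriptor_id = f[1], preferred_term = f[2],
      entry_terms = list(split_pipe(ifelse(is.na(f[3]), "", f[3]))),
      tree_numbers = list(split_pipe(ifelse(is.na(f[4]), "", f[4]))))
  }
  mesh_vocabulary(do.call(rbind, rows))
}

.empty_vocabulary <- function() {
  mesh_vocabulary(tibble::tibble(
    descriptor_id = character(0), preferred_term = character(0),
    entry_terms = list(), tree_numbers = list()))
}

#' Write a vocabulary to the TSV interchange format
#'
#' @param vocab A `mesh_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  d <- vocab$descriptors
  lines <- c("descriptor_id\tpreferred_term\tentry_terms\ttree_numbers",
             vapply(seq_len(nrow(d)), function(i) {
               paste(d$descriptor_id[[i]], d$preferred_term[[i]],
                     paste(d$entry_terms[[i]], collapse = "|"),
                     paste(d$tree_numbers[[i]], collapse = "|"),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Map a term to its descriptor
#'
#' Case-insensitive match against preferred and entry terms. Terms claimed
#' to be MeSH headings that miss the thesaurus resolve to `NA`; the
#' retrieval engine then matches nothing for them, and [to_mesh_only()]
#' deletes them.
#'
#' @param vocab A `mesh_vocabulary`.
#' @param term Term text.
#' @return The descriptor id, or `NA_character_` on a miss.
#' @export
normalize_term <- function(vocab, term) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  key <- tolower(trimws(term))
  if (key %in% names(vocab$term_index)) unname(vocab$term_index[[key]])
  else NA_character_
}

#' Explode a descriptor into its subtree
#'
#' Returns the descriptor together with every descriptor any of whose tree
#' numbers extends one of its tree numbers by the dotted-prefix relation —
#' the narrower-term expansion PubMed applies to `[MeSH Terms]` searches.
#'
#' @param vocab A `mesh_vocabulary`.
#' @param descriptor_id A descriptor present in `vocab`.
#' @return Character vector of descriptor ids (always includes
#'   `descriptor_id` itself).
#' @export
mesh_explode <- function(vocab, descriptor_id) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  d <- vocab$descriptors
  i <- match(descriptor_id, d$descriptor_id)
  if (is.na(i)) stop("unknown descriptor: ", descriptor_id)
  roots <- d$tree_numbers[[i]]
  hit <- vapply(seq_len(nrow(d)), function(j) {
    any(vapply(d$tree_numbers[[j]], function(tn) {
      any(tn == roots | startsWith(tn, paste0(roots, ".")))
    }, logical(1)))
  }, logical(1))
  sort(unique(c(descriptor_id, d$descriptor_id[hit])))
}

# The 14 MeSH check tags PubMed keeps usable as population/species filters;
# these survive the free-text rewrite so the filter clauses stay intact.
.filter_terms <- c(
  "80 and over", "adolescent", "adult", "aged", "animals", "child",
  "female", "humans", "infant", "male", "middle aged", "newborn",
  "preschool", "young adult")

#' The 14-term filter whitelist
#'
#' @return Character vector of the 14 filter terms.
#' @export
mesh_filter_terms <- function() .filter_terms

#' Is a term on the filter whitelist?
#'
#' Case-insensitive membership in the 14-term check-tag list (humans,
#' female, adult, ...). These terms keep their MeSH tag when a query is
#' rewritten to free text, so they can still act as filters.
#'
#' @param term Term text.
#' @return Logical.
#' @export
is_filter_term <- function(term) {
  tolower(trimws(term)) %in% .filter_terms
}
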