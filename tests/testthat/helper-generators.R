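# Shared fixtures and generators, built in code.

# A small thesaurus: cardiovascular branch with an entry term, a two-level
# chain, and an unrelated drug branch. "Hypertension, Renal" is a child of
# "Hypertension"; "Famotidine" sits elsewhere.
make_test_vocab <- function() {
  mesh_vocabulary(tibble::tibble(
    descriptor_id = c("D001", "D002", "D003", "D004", "D005"),
    preferred_term = c("Hypertension", "Hypertension, Renal",
                       "Hypertension, Renovascular", "Famotidine", "Humans"),
    entry_terms = list(c("High Blood Pressure"), character(0),
                       character(0), c("Pepcid"), character(0)),
    tree_numbers = list("C14.280", "C14.280.100", "C14.280.100.200",
                        "D02.100", "B01.050")))
}

rand_from <- function(pool, n = 1) pool[sample.int(length(pool), n, replace = TRUE)]

.word_pool <- c("alpha", "beta", "gamma", "delta", "kappa", "sigma",
                "omega", "zeta", "lambda", "theta")

# Random canonical query tree. Terms draw from a small word pool so random
# corpora below share vocabulary with random queries; untagged terms only
# ever carry the ALL_FIELDS class (parser convention).
gen_term <- function() {
  text <- paste(rand_from(.word_pool, sample(1:2, 1)), collapse = " ")
  untagged <- runif(1) < 0.2
  tag <- if (untagged) "ALL_FIELDS" else
    rand_from(c("MESH", "MESH_NOEXP", "MESH_MAJOR", "TITLE_ABSTRACT",
                "TITLE", "TEXT_WORD", "ALL_FIELDS", "JOURNAL", "FILTER"))
  pm_term(text, tag, quoted = runif(1) < 0.3, untagged = untagged)
}

gen_query <- function(max_depth = 3) {
  if (max_depth == 0 || runif(1) < 0.4) {
    if (runif(1) < 0.1) {
      start <- as.Date("2012-01-01") + sample.int(2000, 1)
      return(pm_date_range(start, start + sample.int(2000, 1)))
    }
    return(gen_term())
  }
  op <- rand_from(c("AND", "OR", "NOT"))
  k <- if (op == "NOT") 2L else sample(2:4, 1)
  pm_bool(op, lapply(seq_len(k), function(i) gen_query(max_depth - 1)))
}

n_nodes <- function(q) {
  if (inherits(q, "pm_bool")) 1L + sum(vapply(q$children, n_nodes, integer(1)))
  else 1L
}

# Random corpus sharing the word pool and the test thesaurus terms.
gen_corpus <- function(n_docs, vocab = make_test_vocab()) {
  all_terms <- c(vocab$descriptors$preferred_term, "Not A Heading")
  headings <- lapply(seq_len(n_docs), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(mesheval:::empty_headings())
    data.frame(term = rand_from(all_terms, k), major = runif(k) < 0.5,
               stringsAsFactors = FALSE)
  })
  corpus(
    pmid = sample.int(10000, n_docs),
    title = vapply(seq_len(n_docs), function(i)
      paste(rand_from(.word_pool, sample(2:5, 1)), collapse = " "), character(1)),
    abstract = vapply(seq_len(n_docs), function(i)
      paste(rand_from(.word_pool, sample(3:8, 1)), collapse = " "), character(1)),
    journal = rand_from(c("alpha", "Journal of Beta", "Gamma Reports"), n_docs),
    pub_date = as.Date("2010-01-01") + sample.int(5000, n_docs, replace = TRUE),
    mesh_headings = headings,
    filters = lapply(seq_len(n_docs), function(i)
      rand_from(c("systematic review", "loattrfree full text"), sample(0:1, 1))))
}

# Independent oracle: evaluate the query as a boolean formula document by
# document (no set algebra, no ranking).
doc_matches <- function(docs, i, expr, vocab) {
  switch(expr$kind,
    term = match_term(docs[i, ], expr, vocab),
    bool = {
      hits <- vapply(expr$children, function(k) doc_matches(docs, i, k, vocab),
                     logical(1))
      switch(expr$op, AND = all(hits), OR = any(hits), hits[1] && !hits[2])
    },
    date_range = !is.na(docs$pub_date[i]) &&
      docs$pub_date[i] >= expr$start && docs$pub_date[i] <= expr$end,
    FALSE)
}

oracle_retrieve <- function(docs, expr, vocab) {
  docs$pmid[vapply(seq_len(nrow(docs)), function(i)
    doc_matches(docs, i, expr, vocab), logical(1))]
}

# Closed-form DerSimonian-Laird pooling of 2x2 tables (0.5-if-any-zero),
# independent of the model-fitting route used by the package.
dl_pool_oracle <- function(tabs) {
  m <- as.matrix(tabs[, c("a", "b", "c", "d")])
  z <- apply(m == 0, 1, any)
  m[z, ] <- m[z, ] + 0.5
  yi <- log((m[, 1] / m[, 2]) / (m[, 3] / m[, 4]))
  vi <- rowSums(1 / m)
  wi <- 1 / vi
  ybar <- sum(wi * yi) / sum(wi)
  q <- sum(wi * (yi - ybar)^2)
  k <- length(yi)
  tau2 <- max(0, (q - (k - 1)) / (sum(wi) - sum(wi^2) / sum(wi)))
  ws <- 1 / (vi + tau2)
  est <- sum(ws * yi) / sum(ws)
  list(pooled_or = exp(est), tau2 = tau2,
       se = sqrt(1 / sum(ws)))
}

table1_fixture_path <- function() {
  system.file("extdata", "table1.csv", package = "mesheval")
}

# strip the logging attributes to_mesh_only attaches, for identical() checks
unclass_attrs <- function(x) {
  attr(x, "deleted_terms") <- NULL
  attr(x, "kept_terms") <- NULL
  x
}
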