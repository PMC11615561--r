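#' Specification for a synthetic retrieval world
#'
#' Describes a small literature in which one target concept (and several
#' distractor concepts) is realized in two channels: as free-text synonym
#' phrases in titles/abstracts and as probabilistic thesaurus indexing.
#' `p_index` is the indexing completeness — lowering it emulates the
#' indexing lag that makes MeSH-only searching miss recent records;
#' `p_broader` is the probability that an indexed record carries a
#' *narrower* (child) descriptor rather than the exact one, which is what
#' makes thesaurus explosion matter.
#'
#' @param n_docs Number of documents (default 200).
#' @param n_concepts Number of concepts in the vocabulary tree (default 8).
#' @param tree_branching Children per node in the concept tree (default 3).
#' @param synonyms_per_concept Entry terms per concept besides the
#'   preferred term (default 3).
#' @param p_text Probability that each synonym of a document's concept
#'   surfaces verbatim in its text (default 0.9).
#' @param p_index Probability that a document is MeSH-indexed for its
#'   concept (default 0.7).
#' @param p_broader Given indexing, probability the heading is a child
#'   descriptor of the exact one (default 0.2).
#' @param p_distractor_text Probability that a distractor document also
#'   mentions one target synonym, creating text false positives
#'   (default 0.05).
#' @param n_gold Number of gold-standard documents about the target
#'   concept (default 30; must not exceed `n_docs`).
#' @param include_filter Add a `humans[MeSH Terms]` filter clause to the
#'   generated query (and a Humans heading to every record)?
#' @param seed Integer seed; the world is a deterministic function of the
#'   spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_docs = 200, n_concepts = 8, tree_branching = 3,
                           synonyms_per_concept = 3, p_text = 0.9,
                           p_index = 0.7, p_broader = 0.2,
                           p_distractor_text = 0.05, n_gold = 30,
                           include_filter = FALSE, seed = 1L) {
  probs <- c(p_text = p_text, p_index = p_index, p_broader = p_broader,
             p_distractor_text = p_distractor_text)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (n_gold > n_docs) stop("infeasible spec: n_gold > n_docs")
  if (n_concepts < tree_branching + 2)
    stop("need at least tree_branching + 2 concepts so the target concept ",
         "has narrower descriptors and distractors exist outside its subtree")
  structure(list(n_docs = as.integer(n_docs), n_concepts = as.integer(n_concepts),
                 tree_branching = as.integer(tree_branching),
                 synonyms_per_concept = as.integer(synonyms_per_concept),
                 p_text = p_text, p_index = p_index, p_broader = p_broader,
                 p_distractor_text = p_distractor_text,
                 n_gold = as.integer(n_gold),
                 include_filter = isTRUE(include_filter),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# concept vocabulary: k-ary tree. The target is concept 2 — an internal
# node with children (so p_broader has narrower descriptors to use) whose
# subtree does not cover the distractor concepts.
.synthetic_vocabulary <- function(spec) {
  n <- spec$n_concepts
  parent <- c(NA_integer_, ((seq_len(n - 1) - 1L) %/% spec$tree_branching) + 1L)
  tree <- character(n)
  tree[1] <- "C01"
  for (i in seq_len(n)[-1]) tree[i] <- paste0(tree[parent[i]], ".", sprintf("%03d", i))
  descriptors <- tibble::tibble(
    descriptor_id = sprintf("D%06d", seq_len(n)),
    preferred_term = sprintf("malady %04d", seq_len(n)),
    entry_terms = lapply(seq_len(n), function(i)
      sprintf("synonym %d for %04d", seq_len(spec$synonyms_per_concept), i)),
    tree_numbers = lapply(tree, identity))
  if (spec$include_filter) {
    descriptors <- rbind(descriptors, tibble::tibble(
      descriptor_id = "D900001", preferred_term = "Humans",
      entry_terms = list(character(0)), tree_numbers = list("Z01.900")))
  }
  mesh_vocabulary(descriptors)
}

#' Generate a synthetic world: vocabulary, corpus, gold standard and query
#'
#' Gold documents are about the target concept — an internal node of the
#' concept tree, so it has narrower descendants while the distractor
#' concepts sit outside its subtree: each of its synonyms surfaces in their text independently with
#' probability `p_text`, and each record is indexed with probability
#' `p_index` (with probability `p_broader`, under a child descriptor, so
#' only an exploded search reaches it). Distractor documents are about
#' other concepts and occasionally mention a target synonym
#' (`p_distractor_text`), creating text false positives. The generated
#' mixed query is the OR of the target heading and all its synonym
#' phrases: `OR(target[MeSH Terms], target[tiab], synonym1[tiab], ...)`,
#' optionally AND-ed with a `humans[MeSH Terms]` filter clause. Because
#' the free-text and MeSH rewrites of this query search subsets of the
#' same clauses, the mixed query's result set contains both rewrites'
#' result sets — the union-dominance property the evaluation relies on.
#'
#' Deterministic: two calls with the same spec produce identical worlds.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `vocab` (`mesh_vocabulary`), `docs` (`corpus`),
#'   `gold` (integer PMIDs), `v1_query` (`pm_query`), and `spec`.
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocab <- .synthetic_vocabulary(spec)
  withr::with_seed(spec$seed, {
    n <- spec$n_docs
    target <- 2L
    target_pref <- "malady 0002"
    target_syns <- sprintf("synonym %d for 0002", seq_len(spec$synonyms_per_concept))
    children <- setdiff(mesh_explode(vocab, "D000002"), "D000002")
    d <- vocab$descriptors
    pref_of <- stats::setNames(d$preferred_term, d$descriptor_id)
    # distractors live outside the target subtree, so thesaurus explosion
    # of the target never reaches them
    child_idx <- as.integer(sub("^D0*", "", children))
    distractor_pool <- setdiff(seq_len(spec$n_concepts), c(target, child_idx))

    is_gold <- seq_len(n) <= spec$n_gold
    concept <- ifelse(is_gold, target,
                      sample(distractor_pool, n, replace = TRUE))
    titles <- character(n); abstracts <- character(n)
    headings <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_gold[i]) {
        phrases <- c(target_pref, target_syns)
        realized <- phrases[stats::runif(length(phrases)) < spec$p_text]
      } else {
        ci <- concept[i]
        realized <- c(pref_of[[sprintf("D%06d", ci)]],
                      sprintf("synonym 1 for %04d", ci))
        if (stats::runif(1) < spec$p_distractor_text)
          realized <- c(realized, sample(c(target_pref, target_syns), 1))
      }
      titles[i] <- if (length(realized))
        sprintf("A study of %s in a hospital cohort", realized[1])
      else "A study of an unnamed condition in a hospital cohort"
      abstracts[i] <- paste0(
        "Background: clinical outcomes were assessed. ",
        if (length(realized)) paste0("We investigated ",
          paste(realized, collapse = " and "), ". ") else "",
        "Methods: retrospective cohort. Results: outcomes varied.")
      hs <- empty_headings()
      if (stats::runif(1) < spec$p_index) {
        if (is_gold[i]) {
          did <- if (length(children) && stats::runif(1) < spec$p_broader)
            sample(children, 1) else "D000002"
        } else {
          did <- sprintf("D%06d", concept[i])
        }
        hs <- data.frame(term = pref_of[[did]],
                         major = stats::runif(1) < 0.5,
                         stringsAsFactors = FALSE)
      }
      if (spec$include_filter)
        hs <- rbind(hs, data.frame(term = "Humans", major = FALSE,
                                   stringsAsFactors = FALSE))
      headings[[i]] <- hs
    }
    docs <- corpus(
      pmid = 100000L + seq_len(n),
      title = titles, abstract = abstracts,
      journal = sample(c("Journal of Synthetic Medicine",
                         "Annals of Simulated Evidence"), n, replace = TRUE),
      pub_date = as.Date("2012-01-01") + sample.int(3650, n, replace = TRUE),
      mesh_headings = headings,
      filters = rep(list(character(0)), n))

    clauses <- c(list(pm_term(target_pref, "MESH")),
                 lapply(c(target_pref, target_syns), function(s)
                   pm_term(s, "TITLE_ABSTRACT")))
    v1 <- pm_bool("OR", clauses)
    if (spec$include_filter)
      v1 <- pm_bool("AND", list(v1, pm_term("humans", "MESH")))

    list(vocab = vocab, docs = docs, gold = docs$pmid[is_gold],
         v1_query = v1, spec = spec)
  })
}

#' Sweep indexing completeness and measure per-arm performance
#'
#' Monte-Carlo harness for the headline contrast: for each value of
#' `p_index`, generates `replicates` worlds (replicate r reuses seed
#' `spec$seed + r` across the grid, coupling the draws), derives the
#' free-text-only and MeSH-only rewrites of the generated query, runs all
#' three against the corpus, and averages sensitivity and PPV per arm.
#'
#' @param spec A [synthetic_spec()] (its own `p_index` is ignored).
#' @param p_index_values Numeric vector of indexing-completeness values.
#' @param replicates Monte-Carlo replicates per grid point (>= 1).
#' @return Long tibble: `p_index`, `version`, `mean_se`, `mean_ppv`,
#'   `replicates`.
#' @export
sweep_indexing <- function(spec, p_index_values = c(0, 0.5, 1),
                           replicates = 10L) {
  stopifnot(inherits(spec, "synthetic_spec"), replicates >= 1)
  out <- list()
  for (p in p_index_values) {
    acc <- list(v1 = c(0, 0), v2 = c(0, 0), v3 = c(0, 0))
    for (r in seq_len(replicates)) {
      sp <- spec
      sp$p_index <- p
      sp$seed <- spec$seed + r
      w <- generate_world(sp)
      v2 <- to_free_text(w$v1_query)
      v3 <- to_mesh_only(w$v1_query, w$vocab)
      for (v in c("v1", "v2", "v3")) {
        q <- switch(v, v1 = w$v1_query, v2 = v2, v3 = v3)
        res <- evaluate_query(w$docs, q, w$vocab)
        s <- score(res$pmids, w$gold, items = length(res$pmids))
        acc[[v]] <- acc[[v]] + c(s$se, s$ppv)
      }
    }
    for (v in c("v1", "v2", "v3")) {
      out[[length(out) + 1L]] <- tibble::tibble(
        p_index = p, version = v,
        mean_se = acc[[v]][1] / replicates,
        mean_ppv = acc[[v]][2] / replicates,
        replicates = as.integer(replicates))
    }
  }
  do.call(rbind, out)
}
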