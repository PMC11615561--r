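#' Validate a study configuration
#'
#' A configuration names the corpus (JSONL or MEDLINE flat file), the
#' vocabulary file, one query file per review, one gold-standard PMID list
#' per review, and the evaluation settings. All referenced paths must
#' exist, except gold files, whose absence skips the review with a warning
#' at run time.
#'
#' @param config Named list (or path to a JSON file with the same keys):
#'   `corpus`, `vocab`, `queries` (named list review-id -> query file),
#'   `gold` (named list review-id -> PMID list file), optional `out`
#'   (artifact directory), `cap` (default 10000), `correction`,
#'   `estimator`, `weights`, `apply_atm` (default TRUE).
#' @return The normalized configuration list, invisibly for
#'   `validate_run_config()`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config))
  defaults <- list(out = NULL, cap = 10000L, correction = "if_any_zero",
                   estimator = "REML", weights = "equal", apply_atm = TRUE)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("corpus", "vocab", "queries", "gold"))
    if (is.null(config[[k]])) stop("config is missing '", k, "'")
  config$queries <- as.list(config$queries)
  config$gold <- as.list(config$gold)
  if (is.null(names(config$queries)) || any(!nzchar(names(config$queries))))
    stop("config$queries must be a named list (review id -> query file)")
  for (p in c(config$corpus, config$vocab, unlist(config$queries)))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  if (config$cap < 1) stop("cap must be >= 1")
  invisible(config)
}

#' Run the three-version study end to end
#'
#' For each review: parse the mixed query, resolve untagged terms through
#' automatic term mapping, derive the free-text-only (V2) and MeSH-only
#' (V3) rewrites, run all three against the corpus, and score each against
#' the review's gold standard. Results are then aggregated: per-version
#' medians/IQRs, headline totals, and (when at least two reviews are
#' scored) pooled random-effects odds ratios of V2 vs V1 for sensitivity
#' and PPV. Every transformation decision — filter terms preserved, terms
#' deleted because they miss the thesaurus — is logged; with `out` set,
#' artifacts are written (`results.csv`, `summary.csv`, `pooled.csv`,
#' `transform_log.jsonl`). Deterministic: same configuration, same
#' artifacts.
#'
#' @param config See [validate_run_config()].
#' @return List with `per_sr` (long tibble of eval records), `wide`
#'   (one row per review in count-table layout), `summary`, `headline`,
#'   `pooled` (list of `pooled_or` or NULL), `log` (list of per-review
#'   transformation records).
#' @export
run_study <- function(config) {
  config <- validate_run_config(config)
  docs <- if (grepl("\\.jsonl$", config$corpus, ignore.case = TRUE))
    read_corpus_jsonl(config$corpus) else read_medline(config$corpus)
  vocab <- load_vocabulary(config$vocab)

  per_sr <- list()
  wide <- list()
  logs <- list()
  for (sr in names(config$queries)) {
    gold_path <- config$gold[[sr]]
    if (is.null(gold_path) || !file.exists(gold_path)) {
      warning("no gold-standard file for review ", sr, "; skipped")
      next
    }
    gold <- read_gold_standard(gold_path)
    qtext <- paste(readLines(config$queries[[sr]], warn = FALSE), collapse = " ")
    v1 <- parse_query(qtext)
    if (isTRUE(config$apply_atm)) v1 <- atm_expand(v1, vocab)
    v1 <- simplify_query(v1)
    v2 <- to_free_text(v1)
    v3 <- to_mesh_only(v1, vocab)
    whitelisted <- character(0)
    map_terms(v1, function(t) {
      if (t$tag %in% .mesh_tags && is_filter_term(t$text))
        whitelisted <<- c(whitelisted, t$text)
      t
    })
    logs[[sr]] <- list(sr_id = sr,
                       whitelisted_terms = unique(whitelisted),
                       deleted_terms = attr(v3, "deleted_terms") %||% character(0),
                       v3_nonviable = is_empty_query(v3))
    row <- list(sr_pmid = sr, gs_size = length(unique(gold)))
    for (v in c("v1", "v2", "v3")) {
      q <- switch(v, v1 = v1, v2 = v2, v3 = v3)
      res <- evaluate_query(docs, q, vocab, cap = config$cap)
      s <- score(res$pmids, gold, items = length(res$pmids),
                 sr_id = sr, version = v)
      per_sr[[length(per_sr) + 1L]] <- s
      row[[paste0("items_", v)]] <- s$items
      row[[paste0("found_", v)]] <- s$gs_found
      row[[paste0("se_", v)]] <- s$se
      row[[paste0("ppv_", v)]] <- s$ppv
      row[[paste0("f1_", v)]] <- s$f1
    }
    wide[[length(wide) + 1L]] <- tibble::as_tibble(row)
  }
  if (length(per_sr) == 0) stop("no review could be scored")
  per_sr <- do.call(rbind, per_sr)
  wide <- do.call(rbind, wide)

  summary <- summarize_versions(wide, metrics_from = "counts")
  headline <- headline_stats(wide)
  pooled <- NULL
  if (nrow(wide) >= 2) {
    pooled <- list(
      sensitivity_v2_vs_v1 = pool_log_odds_ratios(
        or_tables(wide, "v2_vs_v1", "sensitivity"),
        estimator = config$estimator, correction = config$correction,
        weights = config$weights),
      ppv_v2_vs_v1 = pool_log_odds_ratios(
        or_tables(wide, "v2_vs_v1", "ppv"),
        estimator = config$estimator, correction = config$correction,
        weights = config$weights))
  }
  report <- list(per_sr = per_sr, wide = wide, summary = summary,
                 headline = headline, pooled = pooled, log = logs)
  if (!is.null(config$out)) .write_study_artifacts(report, config$out)
  report
}

.write_study_artifacts <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_sr, file.path(out, "results.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(out, "summary.csv"), row.names = FALSE)
  if (!is.null(report$pooled)) {
    pooled_df <- do.call(rbind, lapply(names(report$pooled), function(nm) {
      p <- report$pooled[[nm]]
      data.frame(analysis = nm, pooled_or = p$pooled_or,
                 ci_lo = p$ci95[["lo"]], ci_hi = p$ci95[["hi"]],
                 tau2 = p$tau2, k = p$k, estimator = p$estimator,
                 weights = p$weights)
    }))
    utils::write.csv(pooled_df, file.path(out, "pooled.csv"), row.names = FALSE)
  }
  writeLines(vapply(report$log, function(x)
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE)), character(1)),
    file.path(out, "transform_log.jsonl"))
  invisible(out)
}
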