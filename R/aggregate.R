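#' Per-version performance summary (medians and IQRs)
#'
#' For each query version, the median and quartiles (linear-interpolation
#' order statistics, `stats::quantile` type 7) of sensitivity, PPV and F1
#' (0-100 scale), of the number of results, of the number of gold items
#' found, and of the reading cost (results per gold item found). By
#' default the three proportion metrics are summarized from the published
#' 3-decimal per-row values — the convention under which the published
#' summary table reproduces cell for cell — `metrics_from = "counts"`
#' recomputes them from the raw counts instead. Reading cost keeps
#' infinite values (something screened, nothing found) in the quantiles
#' but drops the degenerate `0/0` rows of nonviable queries.
#'
#' @param rows A table from [load_table1()].
#' @param metrics_from `"printed"` (default) or `"counts"`.
#' @return Long tibble: `version`, `measure`, `median`, `q1`, `q3`,
#'   `n` (rows contributing).
#' @export
summarize_versions <- function(rows, metrics_from = c("printed", "counts")) {
  metrics_from <- match.arg(metrics_from)
  q3n <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  out <- list()
  add <- function(version, measure, x) {
    q <- q3n(x)
    out[[length(out) + 1L]] <<- tibble::tibble(
      version = version, measure = measure,
      median = q[1], q1 = q[2], q3 = q[3], n = length(x))
  }
  for (v in paste0("v", 1:3)) {
    found <- rows[[paste0("found_", v)]]
    items <- rows[[paste0("items_", v)]]
    if (metrics_from == "printed") {
      se <- rows[[paste0("se_", v)]]
      ppv <- rows[[paste0("ppv_", v)]]
      f1 <- rows[[paste0("f1_", v)]]
    } else {
      se <- ifelse(rows$gs_size > 0, found / rows$gs_size, 0)
      ppv <- ifelse(items > 0, found / items, 0)
      f1 <- ifelse(se + ppv > 0, 2 * se * ppv / (se + ppv), 0)
    }
    add(v, "sensitivity", se * 100)
    add(v, "ppv", ppv * 100)
    add(v, "f1", f1 * 100)
    add(v, "items", items)
    add(v, "gs_found", found)
    rc <- reading_cost(items, found)
    add(v, "reading_cost", rc[!(items == 0 & found == 0)])
  }
  do.call(rbind, out)
}

#' Headline totals, means and counts across reviews
#'
#' Totals of items and gold items found per version; the per-review mean
#' extra screening burden and extra relevant yield of the mixed query over
#' the free-text query (V1 minus V2, also rounded to 2 decimals); the
#' screening cost of one additional relevant paper (quotient of the two
#' rounded means); the count of reviews where dropping MeSH terms lost
#' relevant articles (`found_v1 > found_v2`); the counts of reviews whose
#' found-ratio ([gs_ratio()]) is at most 1 and at most 1.05 (finite ratios
#' only); and the count of nonviable MeSH-only queries (zero items).
#'
#' @param rows A table from [load_table1()].
#' @return Named list of scalars (see Details in the source).
#' @export
headline_stats <- function(rows) {
  n <- nrow(rows)
  totals <- list()
  for (v in paste0("v", 1:3)) {
    totals[[paste0("total_items_", v)]] <- sum(rows[[paste0("items_", v)]])
    totals[[paste0("total_found_", v)]] <- sum(rows[[paste0("found_", v)]])
  }
  mean_extra_screened <- (totals$total_items_v1 - totals$total_items_v2) / n
  mean_extra_relevant <- (totals$total_found_v1 - totals$total_found_v2) / n
  r2 <- function(x) round(x, 2)
  ratio <- gs_ratio(rows$found_v1, rows$found_v2)
  c(totals, list(
    n_reviews = n,
    pct_found_v1 = 100 * totals$total_found_v1 / totals$total_items_v1,
    pct_found_v2 = 100 * totals$total_found_v2 / totals$total_items_v2,
    mean_extra_screened = mean_extra_screened,
    mean_extra_relevant = mean_extra_relevant,
    mean_extra_screened_2dp = r2(mean_extra_screened),
    mean_extra_relevant_2dp = r2(mean_extra_relevant),
    cost_per_extra_relevant = r2(r2(mean_extra_screened) / r2(mean_extra_relevant)),
    n_impacted = sum(rows$found_v1 > rows$found_v2),
    n_ratio_le_1 = sum(is.finite(ratio) & ratio <= 1),
    n_ratio_le_1_05 = sum(is.finite(ratio) & ratio <= 1.05),
    n_ratio_infinite = sum(is.infinite(ratio)),
    n_v3_zero_items = sum(rows$items_v3 == 0)))
}

#' Build per-review 2x2 odds tables for a version comparison
#'
#' For sensitivity the cells are (found_a, missed_a, found_b, missed_b)
#' against the shared gold standard; for PPV they are
#' (found_a, false-positives_a, found_b, false-positives_b).
#'
#' @param rows A table from [load_table1()].
#' @param comparison `"v2_vs_v1"` or `"v3_vs_v1"`.
#' @param measure `"sensitivity"` or `"ppv"`.
#' @return Tibble with `sr_id` and cells `a`, `b`, `c`, `d`.
#' @export
or_tables <- function(rows, comparison = c("v2_vs_v1", "v3_vs_v1"),
                      measure = c("sensitivity", "ppv")) {
  comparison <- match.arg(comparison)
  measure <- match.arg(measure)
  va <- sub("_vs.*", "", comparison)
  fa <- rows[[paste0("found_", va)]]
  fb <- rows$found_v1
  if (measure == "sensitivity") {
    b <- rows$gs_size - fa
    d <- rows$gs_size - fb
  } else {
    b <- rows[[paste0("items_", va)]] - fa
    d <- rows$items_v1 - fb
  }
  tibble::tibble(sr_id = as.character(rows$sr_pmid), a = fa, b = b, c = fb, d = d)
}

#' Pool per-review log odds ratios with a random-effects model
#'
#' Applies the continuity rule per table, takes the log odds ratio and its
#' variance from the cell reciprocals, estimates the between-review
#' variance tau-squared (REML by default, DerSimonian-Laird selectable),
#' and combines the log odds ratios under the random-effects model with a
#' Wald 95\% interval, exponentiated back to the OR scale. With
#' `weights = "equal"` (the default) every review counts the same — the
#' pooled log OR is their plain mean, the convention under which the
#' published pooled estimates and intervals reproduce exactly —
#' `"inverse_variance"` weights by `1/(v_i + tau^2)`. Model fitting is
#' delegated to [metafor::rma()].
#'
#' @param tables A tibble from [or_tables()], or any data frame with
#'   numeric cells `a`, `b`, `c`, `d` (one 2x2 table per row).
#' @param estimator `"REML"` (default) or `"DL"`.
#' @param correction Continuity rule: `"if_any_zero"` (default, adds 0.5 to
#'   all four cells of tables containing a zero), `"always"`, `"none"`
#'   (non-estimable tables are then dropped).
#' @param weights `"equal"` (default) or `"inverse_variance"`.
#' @param level Confidence level (default 0.95).
#' @return A `pooled_or` list: `pooled_or`, `ci95` (lo, hi), `tau2`, `k`,
#'   `estimator`, `weights`.
#' @export
pool_log_odds_ratios <- function(tables,
                                 estimator = c("REML", "DL"),
                                 correction = "if_any_zero",
                                 weights = c("equal", "inverse_variance"),
                                 level = 0.95) {
  estimator <- match.arg(estimator)
  weights <- match.arg(weights)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  ors <- lapply(seq_len(nrow(tables)), function(i)
    .or_2x2(tables$a[i], tables$b[i], tables$c[i], tables$d[i], correction))
  est <- vapply(ors, `[[`, logical(1), "estimable")
  yi <- vapply(ors, `[[`, numeric(1), "log_or")[est]
  vi <- vapply(ors, `[[`, numeric(1), "se_log_or")[est]^2
  keep <- is.finite(yi) & is.finite(vi) & vi > 0
  yi <- yi[keep]; vi <- vi[keep]
  if (length(yi) < 2)
    stop("need at least two estimable tables to pool (got ", length(yi), ")")
  fit <- metafor::rma(yi, vi, method = estimator,
                      weighted = (weights == "inverse_variance"),
                      level = 100 * level)
  structure(list(
    pooled_or = unname(exp(fit$b[1])),
    ci95 = c(lo = exp(fit$ci.lb), hi = exp(fit$ci.ub)),
    tau2 = fit$tau2, k = fit$k,
    estimator = estimator, weights = weights),
    class = "pooled_or")
}

#' @export
print.pooled_or <- function(x, ...) {
  cat(sprintf("Pooled OR %.3f (95%% CI %.3f-%.3f), tau2 = %.3f, k = %d [%s, %s weights]\n",
              x$pooled_or, x$ci95[["lo"]], x$ci95[["hi"]], x$tau2, x$k,
              x$estimator, x$weights))
  invisible(x)
}

#' Forest-plot data: per-review odds ratios plus the pooled row
#'
#' One `or_record`-style row per estimable review, with a Wald interval on
#' the log scale, and the pooled random-effects result.
#'
#' @inheritParams or_tables
#' @inheritParams pool_log_odds_ratios
#' @return List with `per_sr` (tibble: `sr_id`, `or`, `lo`, `hi`,
#'   `corrected`) and `pooled` (a `pooled_or`).
#' @export
forest_data <- function(rows, comparison = c("v2_vs_v1", "v3_vs_v1"),
                        measure = c("sensitivity", "ppv"),
                        estimator = "REML", correction = "if_any_zero",
                        weights = "equal") {
  tabs <- or_tables(rows, comparison, measure)
  z <- stats::qnorm(0.975)
  per <- lapply(seq_len(nrow(tabs)), function(i) {
    o <- .or_2x2(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i], correction)
    if (!o$estimable || !is.finite(o$log_or)) return(NULL)
    tibble::tibble(sr_id = tabs$sr_id[i], or = o$or,
                   lo = exp(o$log_or - z * o$se_log_or),
                   hi = exp(o$log_or + z * o$se_log_or),
                   corrected = o$corrected)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  list(per_sr = per,
       pooled = pool_log_odds_ratios(tabs, estimator = estimator,
                                     correction = correction, weights = weights))
}
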