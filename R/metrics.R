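#' Score a retrieval result against a gold standard
#'
#' Computes the confusion counts and derived proportions for one
#' (review, query-version) pair: sensitivity (recall)
#' `se = TP / |gold|`, positive predictive value (precision)
#' `ppv = TP / items`, and their harmonic mean `f1`. The zero conventions
#' are `se = 0` when the gold standard is empty, `ppv = 0` when nothing was
#' retrieved, and `f1 = 0` when `se + ppv = 0`. When a result was capped,
#' pass the retained list as `retrieved` and the engine's total as `items`:
#' gold items are then counted only within the retained list, mirroring the
#' extraction constraint of the search interface.
#'
#' @param retrieved Integer PMIDs retrieved (the retained list if capped).
#' @param gold Integer PMIDs of the gold standard.
#' @param items Number of retrieved items; defaults to `length(retrieved)`.
#' @param sr_id,version Optional labels carried into the record.
#' @return A one-row tibble (`eval_record`): `sr_id`, `version`, `items`,
#'   `gs_size`, `gs_found`, `fp`, `fn`, `se`, `ppv`, `f1`.
#' @export
score <- function(retrieved, gold, items = length(retrieved),
                  sr_id = NA_character_, version = NA_character_) {
  retrieved <- unique(as.integer(retrieved))
  gold <- unique(as.integer(gold))
  gs_found <- length(intersect(retrieved, gold))
  gs_size <- length(gold)
  se <- if (gs_size > 0) gs_found / gs_size else 0
  ppv <- if (items > 0) gs_found / items else 0
  f1 <- if (se + ppv > 0) 2 * se * ppv / (se + ppv) else 0
  out <- tibble::tibble(
    sr_id = as.character(sr_id), version = as.character(version),
    items = as.integer(items), gs_size = gs_size, gs_found = gs_found,
    fp = as.integer(items) - gs_found, fn = gs_size - gs_found,
    se = se, ppv = ppv, f1 = f1)
  class(out) <- c("eval_record", class(out))
  out
}

# Odds ratio from a 2x2 table (a/b) / (c/d) with continuity handling.
# correction: "if_any_zero" adds 0.5 to all four cells iff any cell is 0
# (the common default of meta-analysis software); "always" adds 0.5
# unconditionally; "none" leaves zeros in place (the OR may then be 0,
# Inf or NaN and the record is flagged non-estimable).
.or_2x2 <- function(a, b, c, d, correction = c("if_any_zero", "none", "always")) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell in 2x2 table")
  corrected <- FALSE
  if ((correction == "if_any_zero" && any(cells == 0)) || correction == "always") {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  estimable <- all(cells > 0)
  log_or <- if (estimable) log((cells[1] / cells[2]) / (cells[3] / cells[4])) else NA_real_
  se_log <- if (estimable) sqrt(sum(1 / cells)) else NA_real_
  list(or = exp(log_or), log_or = log_or, se_log_or = se_log,
       corrected = corrected, estimable = estimable)
}

.or_record <- function(cells, sr_id, comparison, measure, correction) {
  o <- .or_2x2(cells[1], cells[2], cells[3], cells[4], correction)
  out <- tibble::tibble(
    sr_id = as.character(sr_id), comparison = comparison, measure = measure,
    or_value = o$or, log_or = o$log_or, se_log_or = o$se_log_or,
    corrected = o$corrected, estimable = o$estimable)
  class(out) <- c("or_record", class(out))
  out
}

#' Odds ratios between two query versions on the same gold standard
#'
#' For sensitivity, the odds of version *i* are `TP_i / FN_i` (gold items
#' found over gold items missed); for PPV they are `TP_i / FP_i`. The odds
#' ratio of `rec_a` to `rec_b` is the ratio of those odds; when any cell
#' of the 2x2 table is zero the continuity rule adds 0.5 to all four cells
#' (`corrected = TRUE` in the output, selectable to `"always"` or
#' `"none"`). A comparison with an empty gold standard (sensitivity)
#' or an all-zero table is flagged non-estimable.
#'
#' @param rec_a,rec_b `eval_record` rows for the same review and gold
#'   standard (the ratio is a-to-b, e.g. V2 vs V1).
#' @param correction `"if_any_zero"` (default), `"always"` or `"none"`.
#' @return A one-row tibble (`or_record`) with `or_value`, `log_or`,
#'   `se_log_or`, `corrected`, `estimable`.
#' @export
odds_ratio_sensitivity <- function(rec_a, rec_b, correction = "if_any_zero") {
  stopifnot(rec_a$gs_size == rec_b$gs_size)
  rec <- .or_record(c(rec_a$gs_found, rec_a$fn, rec_b$gs_found, rec_b$fn),
                    rec_a$sr_id,
                    paste0(rec_a$version, "_vs_", rec_b$version),
                    "sensitivity", correction)
  if (rec_a$gs_size == 0) rec$estimable <- FALSE
  rec
}

#' @rdname odds_ratio_sensitivity
#' @export
odds_ratio_ppv <- function(rec_a, rec_b, correction = "if_any_zero") {
  .or_record(c(rec_a$gs_found, rec_a$fp, rec_b$gs_found, rec_b$fp),
             rec_a$sr_id,
             paste0(rec_a$version, "_vs_", rec_b$version),
             "ppv", correction)
}

#' Ratio of gold-standard counts between two versions
#'
#' The convention follows the reported distribution: `0/0` counts as 1 (the
#' versions agree in finding nothing) and `x/0` with `x > 0` is `+Inf`.
#'
#' @param found_v1,found_v2 Gold-standard items found by each version.
#' @return Non-negative real, possibly `Inf`.
#' @export
gs_ratio <- function(found_v1, found_v2) {
  stopifnot(found_v1 >= 0, found_v2 >= 0)
  ifelse(found_v1 == 0 & found_v2 == 0, 1, found_v1 / found_v2)
}

#' Reading cost: results screened per gold item found
#'
#' `items / gs_found`; `Inf` when nothing relevant was found. Summaries
#' over reviews keep `Inf` values in the quantiles but drop the degenerate
#' `0/0` case of nonviable queries (see [summarize_versions()]).
#'
#' @param items Number of retrieved items.
#' @param gs_found Gold items among them.
#' @return Non-negative real, possibly `Inf`.
#' @export
reading_cost <- function(items, gs_found) {
  stopifnot(items >= 0, gs_found >= 0)
  ifelse(gs_found == 0, Inf, items / gs_found)
}

#' Wald confidence interval for a proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
wald_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(successes >= 0, successes <= n)
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(lo = max(0, p - half), hi = min(1, p + half))
}
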