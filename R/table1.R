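#' Load the per-review count table
#'
#' Reads a CSV with one row per systematic review: `sr_pmid`, the item
#' counts returned by each query version (`items_v1..items_v3`), the
#' gold-standard size (`gs_size`), the gold items found by each version
#' (`found_v1..found_v3`), and the published 3-decimal `se_*`, `ppv_*`,
#' `f1_*` columns. The shipped fixture
#' (`system.file("extdata", "table1.csv", package = "mesheval")`) carries
#' the 59 reviews of a published comparative evaluation of search
#' strategies.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return A validated tibble (`found <= items`, `found <= gs_size`
#'   rowwise; violations raise an error naming the row).
#' @export
load_table1 <- function(path = system.file("extdata", "table1.csv",
                                           package = "mesheval")) {
  if (!file.exists(path)) stop("table file not found: ", path)
  need <- c("sr_pmid",
            paste0("items_v", 1:3), "gs_size", paste0("found_v", 1:3),
            as.vector(outer(c("se_", "ppv_", "f1_"), paste0("v", 1:3), paste0)))
  rows <- utils::read.csv(path, colClasses = "numeric")
  missing <- setdiff(need, names(rows))
  if (length(missing)) stop("table is missing columns: ", paste(missing, collapse = ", "))
  for (v in paste0("v", 1:3)) {
    bad <- which(rows[[paste0("found_", v)]] > rows[[paste0("items_", v)]] |
                 rows[[paste0("found_", v)]] > rows$gs_size)
    if (length(bad))
      stop("row ", rows$sr_pmid[bad[1]], ": found_", v,
           " exceeds items or gold-standard size")
  }
  tibble::as_tibble(rows)
}

#' Check the printed metrics of the count table against its counts
#'
#' Recomputes sensitivity, PPV and F1 from the counts in each row (with the
#' zero conventions of [score()]) and reports every cell whose printed
#' value differs from the recomputed one by more than `tol`. On the shipped
#' fixture this flags a handful of cells in two rows whose published
#' metrics are internally inconsistent with their own published counts.
#'
#' @param rows A table from [load_table1()].
#' @param tol Tolerance on the 3-decimal cells (default 0.0005, i.e.
#'   printed rounding; a hair of slack absorbs binary representation and
#'   round-half-even prints).
#' @return Tibble of discrepancies: `sr_pmid`, `version`, `metric`,
#'   `printed`, `computed`, `diff` (empty when all cells agree).
#' @export
verify_table1 <- function(rows, tol = 0.0005) {
  out <- list()
  for (v in paste0("v", 1:3)) {
    found <- rows[[paste0("found_", v)]]
    items <- rows[[paste0("items_", v)]]
    se <- ifelse(rows$gs_size > 0, found / rows$gs_size, 0)
    ppv <- ifelse(items > 0, found / items, 0)
    f1 <- ifelse(se + ppv > 0, 2 * se * ppv / (se + ppv), 0)
    for (metric in c("se", "ppv", "f1")) {
      computed <- switch(metric, se = se, ppv = ppv, f1 = f1)
      printed <- rows[[paste0(metric, "_", v)]]
      diff <- abs(computed - printed)
      bad <- which(diff > tol + 1e-9)
      if (length(bad)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          sr_pmid = rows$sr_pmid[bad], version = v, metric = metric,
          printed = printed[bad], computed = round(computed[bad], 6),
          diff = round(diff[bad], 6))
      }
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(sr_pmid = numeric(0), version = character(0),
                          metric = character(0), printed = numeric(0),
                          computed = numeric(0), diff = numeric(0)))
  do.call(rbind, out)
}
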