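t1 <- load_table1(table1_fixture_path())

test_that("the shipped count table loads and validates", {
  expect_equal(nrow(t1), 59)
  row <- t1[t1$sr_pmid == 33472813, ]
  expect_equal(row$items_v1, 297)
  expect_equal(row$gs_size, 30)
  expect_equal(row$found_v1, 27)

  # validator rejects impossible counts, naming the row
  f <- tempfile(fileext = ".csv")
  bad <- t1
  bad$found_v1[1] <- bad$gs_size[1] + 5
  write.csv(bad, f, row.names = FALSE)
  expect_error(load_table1(f), as.character(bad$sr_pmid[1]))

  # truncated file (missing columns) is an error
  f2 <- tempfile(fileext = ".csv")
  write.csv(t1[, 1:5], f2, row.names = FALSE)
  expect_error(load_table1(f2), "missing columns")
})

test_that("metric verification flags only the internally inconsistent cells", {
  d <- verify_table1(t1)
  # two published rows carry metrics that disagree with their own counts;
  # every other cell reproduces to the printed 3 decimals
  expect_setequal(unique(d$sr_pmid), c(32479176, 31727627))
  expect_equal(nrow(d), 8)
  expect_true(all(d$metric %in% c("se", "f1")))
  # a perturbed count surfaces as one extra discrepancy
  t1b <- t1
  t1b$found_v1[3] <- t1b$found_v1[3] - 1
  expect_equal(nrow(verify_table1(t1b)), 8 + 3)  # se, ppv and f1 all move
})

test_that("version summaries use type-7 quantiles and the ratio conventions", {
  sv <- summarize_versions(t1)
  g <- function(v, m) sv[sv$version == v & sv$measure == m, ]
  expect_equal(g("v1", "sensitivity")$median, 77.8, tolerance = 1e-9)
  expect_equal(g("v1", "sensitivity")$q1, 62.15, tolerance = 1e-9)
  expect_equal(g("v2", "items")$median, 1166)
  expect_equal(g("v2", "items")$q1, 301.5)
  expect_equal(g("v2", "items")$q3, 2953)
  # reading cost: 0/0 rows drop out, something/0 stays as +Inf
  expect_equal(g("v1", "reading_cost")$n, 59)
  expect_equal(g("v3", "reading_cost")$n, 48)
  expect_equal(round(g("v3", "reading_cost")$median, 3), 81.305)
  # single review: medians collapse onto the row, IQR degenerate
  one <- summarize_versions(t1[1, ])
  g1 <- one[one$version == "v1" & one$measure == "sensitivity", ]
  expect_equal(c(g1$median, g1$q1, g1$q3), rep(90, 3))
})

test_that("headline statistics recover totals, means and counts", {
  h <- headline_stats(t1)
  expect_identical(h$total_items_v1, 206095)
  expect_identical(h$total_found_v1, 1628)
  expect_identical(h$total_items_v2, 157698)
  expect_identical(h$total_found_v2, 1473)
  expect_equal(h$n_impacted, 24)
  expect_equal(h$n_ratio_le_1, 35)
  expect_equal(h$n_ratio_le_1_05, 39)
  expect_equal(h$n_ratio_infinite, 2)
  expect_equal(h$n_v3_zero_items, 11)
  expect_equal(h$mean_extra_screened_2dp, 820.29)
  # no relevant article lost anywhere: impact count zero
  same <- t1
  same$found_v1 <- same$found_v2
  expect_equal(headline_stats(same)$n_impacted, 0)
})

test_that("random-effects pooling matches closed forms and is stable", {
  # identical tables: pooled OR 1, no heterogeneity
  id <- tibble::tibble(a = rep(10, 5), b = rep(20, 5),
                       c = rep(10, 5), d = rep(20, 5))
  for (w in c("equal", "inverse_variance")) {
    p <- pool_log_odds_ratios(id, weights = w)
    expect_equal(p$pooled_or, 1)
    expect_equal(p$tau2, 0)
    expect_equal(p$k, 5)
  }

  # equal weights: the pooled log OR is the plain mean of the log ORs
  tabs <- or_tables(t1, "v2_vs_v1", "sensitivity")
  m <- as.matrix(tabs[, c("a", "b", "c", "d")])
  z <- apply(m == 0, 1, any)
  m[z, ] <- m[z, ] + 0.5
  mean_log <- mean(log((m[, 1] / m[, 2]) / (m[, 3] / m[, 4])))
  p_eq <- pool_log_odds_ratios(tabs, weights = "equal")
  expect_equal(log(p_eq$pooled_or), mean_log, tolerance = 1e-10)

  # DerSimonian-Laird inverse-variance pooling matches the closed form
  withr::local_seed(43)
  toy <- tibble::tibble(a = c(12, 30), b = c(18, 10), c = c(9, 22), d = c(21, 18))
  p_dl <- pool_log_odds_ratios(toy, estimator = "DL",
                               weights = "inverse_variance")
  o <- dl_pool_oracle(toy)
  expect_equal(p_dl$pooled_or, o$pooled_or, tolerance = 1e-10)
  expect_equal(p_dl$tau2, o$tau2, tolerance = 1e-10)
  larger <- tibble::tibble(a = sample(5:40, 8), b = sample(5:40, 8),
                           c = sample(5:40, 8), d = sample(5:40, 8))
  expect_equal(pool_log_odds_ratios(larger, estimator = "DL",
                                    weights = "inverse_variance")$pooled_or,
               dl_pool_oracle(larger)$pooled_or, tolerance = 1e-10)

  # order invariance and the tau2 >= 0 guarantee
  shuffled <- tabs[sample(nrow(tabs)), ]
  p_sh <- pool_log_odds_ratios(shuffled)
  expect_equal(p_sh$pooled_or, p_eq$pooled_or, tolerance = 1e-12)
  expect_gte(p_sh$tau2, 0)

  # fewer than two estimable tables cannot be pooled
  expect_error(pool_log_odds_ratios(id[1, ]), "at least two")
})

test_that("forest data pairs per-review ORs with the pooled row", {
  fd <- forest_data(t1, "v2_vs_v1", "ppv")
  expect_lte(nrow(fd$per_sr), 59)
  expect_s3_class(fd$pooled, "pooled_or")
  expect_true(all(fd$per_sr$lo <= fd$per_sr$or & fd$per_sr$or <= fd$per_sr$hi))
  # single review: the forest is that review and pooling refuses
  expect_error(forest_data(t1[1, ], "v2_vs_v1", "ppv"), "at least two")

  # swapping the two versions inverts every uncorrected per-review OR
  swapped <- t1
  swapped$found_v2 <- t1$found_v1; swapped$found_v1 <- t1$found_v2
  swapped$items_v2 <- t1$items_v1; swapped$items_v1 <- t1$items_v2
  fd_rev <- forest_data(swapped, "v2_vs_v1", "ppv")
  both <- merge(fd$per_sr, fd_rev$per_sr, by = "sr_id")
  keep <- !both$corrected.x & !both$corrected.y
  expect_gt(sum(keep), 40)
  expect_equal(both$or.x[keep], 1 / both$or.y[keep], tolerance = 1e-12)
})
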