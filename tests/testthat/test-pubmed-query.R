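test_that("the journal-selection query parses into the expected structure", {
  q <- parse_query(paste(
    '("The New England Journal of Medicine"[Journal] OR "Lancet London England"[Journal]',
    'OR "JAMA"[Journal] OR "Nature Reviews Disease Primers"[Journal]',
    'OR "BMJ Clinical Research Ed"[Journal] OR "Annals of Internal Medicine"[Journal])',
    'AND "loattrfree full text"[Filter] AND 2012/01/01:2021/12/31[Date - Publication]',
    'AND systematic review[Filter]'))
  expect_s3_class(q, "pm_bool")
  expect_equal(q$op, "AND")
  expect_length(q$children, 4)
  expect_equal(q$children[[1]]$op, "OR")
  expect_length(q$children[[1]]$children, 6)
  expect_true(all(vapply(q$children[[1]]$children, function(t) t$tag,
                         character(1)) == "JOURNAL"))
  expect_s3_class(q$children[[3]], "pm_date_range")
  expect_equal(q$children[[3]]$start, as.Date("2012-01-01"))
  expect_equal(q$children[[3]]$end, as.Date("2021-12-31"))
  # 6 journal terms + 2 filter terms; the date range is not a term
  expect_equal(count_terms(q), 8L)
  expect_equal(count_terms(q, "JOURNAL"), 6L)
  expect_equal(count_terms(q, "MESH"), 0L)
  # round trip preserves the tree
  expect_identical(parse_query(serialize_query(q)), q)
})

test_that("parser handles tags, phrases, NOT, and date ranges", {
  q <- parse_query('"JAMA"[Journal] AND systematic review[Filter]')
  expect_identical(q, pm_bool("AND", list(
    pm_term("JAMA", "JOURNAL", quoted = TRUE),
    pm_term("systematic review", "FILTER"))))

  d <- parse_query('2012/01/01:2021/12/31[Date - Publication]')
  expect_identical(d, pm_date_range("2012/01/01", "2021/12/31"))
  # partial dates widen to the period
  d2 <- parse_query('2012:2014[dp]')
  expect_identical(d2, pm_date_range("2012/01/01", "2014/12/31"))

  expect_identical(parse_query("a[tiab]"), pm_term("a", "TITLE_ABSTRACT"))

  q3 <- parse_query("(x[mh] OR y[tiab]) NOT z[tiab]")
  expect_identical(q3, pm_bool("NOT", list(
    pm_bool("OR", list(pm_term("x", "MESH"), pm_term("y", "TITLE_ABSTRACT"))),
    pm_term("z", "TITLE_ABSTRACT"))))

  # untagged bare terms get ALL_FIELDS plus the untagged flag
  u <- parse_query("hypertension")
  expect_equal(u$tag, "ALL_FIELDS")
  expect_true(u$untagged)

  # equal precedence, left to right, as the search engine applies it
  q4 <- parse_query("a[tiab] OR b[tiab] AND c[tiab]")
  expect_equal(q4$op, "AND")
  expect_equal(q4$children[[1]]$op, "OR")
})

test_that("tag spellings are case-insensitive synonyms of one class", {
  same <- list(
    MESH = c("[MeSH Terms]", "[Mesh]", "[mh]", "[MESH]"),
    TITLE_ABSTRACT = c("[Title/Abstract]", "[tiab]", "[TIAB]"),
    MESH_NOEXP = c("[Mesh:NoExp]", "[mh:noexp]"),
    MESH_MAJOR = c("[Majr]", "[MeSH Major Topic]"),
    ALL_FIELDS = c("[All Fields]", "[all]"),
    JOURNAL = c("[Journal]", "[ta]"),
    FILTER = c("[Filter]", "[sb]"),
    PUBLICATION_TYPE = c("[pt]", "[Publication Type]"))
  for (cls in names(same)) {
    for (sp in same[[cls]]) {
      expect_equal(parse_query(paste0("x", sp))$tag, cls, label = sp)
    }
  }
})

test_that("malformed queries raise errors naming the position or tag", {
  expect_error(parse_query("(a[tiab] OR b[tiab]"), "unbalanced parenthesis")
  expect_error(parse_query('"unterminated[tiab]'), "unbalanced quote")
  expect_error(parse_query("b[NotATag]"), "unknown field tag.*known tags")
  expect_error(parse_query("NOT a[tiab]"), "unary NOT")
  expect_error(parse_query("   "), "empty query")
  expect_error(parse_query("a[tiab] AND"), "unexpected end")
})

test_that("serialization uses canonical spellings and minimal parentheses", {
  expect_equal(serialize_query(pm_term("humans", "MESH")), "humans[MeSH Terms]")
  flat <- pm_bool("OR", list(pm_term("a", "TITLE_ABSTRACT"),
                             pm_term("b", "MESH"),
                             pm_term("c", "JOURNAL")))
  s <- serialize_query(flat)
  expect_false(grepl("(", s, fixed = TRUE))
  expect_identical(parse_query(s), flat)
  expect_warning(out <- serialize_query(pm_empty()), "EMPTY")
  expect_equal(out, "")
})

test_that("parse/serialize round-trips on generated trees", {
  withr::local_seed(20240601)
  for (i in 1:200) {
    q <- gen_query(3)
    expect_identical(parse_query(serialize_query(q)), q)
  }
})

test_that("automatic term mapping expands untagged terms and is idempotent", {
  vocab <- make_test_vocab()
  e <- atm_expand(parse_query("hypertension"), vocab)
  expect_identical(e, pm_bool("OR", list(
    pm_term("hypertension", "MESH"),
    pm_term("hypertension", "ALL_FIELDS"))))
  # vocabulary miss keeps only the all-fields branch
  miss <- atm_expand(parse_query("notarealterm"), vocab)
  expect_identical(miss, pm_term("notarealterm", "ALL_FIELDS"))
  # fully tagged queries pass through unchanged
  tagged <- parse_query("hypertension[mh] AND trial[tiab]")
  expect_identical(atm_expand(tagged, vocab), tagged)
  # idempotence on random trees
  withr::local_seed(42)
  for (i in 1:25) {
    q <- gen_query(3)
    once <- atm_expand(q, vocab)
    expect_identical(atm_expand(once, vocab), once)
  }
})

test_that("count_terms restricts by tag class and ignores non-term nodes", {
  expect_equal(count_terms(pm_empty()), 0L)
  q <- pm_bool("OR", list(pm_term("a", "MESH"), pm_term("b", "TITLE_ABSTRACT")))
  expect_equal(count_terms(q, "MESH"), 1L)
  expect_equal(count_terms(q, "ANY"), 2L)
  expect_error(count_terms(q, "NOT_A_TAG"), "unknown tag class")
})
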