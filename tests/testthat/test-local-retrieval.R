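vocab <- make_test_vocab()

test_that("MEDLINE flat files parse records, headings and dates", {
  f <- tempfile(fileext = ".txt")
  writeLines(c(
    "PMID- 101",
    "TI  - Effect of famotidine on gastric ulcers in",
    "      a randomized trial",
    "AB  - We studied famotidine.",
    "JT  - Journal of Synthetic Medicine",
    "DP  - 2015 Mar 12",
    "MH  - *Hypertension/drug therapy",
    "MH  - Famotidine",
    "PT  - Systematic Review",
    "",
    "PMID- 102",
    "TI  - Second record",
    "DP  - 2019"), f)
  docs <- read_medline(f)
  expect_equal(nrow(docs), 2)
  expect_equal(docs$pmid, c(101L, 102L))
  # continuation line folded into the title
  expect_match(docs$title[1], "ulcers in a randomized trial")
  h <- docs$mesh_headings[[1]]
  expect_equal(h$term, c("Hypertension", "Famotidine"))
  expect_equal(h$major, c(TRUE, FALSE))
  expect_equal(docs$filters[[1]], "systematic review")
  expect_equal(docs$pub_date, as.Date(c("2015-03-12", "2019-01-01")))

  # a record without PMID is an error
  bad <- tempfile()
  writeLines(c("TI  - No id here"), bad)
  expect_error(read_medline(bad), "without PMID")

  # an unparseable date keeps the record with a sentinel
  odd <- tempfile()
  writeLines(c("PMID- 7", "TI  - x", "DP  - in press"), odd)
  expect_warning(d2 <- read_medline(odd), "cannot parse DP")
  expect_true(is.na(d2$pub_date[1]))
})

test_that("JSONL corpus round-trips all fields", {
  withr::local_seed(23)
  docs <- gen_corpus(12, vocab)
  f <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(docs, f)
  back <- read_corpus_jsonl(f)
  expect_equal(as.data.frame(back), as.data.frame(docs))
})

test_that("term matching honors field semantics and explosion", {
  doc <- corpus(
    pmid = 1, title = "Effect of famotidine on blood pressure",
    abstract = "A controlled study.", journal = "Gamma Reports",
    pub_date = as.Date("2016-01-01"),
    mesh_headings = list(data.frame(term = "Hypertension, Renal", major = FALSE)),
    filters = list("systematic review"))
  expect_true(match_term(doc, pm_term("famotidine", "TITLE_ABSTRACT"), vocab))
  expect_true(match_term(doc, pm_term("blood pressure", "TITLE"), vocab))
  expect_false(match_term(doc, pm_term("pressure blood", "TITLE"), vocab))
  expect_false(match_term(doc, pm_term("controlled", "TITLE"), vocab))
  expect_true(match_term(doc, pm_term("controlled", "TEXT_WORD"), vocab))
  # heading is a child of Hypertension: explosion finds it, NoExp does not
  expect_true(match_term(doc, pm_term("hypertension", "MESH"), vocab))
  expect_false(match_term(doc, pm_term("hypertension", "MESH_NOEXP"), vocab))
  expect_false(match_term(doc, pm_term("hypertension", "MESH_MAJOR"), vocab))
  # entry term resolves to the same descriptor
  expect_true(match_term(doc, pm_term("high blood pressure", "MESH"), vocab))
  # a term absent from the thesaurus matches nothing as MeSH
  expect_false(match_term(doc, pm_term("famotidine trial", "MESH"), vocab))
  expect_true(match_term(doc, pm_term("Gamma Reports", "JOURNAL"), vocab))
  expect_true(match_term(doc, pm_term("systematic review", "FILTER"), vocab))
  expect_true(match_term(doc, pm_term("famotidine", "ALL_FIELDS"), vocab))
  expect_true(match_term(doc, pm_term("gamma reports", "ALL_FIELDS"), vocab))
})

test_that("set semantics, dates, cap and ranking behave deterministically", {
  docs <- corpus(
    pmid = 1:5,
    title = c("alpha beta", "alpha", "beta", "gamma", "alpha beta gamma"),
    abstract = "", journal = "J",
    pub_date = as.Date(c("2012-05-01", "2013-05-01", "2020-05-01",
                         "2021-05-01", NA)))
  expect_equal(evaluate_query(docs, pm_empty(), vocab)$total_matched, 0)
  r <- evaluate_query(docs, parse_query("alpha[tiab] OR gamma[tiab]"), vocab)
  expect_setequal(r$pmids, c(1, 2, 4, 5))
  expect_false(r$capped)
  # ranking: most distinct leaves matched first, then pmid
  expect_equal(r$pmids, c(5L, 1L, 2L, 4L))
  # cap truncates after ranking
  rc <- evaluate_query(docs, parse_query("alpha[tiab] OR gamma[tiab]"), vocab,
                       cap = 2)
  expect_true(rc$capped)
  expect_equal(rc$total_matched, 4)
  expect_equal(rc$pmids, c(5L, 1L))
  # sentinel dates fail all date filters
  rd <- evaluate_query(docs, parse_query("alpha[tiab] AND 2012:2019[dp]"), vocab)
  expect_setequal(rd$pmids, c(1, 2))
  # NOT is left minus right
  rn <- evaluate_query(docs, parse_query("alpha[tiab] NOT beta[tiab]"), vocab)
  expect_setequal(rn$pmids, 2)
})

test_that("boolean retrieval agrees with the per-document oracle", {
  withr::local_seed(29)
  for (i in 1:120) {
    docs <- gen_corpus(sample(5:50, 1), vocab)
    q <- gen_query(3)
    expect_setequal(evaluate_query(docs, q, vocab)$pmids,
                    oracle_retrieve(docs, q, vocab))
  }
})

test_that("adding an OR branch never shrinks, an AND branch never grows", {
  withr::local_seed(31)
  for (i in 1:40) {
    docs <- gen_corpus(30, vocab)
    q <- gen_query(2)
    extra <- gen_term()
    base <- evaluate_query(docs, q, vocab)$pmids
    wider <- evaluate_query(docs, pm_bool("OR", list(q, extra)), vocab)$pmids
    narrower <- evaluate_query(docs, pm_bool("AND", list(q, extra)), vocab)$pmids
    expect_true(all(base %in% wider))
    expect_true(all(narrower %in% base))
  }
})
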