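test_that("parse_jats_record extracts abstract, ISSNs and date", {
  rec <- parse_jats_record(jats_xml(long_abstract(250), eissn = "2000-0020"))
  expect_s3_class(rec, "tbl_df")
  expect_equal(rec$paper_id, "PMC0001")
  expect_equal(nchar(rec$abstract_text), 250)
  expect_equal(rec$issn_print, "2000-0019")
  expect_equal(rec$issn_electronic, "2000-0020")
  expect_equal(rec$pub_year, 2012L)
  expect_equal(rec$pub_month, 4L)
})

test_that("parse_jats_record rejects with machine-readable reason codes", {
  no_abs <- parse_jats_record(jats_xml(NULL))
  expect_s3_class(no_abs, "paper_rejection")
  expect_equal(no_abs$reason, "no_abstract")

  short <- parse_jats_record(jats_xml(long_abstract(150)))
  expect_equal(short$reason, "short_abstract")

  no_issn <- parse_jats_record(jats_xml(long_abstract(250), pissn = NULL))
  expect_equal(no_issn$reason, "no_issn")

  bad <- parse_jats_record("<article><front>")
  expect_equal(bad$reason, "malformed")
})

test_that("missing month defaults to January and whitespace is normalised", {
  xml <- paste0(
    "<article><front><article-meta>",
    "<issn pub-type='ppub'>2000-0019</issn>",
    "<pub-date><year>2010</year></pub-date>",
    "<abstract><p>", gsub(" ", "\n  ", long_abstract(260)),
    "</p></abstract></article-meta></front></article>"
  )
  rec <- parse_jats_record(xml)
  expect_equal(rec$pub_month, 1L)
  expect_false(grepl("\\s{2,}", rec$abstract_text))
})

test_that("filter_corpus applies the three rules with conservation", {
  recs <- toy_records(c(150, 50))
  out <- filter_corpus(recs)
  expect_setequal(unique(out$records$journal_label), "J01")
  expect_equal(nrow(out$records) + nrow(out$log), nrow(recs))
  expect_true(all(out$log$rule == "small_journal"))

  # out-of-range dates are removed under the default window
  recs2 <- toy_records(c(150))
  recs2$pub_year[1] <- 2006L
  recs2$pub_year[2] <- 2017L; recs2$pub_month[2] <- 5L
  out2 <- filter_corpus(recs2)
  expect_equal(sort(out2$log$paper_id), c("P0001", "P0002"))
  expect_true(all(out2$log$rule == "date_range"))
})

test_that("journal filter runs after abstract filters (no fixpoint)", {
  recs <- toy_records(c(105))
  recs$abstract_text[1:10] <- long_abstract(150)
  out <- filter_corpus(recs, min_journal_papers = 100)
  # 95 survivors < 100: the whole journal goes
  expect_equal(nrow(out$records), 0)
  expect_equal(sum(out$log$rule == "short_abstract"), 10)
  expect_equal(sum(out$log$rule == "small_journal"), 95)
})

test_that("filtering is idempotent and empty input yields empty output", {
  recs <- toy_records(c(150, 120))
  once <- filter_corpus(recs)
  twice <- filter_corpus(once$records)
  expect_identical(twice$records, once$records)
  expect_equal(nrow(twice$log), 0)

  none <- filter_corpus(recs[0, ])
  expect_equal(nrow(none$records), 0)
  expect_equal(nrow(none$log), 0)
})

test_that("catalog maps both ISSNs to one label with counts and bins", {
  recs <- toy_records(c(300, 15000))
  cat <- build_journal_catalog(recs)
  expect_equal(cat$journals$paper_count, c(300L, 15000L))
  expect_equal(as.character(cat$journals$size_bin), c("tiny", "large"))
  # both print and electronic ISSN of journal 1 resolve to the same label
  hits <- cat$issn_map$journal_label[cat$issn_map$issn %in% c("1000-0001", "2000-0001")]
  expect_equal(unique(hits), "J01")
  # counts match the label multiset of the records
  expect_equal(
    cat$journals$paper_count,
    as.integer(table(recs$journal_label)[cat$journals$journal_label])
  )
})

test_that("size bins follow the 400 / 2000 / 10000 boundaries", {
  expect_equal(
    as.character(size_bin_of(c(100, 400, 401, 2000, 2001, 10000, 10001))),
    c("tiny", "tiny", "small", "small", "medium", "medium", "large")
  )
})

test_that("an ISSN shared by two journals is an ambiguous catalog error", {
  recs <- toy_records(c(120, 120))
  recs$issn_print[recs$journal_label == "J02"] <- "1000-0001"
  expect_error(build_journal_catalog(recs), "ambiguous")
})

test_that("split_corpus is a deterministic disjoint cover with rounded sizes", {
  recs <- toy_records(c(100))
  s1 <- split_corpus(recs, seed = 7)
  s2 <- split_corpus(recs, seed = 7)
  expect_identical(s1$split, s2$split)
  expect_equal(as.integer(table(s1$split)), c(80L, 10L, 10L))
  expect_equal(sum(table(s1$split)), nrow(recs))
  s3 <- split_corpus(recs, seed = 8)
  expect_false(identical(s1$split, s3$split))
})

test_that("split_corpus validates fractions and corpus size", {
  recs <- toy_records(c(10))
  expect_error(split_corpus(recs, fractions = c(0.7, 0.1, 0.1)), "sum to 1")
  expect_error(split_corpus(recs[1:2, ]), "at least 3")
})

test_that("records and catalog round-trip through their text formats", {
  recs <- toy_records(c(5))
  recs$issn_electronic[2] <- NA_character_
  path <- withr::local_tempfile(fileext = ".ndjson")
  write_records(recs, path)
  expect_equal(read_records(path), recs)

  cat <- build_journal_catalog(toy_records(c(300, 5000)))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, cpath)
  back <- read_catalog(cpath)
  expect_equal(back$journals, cat$journals)
  expect_setequal(back$issn_map$issn, cat$issn_map$issn)
})

test_that("resolve_journal_labels rejects unmapped ISSNs with no_issn", {
  recs <- toy_records(c(3, 2))
  jl <- tibble::tibble(issn = c("1000-0001", "2000-0001"), journal_label = "NLM1")
  out <- resolve_journal_labels(dplyr::select(recs, -"journal_label"), jl)
  expect_equal(nrow(out$records), 3)
  expect_equal(unique(out$records$journal_label), "NLM1")
  expect_equal(nrow(out$rejections), 2)
  expect_true(all(out$rejections$reason == "no_issn"))
})
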