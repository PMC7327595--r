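# MEDLINE XML parsing, fixture round-trip, filtering, per-window summaries.

medline_xml <- function(articles) {
  paste0('<?xml version="1.0"?>\n<PubmedArticleSet>', articles,
         "</PubmedArticleSet>")
}

article_xml <- function(pmid, pubdate, title = "A title",
                        abstract = "An abstract.", lang = "eng",
                        ptype = "Journal Article",
                        journal = "Journal of Examples",
                        authors = '<Author><LastName>Smith</LastName><ForeName>Ann B</ForeName><Initials>AB</Initials></Author>') {
  sprintf('<PubmedArticle><MedlineCitation><PMID>%s</PMID><Article>
    <Journal><Title>%s</Title><JournalIssue><PubDate>%s</PubDate></JournalIssue></Journal>
    <ArticleTitle>%s</ArticleTitle>
    <Abstract><AbstractText>%s</AbstractText></Abstract>
    <AuthorList>%s</AuthorList>
    <Language>%s</Language>
    <PublicationTypeList><PublicationType>%s</PublicationType></PublicationTypeList>
    </Article></MedlineCitation></PubmedArticle>',
    pmid, journal, pubdate, title, abstract, authors, lang, ptype)
}

test_that("MEDLINE XML parsing maps fields and resolves years", {
  xml <- medline_xml(paste0(
    article_xml("101", "<Year>1999</Year><Month>Jan</Month>"),
    article_xml("102", "<Year>2003</Year>")))
  corp <- parse_medline_xml(xml)
  expect_equal(nrow(corp$records), 2)
  expect_equal(corp$span, c(1999, 2003))
  expect_equal(corp$records$pmid, c("101", "102"))
  expect_equal(corp$records$title[1], "A title")
  expect_equal(corp$records$authors[[1]]$surname, "Smith")

  # MedlineDate-style free-text dates resolve to their leading year
  corp2 <- parse_medline_xml(medline_xml(
    article_xml("7", "<MedlineDate>1951 Jan-Feb</MedlineDate>")))
  expect_equal(corp2$records$year, 1951L)

  # unresolvable years are dropped and counted
  corp3 <- parse_medline_xml(medline_xml(paste0(
    article_xml("1", "<Year>1980</Year>"),
    article_xml("2", "<MedlineDate>n.d.</MedlineDate>"))))
  expect_equal(nrow(corp3$records), 1)
  expect_equal(corp3$report$no_year, 1L)

  expect_equal(nrow(parse_medline_xml(medline_xml(""))$records), 0)
  expect_error(parse_medline_xml("<PubmedArticleSet><oops"),
               "malformed")
  expect_error(parse_medline_xml(medline_xml(paste0(
    article_xml("9", "<Year>1980</Year>"),
    article_xml("9", "<Year>1981</Year>")))), "duplicate pmid.*9")
})

test_that("fixture round-trip is lossless and validates fields", {
  corp <- mk_corpus(
    rec("1", 1999, title = "Tïtle–one", abstract = "Text body",
        authors = data.frame(surname = "García", given = "María J",
                             initials = "MJ", stringsAsFactors = FALSE),
        pub_types = c("Journal Article", "Review")),
    rec("2", 2003, journal = "Another Journal", language = "fre"))
  path <- withr::local_tempfile()
  write_fixture(corp, path)
  back <- read_fixture(path)
  expect_identical(back$records, corp$records)
  expect_identical(back$span, corp$span)

  # stability: writing the read-back corpus reproduces the bytes
  path2 <- withr::local_tempfile()
  write_fixture(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # missing required field is an error naming line and field
  lines <- readLines(path)
  bad <- sub('"journal":"[^"]*",', "", lines[2])
  writeLines(c(lines[1], bad), path2)
  expect_error(read_fixture(path2), "line 2.*journal")

  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_fixture(empty)$records), 0)
})

test_that("record filtering applies type and language rules idempotently", {
  corp <- mk_corpus(
    rec("1", 2000),
    rec("2", 2000, pub_types = "Letter"),
    rec("3", 2001, language = "fre"),
    rec("4", 2002, pub_types = c("Journal Article", "Editorial")))
  f <- filter_records(corp)
  expect_equal(f$records$pmid, "1")
  expect_equal(f$report$Letter, 1L)
  expect_equal(f$report$Editorial, 1L)
  expect_equal(f$report$language, 1L)

  # idempotence
  f2 <- filter_records(f)
  expect_identical(f2$records, f$records)

  # all-pass corpus comes back unchanged
  ok <- mk_corpus(rec("1", 2000), rec("2", 2001))
  expect_identical(filter_records(ok)$records, ok$records)

  # exclusion report CSV
  path <- withr::local_tempfile()
  write_exclusion_report(f, path)
  tab <- read.csv(path)
  expect_setequal(tab$rule, c("Letter", "Editorial", "language"))
  expect_equal(sum(tab$count), 3)
})

test_that("corpus summary counts publications, authors and journals per window", {
  corp <- mk_corpus(
    rec("1", 2001, authors = au("Aa"), journal = "J1"),
    rec("2", 2003, authors = au("Aa", "Bb", "Cc"), journal = "J2"),
    rec("3", 2007, authors = au("Aa"), journal = "J1"))
  w <- make_windows(c(2001, 2010), 5)
  s <- corpus_summary(corp, w)
  expect_equal(s$publications, c(2, 1))
  expect_equal(s$mean_authors[1], 2.0)   # (1 + 3) / 2
  expect_equal(s$authors, c(3, 1))       # distinct within window
  expect_equal(s$journals, c(2, 1))

  # window with no publications: zero counts, missing mean
  s2 <- corpus_summary(corp, make_windows(c(2011, 2015), 5))
  expect_equal(s2$publications, 0)
  expect_true(is.na(s2$mean_authors))
})

test_that("publication counts are additive and distinct counts sub-additive over partitions", {
  syn <- random_synthetic(seed = 11, n_windows = 4, m_w = 30)
  corp <- syn$corpus
  coarse <- make_windows(c(2000, 2019), 10)
  fine <- make_windows(c(2000, 2019), 5)
  sc <- corpus_summary(corp, coarse)
  sf <- corpus_summary(corp, fine)
  expect_equal(sc$publications[1], sum(sf$publications[1:2]))
  expect_equal(sc$publications[2], sum(sf$publications[3:4]))
  expect_lte(sc$authors[1], sum(sf$authors[1:2]))
  expect_lte(sc$journals[2], sum(sf$journals[3:4]))
})

test_that("corpus construction rejects duplicate pmids and sorts records", {
  expect_error(mk_corpus(rec("1", 2000), rec("1", 2001)), "duplicate pmid")
  corp <- mk_corpus(rec("9", 2005), rec("2", 2001), rec("1", 2005))
  expect_equal(corp$records$pmid, c("2", "1", "9"))
})
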