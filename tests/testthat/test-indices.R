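# Windowing and the four index computations.

test_that("windowing cuts a span into fixed-width windows with a truncated tail", {
  w <- make_windows(c(1951, 2018), 5)
  expect_equal(nrow(w), 14)
  expect_equal(w$label[1], "1951-1955")
  expect_equal(w$label[14], "2016-2018")
  expect_equal(w$end_year[14] - w$start_year[14] + 1, 3)
  # contiguity and coverage
  expect_equal(w$start_year[-1], w$end_year[-14] + 1)

  expect_equal(make_windows(c(2000, 2004), 5)$label, "2000-2004")
  expect_equal(make_windows(c(2000, 2001), 5)$label, "2000-2001")
  expect_error(make_windows(c(2000, 2010), 0), "width")
  expect_error(make_windows(c(2010, 2000), 5), "span")
})

test_that("elementary indices compute ratios and return NA when undefined", {
  expect_equal(p1_index(25, 200), 12.5)
  expect_equal(p1_index(0, 10), 0)
  expect_equal(p1_index(10, 10), 100)
  expect_true(is.na(p1_index(0, 0)))

  expect_equal(p2_index(16, 100, 10, 100), 0.06)
  expect_equal(p2_index(5, 100, 20, 100), -0.15)
  expect_equal(p2_index(10, 100, 10, 100), 0)
  expect_true(is.na(p2_index(1, 0, 1, 10)))

  expect_equal(p3_index(1, 4), 25)
  expect_equal(p3_index(4, 4), 100)
  expect_equal(p3_index(0, 4), 0)
  expect_true(is.na(p3_index(0, 0)))

  expect_equal(ci_index(11, 200), 5.5)
  expect_equal(ci_index(200, 200), 100)
  expect_true(is.na(ci_index(0, 0)))
})

test_that("window counts match a brute-force recount on synthetic corpora", {
  for (seed in c(2, 17)) {
    syn <- random_synthetic(seed, n_windows = 3, m_w = 30)
    idx <- build_mention_index(syn$corpus, syn$lexicon)
    for (ent in c("D1", "X1")) {
      for (i in seq_len(nrow(syn$spec$windows))) {
        w <- syn$spec$windows[i, ]
        got <- count_window(syn$corpus, idx, ent, w, syn$top_journals)
        want <- oracle_count_window(syn$corpus, syn$lexicon, ent, w,
                                    syn$top_journals)
        expect_equal(got$n_i, want$n_i)
        expect_equal(got$n_T, want$n_T)
        expect_equal(got$n_H20, want$n_H20)
        expect_equal(got$n_AI, want$n_AI)
        expect_equal(got$n_AT, want$n_AT)
      }
    }
  }
})

test_that("index table handles constant corpora, thresholds and missing cells", {
  lex <- as_lexicon(data.frame(
    entity_id = "D1", entity_type = "drug", canonical_name = "alphagen",
    synonyms = "alphagen"))
  # entity present in every record of every window
  corp <- mk_corpus(
    rec("1", 2000, abstract = "alphagen", authors = au("Aa")),
    rec("2", 2002, abstract = "alphagen", authors = au("Aa")),
    rec("3", 2005, abstract = "alphagen", authors = au("Bb")),
    rec("4", 2008, abstract = "alphagen", authors = au("Cc")))
  w <- make_windows(c(2000, 2009), 5)
  idx <- build_mention_index(corp, lex)
  tab <- compute_index_table(corp, idx, w, top_journals = character(0))
  expect_equal(tab$p1, c(100, 100))
  expect_equal(tab$ci, c(100, 100))
  expect_true(is.na(tab$p2[1]))   # no pre-span records
  expect_equal(tab$p2[2], 0)
  expect_equal(tab$p3, c(0, 0))
  expect_equal(tab$p3_flag, c(FALSE, FALSE))

  # inclusive threshold: p3 exactly at the threshold is flagged
  corp2 <- mk_corpus(
    rec("1", 2000, abstract = "alphagen", journal = "Top J"),
    do.call(rbind, lapply(2:20, function(i)
      rec(as.character(i), 2000, abstract = "alphagen", journal = "Other"))))
  idx2 <- build_mention_index(corp2, lex)
  tab2 <- compute_index_table(corp2, idx2, make_windows(c(2000, 2004), 5),
                              top_journals = "Top J")
  expect_equal(tab2$p3, 5)
  expect_true(tab2$p3_flag)

  # undefined cells are NA, never zero: entity absent from a window
  lex3 <- as_lexicon(data.frame(
    entity_id = "Z", entity_type = "gene", canonical_name = "zebragene",
    synonyms = "zebragene"))
  idx3 <- build_mention_index(corp, lex3)
  tab3 <- compute_index_table(corp, idx3, w, character(0))
  expect_equal(tab3$n_i, c(0, 0))
  expect_true(all(is.na(tab3$p3)))
  expect_true(all(is.na(tab3$p3_flag)))
  expect_equal(tab3$p1, c(0, 0))  # p1 is defined (0), p3 is not
})

test_that("first-window P2 uses pre-span records when the corpus has them", {
  lex <- as_lexicon(data.frame(
    entity_id = "D1", entity_type = "drug", canonical_name = "alphagen",
    synonyms = "alphagen"))
  # pre-span 1995-1999: 1 of 2 records mention; first window: 2 of 2
  corp <- mk_corpus(
    rec("1", 1996, abstract = "alphagen"),
    rec("2", 1998, abstract = "none"),
    rec("3", 2000, abstract = "alphagen"),
    rec("4", 2003, abstract = "alphagen"))
  w <- make_windows(c(2000, 2004), 5)
  idx <- build_mention_index(corp, lex)
  tab <- compute_index_table(corp, idx, w, character(0))
  expect_equal(tab$p2[1], 1 - 0.5)
})

test_that("truncated final windows get no P2 and the table ignores record order", {
  syn <- random_synthetic(seed = 5, n_windows = 3, m_w = 20)
  corp <- syn$corpus
  idx <- build_mention_index(corp, syn$lexicon)
  w13 <- make_windows(c(2000, 2012), 5)  # last window 2010-2012, width 3
  tab <- compute_index_table(corp, idx, w13, syn$top_journals)
  last <- tab[tab$label == "2010-2012", ]
  expect_true(all(is.na(last$p2)))

  # permuting records leaves the table unchanged
  recs <- corp$records
  set.seed(9)
  shuffled <- as_corpus(recs[sample(nrow(recs)), ])
  idx2 <- build_mention_index(shuffled, syn$lexicon)
  tab2 <- compute_index_table(shuffled, idx2, w13, syn$top_journals)
  expect_equal(tab, tab2)
})

test_that("index values stay in range and P2 telescopes on fuzzed corpora", {
  for (seed in c(21, 22, 23)) {
    syn <- random_synthetic(seed, n_windows = 5, m_w = 30)
    idx <- build_mention_index(syn$corpus, syn$lexicon)
    tab <- compute_index_table(syn$corpus, idx, syn$spec$windows,
                               syn$top_journals)
    for (col in c("p1", "p3", "ci")) {
      v <- tab[[col]][!is.na(tab[[col]])]
      expect_true(all(v >= 0 & v <= 100))
    }
    p2v <- tab$p2[!is.na(tab$p2)]
    expect_true(all(p2v >= -1 & p2v <= 1))
    # telescoping: sum of P2 equals the change in the popularity fraction
    for (ent in unique(tab$entity_id)) {
      sub <- tab[tab$entity_id == ent, ]
      sub <- sub[order(sub$start_year), ]
      expect_equal(sum(sub$p2[-1]),
                   sub$p1[nrow(sub)] / 100 - sub$p1[1] / 100,
                   tolerance = 1e-12)
    }
  }
})

test_that("index CSV export writes missing cells as empty fields", {
  syn <- random_synthetic(seed = 31, n_windows = 2, m_w = 15)
  idx <- build_mention_index(syn$corpus, syn$lexicon)
  tab <- compute_index_table(syn$corpus, idx, syn$spec$windows,
                             syn$top_journals)
  path <- withr::local_tempfile()
  write_index_csv(tab, path)
  txt <- readLines(path)
  expect_equal(length(txt), 1 + nrow(tab))
  expect_false(any(grepl("NaN|NA", txt)))
  back <- read.csv(path)
  expect_true(all(is.na(back$p2[back$window_label == "2000-2004"])))
})
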