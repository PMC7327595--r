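# Lexicon loading, text normalization, dictionary matching, mention index.

test_that("lexicon loads from TSV, normalizes synonyms and enforces uniqueness", {
  tsv <- withr::local_tempfile(lines = c(
    "entity_id\tentity_type\tcanonical_name\tsynonyms",
    "D001\tdrug\taspirin\taspirin|Acetylsalicylic Acid"))
  lex <- load_lexicon(tsv)
  expect_s3_class(lex, "entity_lexicon")
  expect_equal(nrow(lex), 2)  # canonical + one distinct synonym
  expect_setequal(lex$synonym, c("aspirin", "acetylsalicylic acid"))

  # duplicate normalized synonym within one type is an error naming both ids
  expect_error(as_lexicon(data.frame(
    entity_id = c("D1", "D2"), entity_type = "drug",
    canonical_name = c("one", "two"), synonyms = c("asa", "ASA"))),
    "asa.*D1.*D2")

  # the same surface in different types is allowed
  lex2 <- as_lexicon(data.frame(
    entity_id = c("G1", "D1"), entity_type = c("gene", "drug"),
    canonical_name = "cox-2", synonyms = "cox-2"))
  expect_equal(nrow(lex2), 2)

  expect_error(as_lexicon(data.frame(
    entity_id = "X", entity_type = "protein", canonical_name = "x",
    synonyms = "x")), "entity_type")
})

test_that("text normalization folds case, accents and punctuation", {
  expect_equal(normalize_text("Acetylsalicylic Acid,"), "acetylsalicylic acid")
  expect_equal(normalize_text("COX-2–dependent"), "cox-2 dependent")
  expect_equal(normalize_text("P2Y_12_ receptor"), "p2y12 receptor")
  expect_equal(normalize_text("Acetylsalicylsäure"), "acetylsalicylsaure")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text("  spaced   out  "), "spaced out")
  expect_equal(normalize_text("-edge-case- a-b"), "edge-case a-b")
})

test_that("text normalization is idempotent on arbitrary inputs", {
  set.seed(4)
  samples <- c(
    "TNF-α and IL-6; a (random) trial — phase II",
    "Ácido acetilsalicílico!!",
    vapply(1:40, function(i) random_text(), character(1)))
  once <- normalize_text(samples)
  expect_identical(normalize_text(once), once)
})

test_that("dictionary matching finds boundary-respecting mentions with longest-match suppression", {
  lex <- as_lexicon(data.frame(
    entity_id = c("D001", "G001"), entity_type = c("drug", "gene"),
    canonical_name = c("aspirin", "cox-2"), synonyms = c("aspirin", "cox-2")))
  m <- match_entities(rec("1", 2000, abstract = "aspirin inhibits cox-2"), lex)
  expect_equal(nrow(m), 2)
  expect_setequal(m$entity_id, c("D001", "G001"))
  expect_equal(m$field, c("abstract", "abstract"))

  # offsets index the normalized abstract (0-based half-open)
  norm <- normalize_text("aspirin inhibits cox-2")
  for (i in 1:2)
    expect_equal(substr(norm, m$start[i] + 1, m$end[i]), m$surface[i])

  # the longer synonym wins among same-type overlaps
  lex2 <- as_lexicon(data.frame(
    entity_id = c("DA", "DS"), entity_type = "drug",
    canonical_name = c("acetylsalicylic acid", "salicylic acid"),
    synonyms = c("acetylsalicylic acid", "salicylic acid")))
  m2 <- match_entities(rec("2", 2000, abstract = "acetylsalicylic acid"), lex2)
  expect_equal(m2$entity_id, "DA")

  # token-internal substrings never match
  lex3 <- as_lexicon(data.frame(
    entity_id = "DI", entity_type = "disease", canonical_name = "asthma",
    synonyms = "asthma"))
  expect_equal(nrow(match_entities(
    rec("3", 2000, abstract = "asthmatic patients"), lex3)), 0)

  expect_equal(nrow(match_entities(rec("4", 2000), lex)), 0)
})

test_that("matcher agrees with the brute-force positional oracle", {
  set.seed(101)
  tried <- 0
  while (tried < 150) {
    lex <- random_lexicon()
    if (is.null(lex)) next
    tried <- tried + 1
    txt <- normalize_text(random_text())
    got <- p3c:::.match_text(txt, lex)
    want <- oracle_match_text(txt, lex)
    rownames(got) <- NULL
    expect_identical(got[c("entity_id", "entity_type", "start", "end")],
                     want[c("entity_id", "entity_type", "start", "end")])
  }
})

test_that("mention index separates document frequency from mention counts", {
  lex <- as_lexicon(data.frame(
    entity_id = c("D1", "D2"), entity_type = "drug",
    canonical_name = c("alphagen", "zeta"), synonyms = c("alphagen", "zeta")))
  corp <- mk_corpus(
    rec("1", 2000, abstract = "alphagen and again alphagen"),
    rec("2", 2001, abstract = "alphagen once"),
    rec("3", 2002, abstract = "nothing here"))
  idx <- build_mention_index(corp, lex)
  df <- document_frequency(idx)
  expect_equal(unname(df["D1"]), 2L)
  expect_equal(unname(idx$mention_counts["D1"]), 3L)
  expect_equal(unname(df["D2"]), 0L)
  expect_setequal(entity_docs(idx, "D1"), c("1", "2"))

  # document frequency never exceeds mention count
  expect_true(all(df <= idx$mention_counts))

  # the index equals the union of per-record matches
  per_rec <- do.call(rbind, lapply(1:3, function(i)
    match_entities(corp$records[i, ], lex)))
  expect_setequal(paste(idx$pairs$pmid, idx$pairs$entity_id),
                  unique(paste(per_rec$pmid, per_rec$entity_id)))
})

test_that("Boolean query rendering joins synonyms and the date clause", {
  lex <- as_lexicon(data.frame(
    entity_id = "D001", entity_type = "drug", canonical_name = "aspirin",
    synonyms = "aspirin|acetylsalicylic acid"))
  q <- render_query(lex, "D001", c(1951, 2018))
  expect_match(q, "\\(aspirin\\)")
  expect_match(q, "\\(acetylsalicylic acid\\)")
  expect_match(q, " OR ")
  expect_match(q, '\\("1951"\\[PDAT\\] : "2018"\\[PDAT\\]\\)', fixed = FALSE)

  lex1 <- as_lexicon(data.frame(
    entity_id = "X", entity_type = "gene", canonical_name = "tp53",
    synonyms = "tp53"))
  expect_match(render_query(lex1, "X", c(2000, 2001)), "\\(tp53\\)")
  expect_error(render_query(lex, "D001", c(2018, 1951)), "span")
})

test_that("mentions export carries offsets and fields", {
  lex <- as_lexicon(data.frame(
    entity_id = "D1", entity_type = "drug", canonical_name = "alphagen",
    synonyms = "alphagen"))
  corp <- mk_corpus(rec("1", 2000, title = "Alphagen trial",
                        abstract = "more alphagen"))
  idx <- build_mention_index(corp, lex)
  path <- withr::local_tempfile()
  write_mentions_csv(idx, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 2)
  expect_setequal(out$field, c("title", "abstract"))
})
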