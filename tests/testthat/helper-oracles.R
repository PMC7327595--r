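# Brute-force oracles and in-code fixtures shared across the suite.

# Construct a minimal publication record data frame.
rec <- function(pmid, year, title = "", abstract = "", authors = NULL,
                journal = "Journal A", pub_types = "Journal Article",
                language = "eng") {
  if (is.null(authors))
    authors <- data.frame(surname = character(), given = character(),
                          initials = character(), stringsAsFactors = FALSE)
  data.frame(pmid = pmid, year = as.integer(year), title = title,
             abstract = abstract, authors = I(list(authors)),
             journal = journal, pub_types = I(list(pub_types)),
             language = language, stringsAsFactors = FALSE)
}

au <- function(...) {
  names <- c(...)
  data.frame(surname = names, given = "", initials = "",
             stringsAsFactors = FALSE)
}

mk_corpus <- function(...) as_corpus(do.call(rbind, list(...)))

# Character-level brute-force matcher: tries every synonym at every start
# position with explicit substring comparison and flanking-character boundary
# checks, then applies greedy longest-match suppression within each entity
# type (longest first; ties earliest start, then entity id).
oracle_match_text <- function(txt, lexicon) {
  cand <- list()
  n <- nchar(txt)
  for (i in seq_len(nrow(lexicon))) {
    syn <- lexicon$synonym[i]
    L <- nchar(syn)
    if (L == 0 || L > n) next
    for (s in seq_len(n - L + 1)) {
      if (substr(txt, s, s + L - 1) != syn) next
      before <- if (s == 1) "" else substr(txt, s - 1, s - 1)
      after <- if (s + L - 1 == n) "" else substr(txt, s + L, s + L)
      if (grepl("^[a-z0-9]$", before) || grepl("^[a-z0-9]$", after)) next
      cand[[length(cand) + 1]] <- data.frame(
        entity_id = lexicon$entity_id[i],
        entity_type = lexicon$entity_type[i], surface = syn,
        start = s - 1L, end = s + L - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(entity_id = character(), entity_type = character(),
                      surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  # greedy longest-match suppression, independently re-implemented
  kept <- list()
  for (ty in unique(cand$entity_type)) {
    pool <- cand[cand$entity_type == ty, , drop = FALSE]
    acc <- pool[0, ]
    while (nrow(pool)) {
      len <- pool$end - pool$start
      best <- order(-len, pool$start, pool$entity_id)[1]
      b <- pool[best, , drop = FALSE]
      acc <- rbind(acc, b)
      overlap <- pool$start < b$end & pool$end > b$start
      pool <- pool[!overlap, , drop = FALSE]
    }
    kept[[ty]] <- acc
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$start, out$entity_type, out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Explicit per-window recount: loops over records one by one.
oracle_count_window <- function(corpus, lexicon, entity_id, window,
                                top_journals) {
  recs <- corpus$records
  n_i <- 0L; n_T <- 0L; n_H20 <- 0L
  ent_keys <- character(); all_keys <- character()
  top_norm <- normalize_text(top_journals)
  for (i in seq_len(nrow(recs))) {
    if (recs$year[i] < window$start_year || recs$year[i] > window$end_year)
      next
    n_T <- n_T + 1L
    auth <- recs$authors[[i]]
    keys <- if (nrow(auth)) author_key(auth) else character()
    all_keys <- union(all_keys, keys)
    m <- match_entities(recs[i, ], lexicon)
    if (entity_id %in% m$entity_id) {
      n_i <- n_i + 1L
      if (normalize_text(recs$journal[i]) %in% top_norm) n_H20 <- n_H20 + 1L
      ent_keys <- union(ent_keys, keys)
    }
  }
  list(n_i = n_i, n_T = n_T, n_H20 = n_H20,
       n_AI = length(ent_keys), n_AT = length(all_keys))
}

# Random lexicon of <= max_entities entities with single-token or two-token
# synonyms drawn from a small alphabet (collision-prone by design).
random_lexicon <- function(max_entities = 5) {
  words <- c("alfa", "bravo", "cargo", "delta", "gamma-1", "nodes", "umbra")
  k <- sample(2:max_entities, 1)
  entries <- lapply(seq_len(k), function(i) {
    ty <- sample(c("disease", "drug", "gene"), 1)
    n_syn <- sample(1:2, 1)
    syn <- vapply(seq_len(n_syn), function(j) {
      paste(sample(words, sample(1:2, 1)), collapse = " ")
    }, character(1))
    data.frame(entity_id = sprintf("E%02d", i), entity_type = ty,
               canonical_name = syn[1],
               synonyms = paste(syn, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, entries)
  tryCatch(as_lexicon(entries), error = function(e) NULL)
}

random_text <- function(max_words = 40) {
  words <- c("alfa", "bravo", "cargo", "delta", "gamma-1", "nodes", "umbra",
             "alfabravo", "the", "study", "of")
  paste(sample(words, sample(3:max_words, 1), replace = TRUE),
        collapse = " ")
}

# Small random corpus with planted trends, for fuzz tests.
random_synthetic <- function(seed, n_windows = 4, m_w = 40) {
  span <- c(2000, 2000 + n_windows * 5 - 1)
  set.seed(seed * 13 + 1)
  trends <- list(
    trend_spec("D1", "disease", "alphagen",
               q = round(stats::runif(n_windows, 0.05, 0.6), 2),
               top_journal_lift = 1.5, author_affinity = 0.3),
    trend_spec("X1", "drug", "betacilin",
               q = round(stats::runif(n_windows, 0, 0.5), 2)))
  generate_corpus(corpus_spec(span, m_w = m_w, trends = trends), seed = seed)
}
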