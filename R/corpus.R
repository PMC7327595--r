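#' @title Publication corpora
#' @description
#' A corpus is the ordered collection of publication records the indices are
#' computed over: one row per article with identifiers, year, text fields,
#' authors, journal and record-type metadata. Objects of class `"corpus"` hold
#' a data frame `records` (with list columns `authors` and `pub_types`) plus
#' the year span, and optionally the parse/exclusion report that produced
#' them.
#' @name corpus
NULL

# authors: list of data.frames(surname, given, initials); pub_types: list of
# character vectors.
new_corpus <- function(records, report = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records)) {
    if (any(!nzchar(records$pmid))) stop("empty pmid in corpus records")
    dup <- unique(records$pmid[duplicated(records$pmid)])
    if (length(dup))
      stop("duplicate pmid(s) in corpus: ", paste(dup, collapse = ", "))
    records <- records[order(records$year, records$pmid), , drop = FALSE]
    rownames(records) <- NULL
    span <- c(min(records$year), max(records$year))
  } else {
    span <- c(NA_integer_, NA_integer_)
  }
  structure(list(records = records, span = span, report = report),
            class = "corpus")
}

.record_columns <- c("pmid", "year", "title", "abstract", "authors",
                     "journal", "pub_types", "language")

.empty_records <- function() {
  data.frame(pmid = character(), year = integer(), title = character(),
             abstract = character(),
             authors = I(list()), journal = character(),
             pub_types = I(list()), language = character(),
             stringsAsFactors = FALSE)
}

#' Assemble a corpus from a records data frame
#'
#' @param records Data frame with columns `pmid`, `year`, `title`, `abstract`,
#'   `authors` (list column of data frames with `surname`, `given`,
#'   `initials`), `journal`, `pub_types` (list column of character vectors),
#'   `language`.
#' @return A `corpus` object; records are sorted by (year, pmid). Duplicate or
#'   empty pmids are an error.
#' @export
as_corpus <- function(records) {
  miss <- setdiff(.record_columns, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  records$pmid <- as.character(records$pmid)
  records$year <- as.integer(records$year)
  new_corpus(records[.record_columns])
}

#' @export
print.corpus <- function(x, ...) {
  n <- nrow(x$records)
  cat("Publication corpus: ", n, " records", sep = "")
  if (n) cat(", span ", x$span[1], "-", x$span[2], sep = "")
  cat("\n")
  if (!is.null(x$report) && length(x$report))
    cat("  report: ", paste(names(x$report), unlist(x$report), sep = "=",
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of records in a corpus
#' @param x A `corpus`.
#' @param ... Ignored.
#' @export
length.corpus <- function(x) nrow(x$records)

# First plausible 4-digit calendar year in a MEDLINE date string, NA if none.
.scan_year <- function(s) {
  m <- regmatches(s, gregexpr("[0-9]{4}", s))[[1]]
  for (y in as.integer(m)) if (y >= 1000L && y <= 2999L) return(y)
  NA_integer_
}

.xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
}

#' Parse MEDLINE/PubMed XML into a corpus
#'
#' Reads a `PubmedArticleSet` document (the standard MEDLINE XML dialect) and
#' extracts, per article: PMID, publication year, title, abstract, author
#' list, journal title, publication types and language. The year is resolved
#' as the first 4-digit year appearing in the journal issue's `PubDate`
#' (covering both `<Year>` and `MedlineDate` strings such as "1951 Jan-Feb");
#' articles with no resolvable year are dropped and counted in the corpus
#' report under `no_year`.
#'
#' @param path Path to an XML file, a URL, or a literal XML string.
#' @return A `corpus`; its `report` holds `parsed` and `no_year` counts.
#'   Malformed XML is an error (with the parser's position information);
#'   duplicate PMIDs are an error naming the pmid.
#' @export
parse_medline_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed MEDLINE XML: ",
                                           conditionMessage(e), call. = FALSE))
  arts <- xml2::xml_find_all(doc, "//PubmedArticle")
  rows <- vector("list", length(arts))
  dropped <- 0L
  for (i in seq_along(arts)) {
    a <- arts[[i]]
    pmid <- .xml_text1(a, ".//MedlineCitation/PMID")
    pubdate <- xml2::xml_find_first(a, ".//Journal/JournalIssue/PubDate")
    year <- if (inherits(pubdate, "xml_missing")) NA_integer_ else
      .scan_year(xml2::xml_text(pubdate))
    if (is.na(year)) { dropped <- dropped + 1L; next }
    title <- .xml_text1(a, ".//Article/ArticleTitle")
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(a, ".//Article/Abstract/AbstractText")),
      collapse = " ")
    journal <- .xml_text1(a, ".//Article/Journal/Title")
    language <- .xml_text1(a, ".//Article/Language")
    pub_types <- xml2::xml_text(
      xml2::xml_find_all(a, ".//PublicationTypeList/PublicationType"))
    au_nodes <- xml2::xml_find_all(a, ".//AuthorList/Author")
    authors <- data.frame(
      surname = vapply(au_nodes, function(n) .xml_text1(n, "./LastName"), ""),
      given = vapply(au_nodes, function(n) .xml_text1(n, "./ForeName"), ""),
      initials = vapply(au_nodes, function(n) .xml_text1(n, "./Initials"), ""),
      stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(
      pmid = pmid, year = year, title = title, abstract = abstract,
      authors = I(list(authors)), journal = journal,
      pub_types = I(list(pub_types)), language = language,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows)) do.call(rbind, rows) else .empty_records()
  new_corpus(records, report = list(parsed = nrow(records), no_year = dropped))
}

#' Read / write the line-delimited corpus fixture format
#'
#' The fixture format is UTF-8 text with one JSON object per line and keys
#' `pmid`, `year`, `title`, `abstract`, `authors` (array of objects with
#' `surname`, `given`, `initials`), `journal`, `pub_types` (array of strings),
#' `language`. `write_fixture()` followed by `read_fixture()` reproduces the
#' corpus exactly.
#'
#' @param path File path.
#' @return `read_fixture()` returns a `corpus`; `write_fixture()` returns
#'   `path` invisibly. A line missing a required field is an error naming the
#'   line number and field.
#' @export
read_fixture <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(new_corpus(.empty_records()))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- jsonlite::fromJSON(lines[i], simplifyDataFrame = FALSE)
    miss <- setdiff(.record_columns, names(obj))
    if (length(miss))
      stop("fixture line ", i, ": missing field(s) ",
           paste(miss, collapse = ", "))
    authors <- if (length(obj$authors)) {
      do.call(rbind, lapply(obj$authors, function(a)
        data.frame(surname = a$surname %||% "", given = a$given %||% "",
                   initials = a$initials %||% "", stringsAsFactors = FALSE)))
    } else {
      data.frame(surname = character(), given = character(),
                 initials = character(), stringsAsFactors = FALSE)
    }
    rows[[i]] <- data.frame(
      pmid = obj$pmid, year = as.integer(obj$year), title = obj$title,
      abstract = obj$abstract, authors = I(list(authors)),
      journal = obj$journal,
      pub_types = I(list(as.character(unlist(obj$pub_types)))),
      language = obj$language, stringsAsFactors = FALSE)
  }
  new_corpus(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_fixture
#' @param corpus A `corpus` to serialize.
#' @export
write_fixture <- function(corpus, path) {
  recs <- corpus$records
  lines <- vapply(seq_len(nrow(recs)), function(i) {
    au <- recs$authors[[i]]
    jsonlite::toJSON(list(
      pmid = recs$pmid[i], year = recs$year[i], title = recs$title[i],
      abstract = recs$abstract[i],
      authors = lapply(seq_len(nrow(au)), function(j)
        list(surname = au$surname[j], given = au$given[j],
             initials = au$initials[j])),
      journal = recs$journal[i],
      pub_types = as.list(recs$pub_types[[i]]),
      language = recs$language[i]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default record filtering policy
#'
#' Excludes letters, editorials, comments and other non-journal record types,
#' and keeps English-language records only — the usual cleaning applied to a
#' MEDLINE download before bibliometric analysis.
#'
#' @param excluded_types Character vector of publication types to exclude.
#' @param language Required language code (set to `NULL` to keep all).
#' @return A list with class `"filter_policy"`.
#' @export
filter_policy <- function(excluded_types = c("Letter", "Editorial", "Comment",
                                             "News", "Retraction of Publication",
                                             "Published Erratum"),
                          language = "eng") {
  structure(list(excluded_types = excluded_types, language = language),
            class = "filter_policy")
}

#' Filter a corpus by record type and language
#'
#' @param corpus A `corpus`.
#' @param policy A [filter_policy()].
#' @return The filtered `corpus`; its `report` counts exclusions per rule
#'   (one entry per excluded publication type, plus `language`). A record
#'   failing several rules is counted once, under the first matching excluded
#'   type (language otherwise). Filtering is idempotent.
#' @export
filter_records <- function(corpus, policy = filter_policy()) {
  recs <- corpus$records
  n <- nrow(recs)
  excl_rule <- character(n)
  for (i in seq_len(n)) {
    hit <- intersect(policy$excluded_types, recs$pub_types[[i]])
    if (length(hit)) {
      excl_rule[i] <- hit[1L]
    } else if (!is.null(policy$language) &&
               !identical(recs$language[i], policy$language)) {
      excl_rule[i] <- "language"
    }
  }
  keep <- !nzchar(excl_rule)
  report <- as.list(table(excl_rule[!keep]))
  new_corpus(recs[keep, , drop = FALSE], report = report)
}

#' Write an exclusion report as CSV
#'
#' @param corpus A filtered `corpus` (as returned by [filter_records()]).
#' @param path Output path; rows are `rule,count`.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(corpus, path) {
  rep <- corpus$report
  df <- data.frame(rule = names(rep), count = as.integer(unlist(rep)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-window descriptive statistics of a corpus
#'
#' For each time window reports the number of publications, the number of
#' distinct authors (under the supplied keying function), the mean number of
#' authors per publication, and the number of distinct journals. Distinct
#' counts are taken within each window separately, so they are sub-additive
#' over finer partitions while publication counts are additive.
#'
#' @param corpus A `corpus`.
#' @param windows A [windowing_scheme()] (or any data frame with
#'   `start_year`, `end_year`, `label`).
#' @param key_fun Author keying function mapping a one-row author data frame
#'   to a string; defaults to [author_key()].
#' @return Data frame with one row per window: `label`, `start_year`,
#'   `end_year`, `publications`, `authors`, `mean_authors`, `journals`.
#'   Windows with no publications have zero counts and `NA` mean.
#' @export
corpus_summary <- function(corpus, windows, key_fun = author_key) {
  recs <- corpus$records
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    in_w <- recs$year >= w$start_year & recs$year <= w$end_year
    sub <- recs[in_w, , drop = FALSE]
    npub <- nrow(sub)
    nau_slots <- sum(vapply(sub$authors, nrow, 0L))
    data.frame(
      label = w$label, start_year = w$start_year, end_year = w$end_year,
      publications = npub,
      authors = distinct_authors(sub, key_fun = key_fun),
      mean_authors = if (npub) nau_slots / npub else NA_real_,
      journals = length(unique(normalize_text(sub$journal))) -
        any(!nzchar(normalize_text(sub$journal))),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
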