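#' @title Typed entity lexicons
#' @description
#' An entity lexicon maps canonical biomedical entities (diseases, drugs,
#' genes) to their surface-form synonyms. It plays the role of the dictionary
#' behind dictionary-based entity extraction: tagging is purely lexical, with
#' no learned model. Lexicons are stored as a data frame of class
#' `"entity_lexicon"` with one row per (entity, normalized synonym) pair.
#' @name entity_lexicon
NULL

ENTITY_TYPES <- c("disease", "drug", "gene")

new_lexicon <- function(df) {
  stopifnot(all(c("entity_id", "entity_type", "canonical_name", "synonym") %in%
                  names(df)))
  class(df) <- c("entity_lexicon", "data.frame")
  df
}

#' Build an entity lexicon from entries
#'
#' @param entries A data frame with columns `entity_id`, `entity_type`
#'   (`"disease"`, `"drug"` or `"gene"`), `canonical_name`, and `synonyms`
#'   (pipe-separated surface forms; the canonical name is always included).
#' @return An `entity_lexicon`: one row per (entity, normalized synonym),
#'   with columns `entity_id`, `entity_type`, `canonical_name`, `synonym`.
#' @details Synonyms are normalized with [normalize_text()]. Within one entity
#'   type a normalized surface form must resolve to exactly one entity;
#'   duplicates across types (gene/drug homonyms such as "adenosine") are
#'   allowed. Violations are errors naming the offending entity ids.
#' @seealso [load_lexicon()] to read the TSV interchange format.
#' @export
as_lexicon <- function(entries) {
  req <- c("entity_id", "entity_type", "canonical_name", "synonyms")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop("lexicon entries missing column(s): ", paste(miss, collapse = ", "))
  bad_type <- setdiff(unique(entries$entity_type), ENTITY_TYPES)
  if (length(bad_type))
    stop("unknown entity_type(s): ", paste(bad_type, collapse = ", "),
         " (expected one of ", paste(ENTITY_TYPES, collapse = ", "), ")")
  if (anyDuplicated(entries$entity_id))
    stop("duplicate entity_id(s): ",
         paste(unique(entries$entity_id[duplicated(entries$entity_id)]),
               collapse = ", "))

  rows <- lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    syn <- unique(c(e$canonical_name,
                    strsplit(as.character(e$synonyms), "|", fixed = TRUE)[[1]]))
    syn <- unique(normalize_text(syn))
    syn <- syn[nzchar(syn)]
    if (!length(syn))
      stop("entity ", e$entity_id, " has no non-empty synonym after normalization")
    data.frame(entity_id = e$entity_id, entity_type = e$entity_type,
               canonical_name = e$canonical_name, synonym = syn,
               stringsAsFactors = FALSE)
  })
  lex <- do.call(rbind, rows)

  # one entity per normalized surface within a type
  key <- paste(lex$entity_type, lex$synonym, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    k <- dup[1L]
    owners <- lex$entity_id[key == k]
    stop("synonym '", sub("^.*\r", "", k), "' maps to multiple ",
         sub("\r.*$", "", k), " entities: ", paste(owners, collapse = ", "))
  }
  new_lexicon(lex)
}

#' Load an entity lexicon from TSV
#'
#' Reads the tab-separated lexicon interchange format: columns `entity_id`,
#' `entity_type`, `canonical_name`, `synonyms` (pipe-separated), with a header
#' line.
#'
#' @param path Path to the TSV file (or a connection).
#' @return An `entity_lexicon`; see [as_lexicon()].
#' @export
load_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  as_lexicon(df)
}

#' @export
print.entity_lexicon <- function(x, ...) {
  ids <- unique(x$entity_id)
  cat("Entity lexicon: ", length(ids), " entities, ", nrow(x),
      " normalized synonyms\n", sep = "")
  tab <- table(x$entity_type[!duplicated(x$entity_id)])
  cat("  ", paste(names(tab), as.integer(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tag entity mentions in one publication record
#'
#' Runs dictionary matching over the normalized title and abstract of a
#' record. A synonym matches only at word boundaries: the matched span must be
#' flanked by start/end of text or by a non-alphanumeric character, so
#' "asthma" never matches inside "asthmatic". Among overlapping matches of the
#' *same* entity type the longest wins and shorter overlapped matches are
#' suppressed (ties broken by earliest start, then entity id); matches of
#' different types may overlap freely.
#'
#' @param record A single-row record data frame with `pmid`, `title`,
#'   `abstract` (as held in a [corpus]).
#' @param lexicon An [entity_lexicon].
#' @return Data frame of mentions: `pmid`, `entity_id`, `entity_type`,
#'   `surface`, `field` (`"title"`/`"abstract"`), `start`, `end` (0-based,
#'   half-open offsets into the normalized field text).
#' @export
match_entities <- function(record, lexicon) {
  out <- list()
  for (field in c("title", "abstract")) {
    txt <- normalize_text(record[[field]])
    m <- .match_text(txt, lexicon)
    if (nrow(m)) {
      m$pmid <- record$pmid
      m$field <- field
      out[[field]] <- m
    }
  }
  if (!length(out)) return(.empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("pmid", "entity_id", "entity_type", "surface", "field", "start", "end")]
}

.empty_mentions <- function() {
  data.frame(pmid = character(), entity_id = character(),
             entity_type = character(), surface = character(),
             field = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

# All candidate matches of every synonym in `txt` (already normalized),
# before overlap suppression. Fixed-string search per synonym, then a
# vectorized boundary check on the flanking characters.
.candidate_matches <- function(txt, lexicon) {
  if (!nzchar(txt)) return(NULL)
  hits <- lapply(seq_len(nrow(lexicon)), function(i) {
    syn <- lexicon$synonym[i]
    g <- gregexpr(syn, txt, fixed = TRUE)[[1]]
    if (g[1L] == -1L) return(NULL)
    st <- as.integer(g)
    en <- st + nchar(syn) - 1L
    ok <- !.is_word_char(txt, st - 1L) & !.is_word_char(txt, en + 1L)
    if (!any(ok)) return(NULL)
    data.frame(entity_id = lexicon$entity_id[i],
               entity_type = lexicon$entity_type[i],
               surface = syn, start = st[ok] - 1L, end = en[ok],
               stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# Greedy longest-match suppression within entity type: repeatedly accept the
# longest remaining candidate (ties: earliest start, then entity_id) and drop
# same-type candidates overlapping it.
.suppress_overlaps <- function(cand) {
  len <- cand$end - cand$start
  ord <- order(-len, cand$start, cand$entity_id)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (ty in unique(cand$entity_type)) {
    idx <- which(cand$entity_type == ty)
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      s <- cand$start[i]; e <- cand$end[i]
      if (!any(s < taken_e & e > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
  }
  res <- cand[keep, , drop = FALSE]
  res[order(res$start, res$entity_type, res$entity_id), , drop = FALSE]
}

# Vectorized corpus-scale matcher: one fixed-string pass per synonym over all
# texts at once, shared boundary rule, then overlap suppression applied only
# to documents where same-type candidates actually overlap. Produces exactly
# the mentions per-record match_entities() would.
.match_corpus <- function(pmids, texts, field, lexicon) {
  parts <- list()
  for (i in seq_len(nrow(lexicon))) {
    syn <- lexicon$synonym[i]
    L <- nchar(syn)
    g <- gregexpr(syn, texts, fixed = TRUE)
    nhit <- vapply(g, function(v) if (v[1L] == -1L) 0L else length(v), 0L)
    if (!any(nhit)) next
    doc <- rep.int(which(nhit > 0L), nhit[nhit > 0L])
    st <- unlist(lapply(g[nhit > 0L], as.integer), use.names = FALSE)
    en <- st + L - 1L
    before <- substring(texts[doc], st - 1L, st - 1L)
    after <- substring(texts[doc], en + 1L, en + 1L)
    ok <- !grepl("[a-z0-9]", before) & !grepl("[a-z0-9]", after)
    if (!any(ok)) next
    parts[[length(parts) + 1L]] <- data.frame(
      doc = doc[ok], entity_id = lexicon$entity_id[i],
      entity_type = lexicon$entity_type[i], surface = syn,
      start = st[ok] - 1L, end = en[ok], stringsAsFactors = FALSE)
  }
  if (!length(parts)) return(.empty_mentions())
  cand <- do.call(rbind, parts)
  # overlap detection per (doc, type): after sorting by start, an overlap
  # exists iff some candidate starts before its predecessor ends
  key <- paste(cand$doc, cand$entity_type)
  ord <- order(key, cand$start, cand$end)
  cand <- cand[ord, , drop = FALSE]
  key <- key[ord]
  same <- c(FALSE, key[-1L] == key[-length(key)])
  prev_end <- c(0L, cand$end[-length(key)])
  # sorted by start, any overlap within a group implies an adjacent overlap
  overlapped <- same & cand$start < prev_end
  bad_docs <- unique(cand$doc[overlapped])
  keep <- !(cand$doc %in% bad_docs)
  kept <- cand[keep, , drop = FALSE]
  if (length(bad_docs)) {
    fixed <- lapply(bad_docs, function(d)
      .suppress_overlaps(cand[cand$doc == d, , drop = FALSE]))
    kept <- rbind(kept, do.call(rbind, fixed))
  }
  out <- data.frame(pmid = pmids[kept$doc], entity_id = kept$entity_id,
                    entity_type = kept$entity_type, surface = kept$surface,
                    field = field, start = kept$start, end = kept$end,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.match_text <- function(txt, lexicon) {
  cand <- .candidate_matches(txt, lexicon)
  if (is.null(cand))
    return(data.frame(entity_id = character(), entity_type = character(),
                      surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  .suppress_overlaps(cand)
}

#' Build a document-level mention index over a corpus
#'
#' @param corpus A [corpus] (typically already passed through
#'   [filter_records()]).
#' @param lexicon An [entity_lexicon].
#' @return An object of class `"mention_index"` with components:
#'   \describe{
#'     \item{pairs}{data frame of distinct (pmid, entity_id, entity_type)
#'       pairs — the document-level presence relation.}
#'     \item{mention_counts}{named integer vector: total mention count per
#'       entity (every matched span counts, including repeats in one record).}
#'     \item{entity_type}{named character vector: type per tagged entity.}
#'   }
#'   Document frequency for an entity is the number of rows of `pairs`
#'   carrying it; a record contributes at most once however often it repeats
#'   the entity.
#' @export
build_mention_index <- function(corpus, lexicon) {
  recs <- corpus$records
  all_m <- rbind(.match_corpus(recs$pmid, normalize_text(recs$title),
                               "title", lexicon),
                 .match_corpus(recs$pmid, normalize_text(recs$abstract),
                               "abstract", lexicon))
  all_m <- all_m[order(match(all_m$pmid, recs$pmid),
                       match(all_m$field, c("title", "abstract")),
                       all_m$start, all_m$entity_type, all_m$entity_id), ,
                 drop = FALSE]
  rownames(all_m) <- NULL

  pairs <- unique(all_m[c("pmid", "entity_id", "entity_type")])
  rownames(pairs) <- NULL
  counts <- table(factor(all_m$entity_id, levels = unique(lexicon$entity_id)))
  mention_counts <- stats::setNames(as.integer(counts), names(counts))
  etype <- stats::setNames(
    lexicon$entity_type[!duplicated(lexicon$entity_id)],
    lexicon$entity_id[!duplicated(lexicon$entity_id)])
  structure(list(pairs = pairs, mention_counts = mention_counts,
                 entity_type = etype, mentions = all_m),
            class = "mention_index")
}

#' @export
print.mention_index <- function(x, ...) {
  cat("Mention index: ", nrow(x$pairs), " (document, entity) pairs, ",
      sum(x$mention_counts), " mentions, ",
      sum(x$mention_counts > 0), " of ", length(x$mention_counts),
      " entities observed\n", sep = "")
  invisible(x)
}

#' Document frequency of entities
#'
#' Number of distinct publications mentioning each entity at least once.
#'
#' @param index A `mention_index` from [build_mention_index()].
#' @return Named integer vector over all lexicon entities (zeros included).
#' @export
document_frequency <- function(index) {
  df <- table(factor(index$pairs$entity_id, levels = names(index$mention_counts)))
  stats::setNames(as.integer(df), names(df))
}

#' PMIDs of records mentioning an entity
#' @param index A `mention_index`.
#' @param entity_id Entity identifier.
#' @return Character vector of pmids (possibly empty).
#' @export
entity_docs <- function(index, entity_id) {
  index$pairs$pmid[index$pairs$entity_id == entity_id]
}

#' Render a Boolean retrieval query for an entity
#'
#' Produces a PubMed-style Boolean query: the OR-disjunction of the entity's
#' synonyms, AND-combined with a publication-date range clause
#' `("YYYY"[PDAT] : "YYYY"[PDAT])`.
#'
#' @param lexicon An [entity_lexicon].
#' @param entity_id Which entity to render.
#' @param span Integer vector `c(first_year, last_year)`.
#' @return A single query string.
#' @examples
#' lex <- as_lexicon(data.frame(
#'   entity_id = "D001", entity_type = "drug", canonical_name = "aspirin",
#'   synonyms = "aspirin|acetylsalicylic acid"))
#' render_query(lex, "D001", c(1951, 2018))
#' @export
render_query <- function(lexicon, entity_id, span) {
  if (length(span) != 2L || span[2L] < span[1L])
    stop("span must be c(first_year, last_year) with first_year <= last_year")
  syn <- lexicon$synonym[lexicon$entity_id == entity_id]
  if (!length(syn)) stop("unknown entity_id: ", entity_id)
  terms <- paste0("(", syn, ")", collapse = " OR ")
  sprintf('((%s) AND ("%d"[PDAT] : "%d"[PDAT]))', terms, span[1L], span[2L])
}

#' Export mentions to CSV
#'
#' Writes one row per matched span with columns
#' `pmid,entity_id,entity_type,field,start,end,surface`.
#'
#' @param index A `mention_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mentions_csv <- function(index, path) {
  m <- index$mentions[c("pmid", "entity_id", "entity_type", "field",
                        "start", "end", "surface")]
  utils::write.csv(m, path, row.names = FALSE, na = "")
  invisible(path)
}
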