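#' Declare a planted entity trend
#'
#' A trend specifies, per time window, the probability `q_w` that a synthetic
#' publication mentions the entity — either directly (`q`) or through a
#' unimodal rise-peak-decline shape: `q_w = baseline + (peak_height -
#' baseline) * rate^|w - peak_window|`, with separate retention `rate`s on the
#' rising (`rise`) and declining (`decay`) side. This is the kind of
#' trajectory the windowed indices are meant to detect: an entity whose share
#' of the literature climbs to a peak window and fades again.
#'
#' @param entity_id,entity_type Identity of the planted entity.
#' @param synonyms Character vector of surface forms; the first is the
#'   canonical name and is the form planted into abstracts.
#' @param q Optional numeric vector of per-window mention probabilities (it
#'   is recycled/truncated to the number of windows at generation time).
#' @param baseline,peak_window,peak_height,rise,decay Shape parameters used
#'   when `q` is `NULL`: baseline probability, 1-based index of the peak
#'   window, probability at the peak, and per-window retention factors in
#'   (0, 1] on each side of the peak.
#' @param top_journal_lift Multiplier applied to the corpus-level top-journal
#'   probability for records mentioning this entity (>= 0).
#' @param author_affinity Probability in `[0, 1]` that an author slot of an
#'   entity-mentioning record is drawn from the entity's dedicated author
#'   sub-pool rather than the general pool; this is what creates a
#'   collaboration-index signal.
#' @return A list of class `"trend_spec"`.
#' @export
trend_spec <- function(entity_id, entity_type, synonyms,
                       q = NULL, baseline = 0.05, peak_window = 1L,
                       peak_height = 0.3, rise = 0.5, decay = 0.5,
                       top_journal_lift = 1, author_affinity = 0) {
  if (!length(synonyms)) stop("trend needs at least one synonym")
  if (author_affinity < 0 || author_affinity > 1)
    stop("author_affinity must lie in [0, 1]")
  if (top_journal_lift < 0) stop("top_journal_lift must be >= 0")
  structure(list(entity_id = entity_id, entity_type = entity_type,
                 synonyms = synonyms, q = q, baseline = baseline,
                 peak_window = as.integer(peak_window),
                 peak_height = peak_height, rise = rise, decay = decay,
                 top_journal_lift = top_journal_lift,
                 author_affinity = author_affinity),
            class = "trend_spec")
}

#' Per-window mention probabilities of a trend
#'
#' @param trend A [trend_spec()].
#' @param n_windows Number of windows to evaluate over.
#' @return Numeric vector of length `n_windows`, all values in `[0, 1]`.
#' @export
trend_q <- function(trend, n_windows) {
  if (!is.null(trend$q)) {
    q <- rep_len(trend$q, n_windows)
  } else {
    w <- seq_len(n_windows)
    d <- w - trend$peak_window
    rate <- ifelse(d < 0, trend$rise, trend$decay)
    q <- trend$baseline + (trend$peak_height - trend$baseline) * rate^abs(d)
  }
  if (any(q < 0 | q > 1))
    stop("trend '", trend$entity_id,
         "': mention probabilities fall outside [0, 1]")
  q
}

#' Declare a synthetic corpus
#'
#' Fixes every parameter of the generator: the study span and windowing, the
#' per-window publication counts, the journal pool with its designated
#' top-journal subset and baseline top-journal fraction, the author pool and
#' per-paper author-count range, and the planted entity trends. Together with
#' a seed this determines the corpus bit-for-bit.
#'
#' @param span Integer `c(first_year, last_year)`.
#' @param width Window width in years (default 5).
#' @param m_w Publications per window; scalar or vector over windows.
#' @param n_journals,n_top_journals Size of the journal pool and of its
#'   top-journal subset.
#' @param top_fraction Baseline probability that a record lands in a top
#'   journal; per-entity `top_journal_lift` multiplies it (the product must
#'   stay within `[0, 1]` for every trend).
#' @param author_pool Size of the general author pool.
#' @param author_subpool Size of each entity's dedicated author sub-pool.
#' @param authors_per_paper Integer `c(min, max)` range of authors per record
#'   (drawn uniformly).
#' @param trends List of [trend_spec()] objects.
#' @return A list of class `"corpus_spec"`, validated.
#' @export
corpus_spec <- function(span, width = 5L, m_w = 100L,
                        n_journals = 20L, n_top_journals = 4L,
                        top_fraction = 0.15,
                        author_pool = 500L, author_subpool = 40L,
                        authors_per_paper = c(1L, 8L),
                        trends = list()) {
  windows <- make_windows(span, width)
  m_w <- rep_len(as.integer(m_w), nrow(windows))
  if (any(m_w < 0)) stop("m_w must be >= 0")
  if (n_top_journals < 1L || n_top_journals > n_journals)
    stop("need 1 <= n_top_journals <= n_journals")
  if (authors_per_paper[1] < 1L || authors_per_paper[2] < authors_per_paper[1])
    stop("authors_per_paper must be an increasing positive range")
  for (tr in trends) {
    stopifnot(inherits(tr, "trend_spec"))
    trend_q(tr, nrow(windows))  # range-validated here
    if (top_fraction * tr$top_journal_lift > 1)
      stop("trend '", tr$entity_id,
           "': top_fraction * top_journal_lift exceeds 1")
  }
  ids <- vapply(trends, `[[`, "", "entity_id")
  if (anyDuplicated(ids)) stop("duplicate entity_id among trends")
  structure(list(span = span, width = width, windows = windows, m_w = m_w,
                 n_journals = n_journals, n_top_journals = n_top_journals,
                 top_fraction = top_fraction, author_pool = author_pool,
                 author_subpool = author_subpool,
                 authors_per_paper = authors_per_paper, trends = trends),
            class = "corpus_spec")
}

#' Lexicon matching a synthetic corpus specification
#'
#' @param spec A [corpus_spec()].
#' @return An [entity_lexicon] holding every trend's synonyms.
#' @export
synthetic_lexicon <- function(spec) {
  entries <- do.call(rbind, lapply(spec$trends, function(tr)
    data.frame(entity_id = tr$entity_id, entity_type = tr$entity_type,
               canonical_name = tr$synonyms[1],
               synonyms = paste(tr$synonyms, collapse = "|"),
               stringsAsFactors = FALSE)))
  as_lexicon(entries)
}

#' Journal pool of a synthetic corpus specification
#'
#' @param spec A [corpus_spec()].
#' @return List with `pool` (all journal titles) and `top` (the designated
#'   top-journal subset, the first `n_top_journals` titles).
#' @export
synthetic_journals <- function(spec) {
  pool <- c(sprintf("Top Journal %02d", seq_len(spec$n_top_journals)),
            sprintf("Regular Journal %02d",
                    seq_len(spec$n_journals - spec$n_top_journals)))
  list(pool = pool, top = pool[seq_len(spec$n_top_journals)])
}

# Independent RNG substream per concern: a stable string hash is folded into
# the user seed so that, e.g., adding an entity re-seeds only that entity's
# mention stream and leaves journal/author draws untouched.
.derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 1073741789
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

.substream_unif <- function(seed, tag, n) {
  if (n == 0L) return(numeric(0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(.derive_seed(seed, tag))
  stats::runif(n)
}

.FILLER_HEAD <- "observational cohort analysis of clinical outcomes for"
.FILLER_TAIL <- "with extended followup and standard reporting of measures"

#' Generate a synthetic publication corpus with known ground truth
#'
#' Materializes a [corpus_spec()]: exactly `m_w` records per window; each
#' record independently mentions each planted entity with that window's
#' probability `q_w` (a mention is realized by inserting the entity's
#' canonical surface form into templated filler text containing no lexicon
#' surface forms, so the dictionary matcher must find all and only the
#' planted mentions); the journal is a top journal with probability
#' `top_fraction` times the largest `top_journal_lift` among the record's
#' mentioned entities; author slots are drawn from entity-dedicated sub-pools
#' with probability `author_affinity`, otherwise from the general pool.
#' Random draws are partitioned into per-concern substreams, so the same
#' `seed` always yields a bit-identical corpus and adding a trend does not
#' perturb the other entities' draws.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `"synthetic_corpus"`:
#'   \describe{
#'     \item{corpus}{the generated [corpus];}
#'     \item{lexicon}{the matching [entity_lexicon];}
#'     \item{top_journals}{the designated top-journal titles;}
#'     \item{ground_truth}{data frame of realized per-entity per-window
#'       counts `n_i`, `n_T`, `n_H20`, `n_AI`, `n_AT`;}
#'     \item{spec, seed}{the inputs.}
#'   }
#' @export
generate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "corpus_spec"))
  windows <- spec$windows
  nw <- nrow(windows)
  n <- sum(spec$m_w)
  widths <- windows$end_year - windows$start_year + 1L
  win_of <- rep(seq_len(nw), spec$m_w)
  # deterministic year assignment: cycle through the window's years
  within_idx <- unlist(lapply(spec$m_w, seq_len), use.names = FALSE)
  year <- windows$start_year[win_of] + (within_idx - 1L) %% widths[win_of]
  pmid <- sprintf("S%06d", seq_len(n))

  lex <- if (length(spec$trends)) synthetic_lexicon(spec) else NULL
  .validate_filler(lex)

  # per-entity mention indicators (own substream per entity)
  ids <- vapply(spec$trends, `[[`, "", "entity_id")
  mention <- matrix(FALSE, nrow = n, ncol = length(spec$trends),
                    dimnames = list(NULL, ids))
  for (j in seq_along(spec$trends)) {
    q <- trend_q(spec$trends[[j]], nw)
    u <- .substream_unif(seed, paste0("mention:", ids[j]), n)
    mention[, j] <- u < q[win_of]
  }

  # journals: one substream; uniforms drawn regardless of mention outcomes
  jinfo <- synthetic_journals(spec)
  u_top <- .substream_unif(seed, "journal-top", n)
  u_pick <- .substream_unif(seed, "journal-pick", n)
  lifts <- vapply(spec$trends, `[[`, 0, "top_journal_lift")
  p_top <- rep(spec$top_fraction, n)
  if (length(spec$trends)) {
    has_m <- rowSums(mention) > 0
    max_lift <- apply(mention, 1L, function(m)
      if (any(m)) max(lifts[m]) else 1)
    p_top <- spec$top_fraction * ifelse(has_m, max_lift, 1)
  }
  is_top <- u_top < p_top
  n_top <- spec$n_top_journals
  n_reg <- spec$n_journals - n_top
  journal <- ifelse(is_top,
                    jinfo$pool[pmin(n_top, 1L + floor(u_pick * n_top))],
                    jinfo$pool[n_top + pmin(n_reg, 1L + floor(u_pick * n_reg))])

  # authors: general pool 1..A, entity j's sub-pool A + (j-1)*S + 1..S
  amin <- spec$authors_per_paper[1]; amax <- spec$authors_per_paper[2]
  u_k <- .substream_unif(seed, "author-count", n)
  k <- amin + pmin(amax - amin, floor(u_k * (amax - amin + 1L)))
  u_slot <- matrix(.substream_unif(seed, "author-slot", n * amax), nrow = n)
  u_aff <- matrix(.substream_unif(seed, "author-affinity", n * amax), nrow = n)
  affin <- vapply(spec$trends, `[[`, 0, "author_affinity")
  A <- spec$author_pool; S <- spec$author_subpool
  authors <- vector("list", n)
  for (i in seq_len(n)) {
    ment <- if (length(spec$trends)) which(mention[i, ]) else integer(0)
    aff_ent <- if (length(ment)) ment[which.max(affin[ment])] else 0L
    slot_ids <- integer(k[i])
    for (s in seq_len(k[i])) {
      if (aff_ent > 0L && u_aff[i, s] < affin[aff_ent]) {
        slot_ids[s] <- A + (aff_ent - 1L) * S +
          pmin(S, 1L + floor(u_slot[i, s] * S))
      } else {
        slot_ids[s] <- pmin(A, 1L + floor(u_slot[i, s] * A))
      }
    }
    authors[[i]] <- structure(
      list(surname = sprintf("Author%05d", slot_ids),
           given = rep("A", k[i]), initials = rep("A", k[i])),
      class = "data.frame", row.names = seq_len(k[i]))
  }

  abstract <- vapply(seq_len(n), function(i) {
    planted <- if (length(spec$trends))
      vapply(spec$trends[mention[i, ]], function(tr) tr$synonyms[1], "")
    else character(0)
    paste(c(.FILLER_HEAD, planted, .FILLER_TAIL), collapse = " ")
  }, character(1))

  records <- data.frame(
    pmid = pmid, year = year,
    title = paste("registry study", pmid),
    abstract = abstract, authors = I(authors), journal = journal,
    pub_types = I(replicate(n, "Journal Article", simplify = FALSE)),
    language = "eng", stringsAsFactors = FALSE)
  corpus <- new_corpus(records)

  gt <- .ground_truth(spec, windows, win_of, mention, is_top, authors, ids)
  structure(list(corpus = corpus, lexicon = lex,
                 top_journals = jinfo$top, ground_truth = gt,
                 spec = spec, seed = seed),
            class = "synthetic_corpus")
}

# Planted text must be exactly recoverable: the filler template may not match
# any lexicon entry, and no planted surface may embed another entity's
# synonym at word boundaries.
.validate_filler <- function(lex) {
  if (is.null(lex)) return(invisible(TRUE))
  filler <- normalize_text(paste(.FILLER_HEAD, .FILLER_TAIL,
                                 "registry study s000000"))
  if (nrow(.match_text(filler, lex)))
    stop("lexicon synonym collides with the filler text template")
  for (id in unique(lex$entity_id)) {
    planted <- normalize_text(lex$synonym[match(id, lex$entity_id)])
    m <- .match_text(planted, lex)
    if (any(m$entity_id != id))
      stop("planted surface for '", id,
           "' embeds a synonym of another entity")
  }
  invisible(TRUE)
}

.ground_truth <- function(spec, windows, win_of, mention, is_top, authors,
                          ids) {
  nw <- nrow(windows)
  rows <- list()
  all_keys_by_w <- lapply(seq_len(nw), function(w)
    unique(unlist(lapply(authors[win_of == w], function(a) a$surname))))
  for (j in seq_along(ids)) {
    for (w in seq_len(nw)) {
      sel <- win_of == w & mention[, j]
      rows[[length(rows) + 1L]] <- data.frame(
        entity_id = ids[j], label = windows$label[w],
        n_i = sum(sel), n_T = sum(win_of == w),
        n_H20 = sum(sel & is_top),
        n_AI = length(unique(unlist(lapply(authors[sel], `[[`, "surname")))),
        n_AT = length(all_keys_by_w[[w]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Analytic expected indices of a synthetic specification
#'
#' Closed-form companions to the popularity and promising indices under the
#' generator's model: with mention probability `q_w`, `E[P1] = 100 * q_w` and
#' `E[P2] = q_w - q_{w-1}` (undefined on the first window). Pipeline
#' estimates converge to these as the per-window publication count grows.
#'
#' @param spec A [corpus_spec()].
#' @return Data frame `entity_id`, `label`, `q`, `e_p1`, `e_p2`.
#' @export
expected_indices <- function(spec) {
  nw <- nrow(spec$windows)
  out <- lapply(spec$trends, function(tr) {
    q <- trend_q(tr, nw)
    data.frame(entity_id = tr$entity_id, label = spec$windows$label,
               q = q, e_p1 = 100 * q, e_p2 = c(NA_real_, diff(q)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("Synthetic corpus: ", nrow(x$corpus$records), " records, ",
      nrow(x$spec$windows), " windows, ", length(x$spec$trends),
      " planted trends (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
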