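#' Build a consecutive windowing scheme
#'
#' Cuts a year span into consecutive windows of fixed width (inclusive years);
#' the final window is truncated when the span length is not a multiple of
#' the width. Five-year windows over 1951-2018 give 14 windows, the last
#' being the 3-year window "2016-2018".
#'
#' @param span Integer vector `c(first_year, last_year)`.
#' @param width Window width in years (>= 1), default 5.
#' @return A data frame of class `"windowing_scheme"` with columns
#'   `start_year`, `end_year`, `label` ("YYYY-YYYY"); windows are contiguous,
#'   non-overlapping, sorted, and cover the span exactly.
#' @examples
#' make_windows(c(1951, 2018), 5)
#' @export
make_windows <- function(span, width = 5L) {
  if (length(span) != 2L || is.na(span[1L]) || is.na(span[2L]) ||
      span[2L] < span[1L])
    stop("span must be c(first_year, last_year) with first_year <= last_year")
  if (width < 1L) stop("window width must be >= 1")
  starts <- seq(span[1L], span[2L], by = width)
  ends <- pmin(starts + width - 1L, span[2L])
  structure(data.frame(start_year = as.integer(starts),
                       end_year = as.integer(ends),
                       label = sprintf("%d-%d", starts, ends),
                       stringsAsFactors = FALSE),
            class = c("windowing_scheme", "data.frame"))
}

.window_width <- function(w) w$end_year - w$start_year + 1L

#' Per-window counts behind the four indices
#'
#' For one entity and one window computes the raw counts the indices are
#' ratios of:
#' \describe{
#'   \item{n_i}{publications in the window mentioning the entity (document
#'     frequency restricted to the window);}
#'   \item{n_T}{all publications in the window;}
#'   \item{n_H20}{entity publications in the window whose journal is in the
#'     designated top-journal set (normalized exact title match);}
#'   \item{n_AI}{distinct authors of the entity publications in the window;}
#'   \item{n_AT}{distinct authors of all publications in the window.}
#' }
#'
#' @param corpus A filtered [corpus].
#' @param index A `mention_index` built over the same corpus.
#' @param entity_id Entity to count.
#' @param window One-row window (from [make_windows()]).
#' @param top_journals Character vector of top-journal titles (compared after
#'   [normalize_text()]).
#' @param key_fun Author keying function.
#' @return One-row data frame `entity_id`, `label`, `n_i`, `n_T`, `n_H20`,
#'   `n_AI`, `n_AT`.
#' @export
count_window <- function(corpus, index, entity_id, window, top_journals,
                         key_fun = author_key) {
  recs <- corpus$records
  in_w <- recs$year >= window$start_year & recs$year <= window$end_year
  wrecs <- recs[in_w, , drop = FALSE]
  ent_pmids <- entity_docs(index, entity_id)
  erecs <- wrecs[wrecs$pmid %in% ent_pmids, , drop = FALSE]
  top_norm <- normalize_text(top_journals)
  data.frame(
    entity_id = entity_id, label = window$label,
    n_i = nrow(erecs), n_T = nrow(wrecs),
    n_H20 = sum(normalize_text(erecs$journal) %in% top_norm),
    n_AI = distinct_authors(erecs, key_fun = key_fun),
    n_AT = distinct_authors(wrecs, key_fun = key_fun),
    stringsAsFactors = FALSE)
}

#' The four entitymetric indices
#'
#' Elementary index computations on window counts; each returns `NA` (an
#' undefined value, not an error and never a zero) when its denominator is
#' zero.
#'
#' * `p1_index(n_i, n_T)` — Popularity: percentage of the window's
#'   publications mentioning the entity, `100 * n_i / n_T`.
#' * `p2_index(n_i, n_T, n_pi, n_pT)` — Promising: change in the popularity
#'   *fraction* relative to the preceding window of the same length,
#'   `n_i/n_T - n_pi/n_pT`. Reported on the fraction scale (a value of 0.06
#'   reads as "increased by 6 percentage points").
#' * `p3_index(n_H20, n_i)` — Prestige: percentage of the entity's
#'   publications appearing in the top-journal set, `100 * n_H20 / n_i`.
#' * `ci_index(n_AI, n_AT)` — Collaboration: percentage of the window's
#'   distinct authors who authored entity publications, `100 * n_AI / n_AT`.
#'
#' @param n_i,n_T,n_H20,n_AI,n_AT,n_pi,n_pT Window counts; see
#'   [count_window()]. The `p`-prefixed pair belongs to the preceding window.
#' @return Numeric value (vectorized), `NA` where undefined.
#' @name indices
NULL

#' @rdname indices
#' @export
p1_index <- function(n_i, n_T) ifelse(n_T > 0, 100 * n_i / n_T, NA_real_)

#' @rdname indices
#' @export
p2_index <- function(n_i, n_T, n_pi, n_pT)
  ifelse(n_T > 0 & n_pT > 0, n_i / n_T - n_pi / n_pT, NA_real_)

#' @rdname indices
#' @export
p3_index <- function(n_H20, n_i) ifelse(n_i > 0, 100 * n_H20 / n_i, NA_real_)

#' @rdname indices
#' @export
ci_index <- function(n_AI, n_AT) ifelse(n_AT > 0, 100 * n_AI / n_AT, NA_real_)

#' Full index table over entities and windows
#'
#' Computes, for every (entity, window) pair, the raw counts and the four
#' indices, plus threshold flags for the prestige and collaboration indices.
#' The promising index compares consecutive windows of equal width; it is
#' undefined (`NA`) on the first window — unless pre-span records are present
#' in the corpus before the first window, in which case the years immediately
#' preceding it (same width) serve as its baseline — and on a truncated final
#' window whose width differs from its predecessor.
#'
#' @param corpus A filtered [corpus].
#' @param index A `mention_index` over the same corpus.
#' @param windows A [windowing_scheme()].
#' @param top_journals Character vector of top-journal titles.
#' @param key_fun Author keying function, default [author_key()].
#' @param threshold Flag threshold in percent (default 5); flags are
#'   inclusive (`>= threshold`) and `NA` where the index is undefined.
#' @param entities Entities to tabulate (default: all lexicon entities in the
#'   mention index).
#' @return Data frame of class `"index_table"`: one row per (entity, window)
#'   with `entity_id`, `entity_type`, `label`, `start_year`, `end_year`, the
#'   five counts, `p1`, `p2`, `p3`, `ci`, `p3_flag`, `ci_flag`. Undefined
#'   cells are `NA`, never 0.
#' @export
compute_index_table <- function(corpus, index, windows, top_journals,
                                key_fun = author_key, threshold = 5,
                                entities = NULL) {
  if (is.null(entities)) entities <- names(index$mention_counts)
  rows <- list()
  for (ent in entities) {
    cw <- lapply(seq_len(nrow(windows)), function(i)
      count_window(corpus, index, ent, windows[i, ], top_journals,
                   key_fun = key_fun))
    cw <- do.call(rbind, cw)
    widths <- .window_width(windows)
    # pre-span baseline for the first window, if the corpus extends before it
    pre <- .pre_window_counts(corpus, index, ent, windows[1, ], widths[1])
    p2 <- rep(NA_real_, nrow(cw))
    if (!is.null(pre))
      p2[1] <- p2_index(cw$n_i[1], cw$n_T[1], pre$n_i, pre$n_T)
    for (i in seq_len(nrow(cw))[-1]) {
      if (widths[i] == widths[i - 1])
        p2[i] <- p2_index(cw$n_i[i], cw$n_T[i], cw$n_i[i - 1], cw$n_T[i - 1])
    }
    rows[[ent]] <- data.frame(
      entity_id = ent,
      entity_type = unname(index$entity_type[ent]),
      label = windows$label,
      start_year = windows$start_year, end_year = windows$end_year,
      n_i = cw$n_i, n_T = cw$n_T, n_H20 = cw$n_H20,
      n_AI = cw$n_AI, n_AT = cw$n_AT,
      p1 = p1_index(cw$n_i, cw$n_T),
      p2 = p2,
      p3 = p3_index(cw$n_H20, cw$n_i),
      ci = ci_index(cw$n_AI, cw$n_AT),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p3_flag <- ifelse(is.na(tab$p3), NA, tab$p3 >= threshold)
  tab$ci_flag <- ifelse(is.na(tab$ci), NA, tab$ci >= threshold)
  attr(tab, "threshold") <- threshold
  class(tab) <- c("index_table", "data.frame")
  tab
}

# Counts over the width-year window immediately preceding `window`, or NULL
# when the corpus holds no records before the first window.
.pre_window_counts <- function(corpus, index, entity_id, window, width) {
  if (!nrow(corpus$records) ||
      !any(corpus$records$year < window$start_year)) return(NULL)
  pre_w <- data.frame(start_year = window$start_year - width,
                      end_year = window$start_year - 1L,
                      label = sprintf("%d-%d", window$start_year - width,
                                      window$start_year - 1L),
                      stringsAsFactors = FALSE)
  count_window(corpus, index, entity_id, pre_w, character(0))
}

#' Export an index table as CSV
#'
#' Columns `entity_id,entity_type,window_label,p1,p2,p3,ci,p3_flag,ci_flag`;
#' undefined cells are written as empty fields, never as 0 or `"NaN"`.
#'
#' @param table An `index_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(table, path) {
  out <- data.frame(entity_id = table$entity_id,
                    entity_type = table$entity_type,
                    window_label = table$label,
                    p1 = table$p1, p2 = table$p2, p3 = table$p3,
                    ci = table$ci,
                    p3_flag = table$p3_flag, ci_flag = table$ci_flag,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
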