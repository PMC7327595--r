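#' Default research-phase scheme for the aspirin study span
#'
#' Four expert-defined eras of aspirin research: original use (1951-1960),
#' in-depth studies of pharmacological mechanisms and side effects
#' (1961-1990), repurposing for cardiovascular diseases (1991-2000) and
#' repurposing for other diseases (2001-2018). Any alternative contiguous,
#' non-overlapping scheme can be supplied in its place.
#'
#' @param phases Optional data frame with `phase`, `start_year`, `end_year`.
#' @return A data frame of class `"phase_scheme"`.
#' @export
phase_scheme <- function(phases = NULL) {
  if (is.null(phases)) {
    phases <- data.frame(
      phase = c("Phase 1", "Phase 2", "Phase 3", "Phase 4"),
      start_year = c(1951L, 1961L, 1991L, 2001L),
      end_year = c(1960L, 1990L, 2000L, 2018L),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("phase", "start_year", "end_year") %in% names(phases)))
  phases <- phases[order(phases$start_year), , drop = FALSE]
  if (any(phases$end_year < phases$start_year))
    stop("phase with end_year < start_year")
  if (nrow(phases) > 1 &&
      any(phases$start_year[-1] != phases$end_year[-nrow(phases)] + 1L))
    stop("phases must be contiguous and non-overlapping")
  rownames(phases) <- NULL
  class(phases) <- c("phase_scheme", "data.frame")
  phases
}

#' Rank entities of a type by corpus frequency
#'
#' @param index A `mention_index`.
#' @param entity_type One of `"disease"`, `"drug"`, `"gene"`.
#' @param k Maximum number of entities to return (>= 1).
#' @param mode Frequency definition: `"document"` (number of distinct
#'   publications mentioning the entity; the default used for rankings) or
#'   `"mention"` (total mention count).
#' @param lexicon Optional [entity_lexicon] used to resolve canonical names
#'   for tie-breaking and display; without it ties break by `entity_id`.
#' @return Data frame `entity_id`, `canonical_name` (if resolvable),
#'   `frequency`, sorted by frequency descending with ties broken
#'   lexicographically by canonical name.
#' @export
top_entities <- function(index, entity_type, k = 10L,
                         mode = c("document", "mention"), lexicon = NULL) {
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be >= 1")
  ids <- names(index$entity_type)[index$entity_type == entity_type]
  freq <- switch(mode,
                 document = document_frequency(index)[ids],
                 mention = index$mention_counts[ids])
  name <- if (!is.null(lexicon)) {
    cn <- lexicon$canonical_name[!duplicated(lexicon$entity_id)]
    names(cn) <- lexicon$entity_id[!duplicated(lexicon$entity_id)]
    unname(cn[ids])
  } else ids
  ord <- order(-freq, name)
  out <- data.frame(entity_id = ids[ord], canonical_name = name[ord],
                    frequency = as.integer(freq[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Window of an entity's index maximum
#'
#' Locates the earliest window where the given index attains its maximum
#' defined value for an entity; undefined (`NA`) cells never participate.
#'
#' @param table An `index_table` from [compute_index_table()].
#' @param entity_id Entity to scan.
#' @param index_name One of `"p1"`, `"p2"`, `"p3"`, `"ci"`.
#' @return One-row data frame `entity_id`, `index_name`, `label`,
#'   `start_year`, `end_year`, `value`. All-`NA` series are an error.
#' @export
argmax_window <- function(table, entity_id,
                          index_name = c("p1", "p2", "p3", "ci")) {
  index_name <- match.arg(index_name)
  sub <- table[table$entity_id == entity_id, , drop = FALSE]
  sub <- sub[order(sub$start_year), , drop = FALSE]
  vals <- sub[[index_name]]
  if (!nrow(sub) || all(is.na(vals)))
    stop("no defined ", index_name, " value for entity ", entity_id)
  i <- which(vals == max(vals, na.rm = TRUE))[1L]
  data.frame(entity_id = entity_id, index_name = index_name,
             label = sub$label[i], start_year = sub$start_year[i],
             end_year = sub$end_year[i], value = vals[i],
             stringsAsFactors = FALSE)
}

#' Assign a research phase to an index maximum
#'
#' A maximum's window is assigned to the phase containing the window's start
#' year; a window straddling a phase boundary therefore follows its start.
#'
#' @param max_rec A one-row maxima record from [argmax_window()] (or anything
#'   with a `start_year`).
#' @param phases A [phase_scheme()].
#' @return The phase name (character scalar); a window outside every phase is
#'   an error.
#' @export
assign_phase <- function(max_rec, phases = phase_scheme()) {
  y <- max_rec$start_year
  hit <- which(phases$start_year <= y & y <= phases$end_year)
  if (!length(hit))
    stop("window starting ", y, " lies outside every phase")
  phases$phase[hit[1L]]
}

#' Years between two windows
#'
#' The interval convention is the difference of window *start* years:
#' `interval_years(t1, t2) = t1$start_year - t2$start_year`. With `t1` the
#' popularity-maximum window and `t2` the prestige-maximum window, a positive
#' interval means prestige peaked earlier than popularity. The function is
#' antisymmetric and may return negative values.
#'
#' @param t1,t2 One-row windows (anything carrying `start_year`).
#' @return Integer number of years.
#' @examples
#' w <- make_windows(c(1951, 2018), 5)
#' interval_years(w[w$label == "1986-1990", ], w[w$label == "1966-1970", ])  # 20
#' @export
interval_years <- function(t1, t2) {
  as.integer(t1$start_year) - as.integer(t2$start_year)
}

#' Maxima-interval report: popularity vs prestige peaks
#'
#' For each entity finds the windows of maximum popularity (p1) and maximum
#' prestige (p3) and the interval in years between them (start-year
#' convention; positive = prestige peaked earlier). Entities with no defined
#' p1 or p3 cell are excluded and listed.
#'
#' @param table An `index_table`.
#' @param entities Entities to include (default: all in the table).
#' @return List with `intervals` (data frame `entity_id`, `t1_label`,
#'   `t2_label`, `years`), `mean_years` (mean interval, rounded to 1 decimal;
#'   `NA` when empty) and `excluded` (entity ids lacking a defined maximum).
#' @export
interval_report <- function(table, entities = unique(table$entity_id)) {
  rows <- list(); excluded <- character(0)
  for (ent in entities) {
    t1 <- tryCatch(argmax_window(table, ent, "p1"), error = function(e) NULL)
    t2 <- tryCatch(argmax_window(table, ent, "p3"), error = function(e) NULL)
    if (is.null(t1) || is.null(t2)) { excluded <- c(excluded, ent); next }
    rows[[ent]] <- data.frame(entity_id = ent, t1_label = t1$label,
                              t2_label = t2$label,
                              years = interval_years(t1, t2),
                              stringsAsFactors = FALSE)
  }
  intervals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity_id = character(), t1_label = character(),
               t2_label = character(), years = integer(),
               stringsAsFactors = FALSE)
  rownames(intervals) <- NULL
  list(intervals = intervals,
       mean_years = if (nrow(intervals)) round(mean(intervals$years), 1)
                    else NA_real_,
       excluded = excluded)
}
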