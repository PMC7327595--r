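#' Reference descriptive statistics of the aspirin literature, 1951-2018
#'
#' Published descriptive statistics of the aspirin-related PubMed literature
#' used as the package's worked reference: per 5-year window (final window
#' 2016-2018), the number of publications, distinct authors, mean authors per
#' publication and distinct journals; and the same quantities aggregated to
#' the four research phases plus the overall total. Publication counts are
#' additive across windows; distinct-author and distinct-journal counts are
#' not (an author active in two windows is counted once per window but once
#' overall), which is why the phase-level rows are carried explicitly rather
#' than derived.
#'
#' @param level `"window"` for the 14 window rows, `"phase"` for the 4 phase
#'   rows plus the `Total` row.
#' @return Data frame with `label`, `start_year`, `end_year`,
#'   `publications`, `authors`, `mean_authors`, `journals` (phase rows also
#'   carry `phase`).
#' @seealso [phase_totals()] to re-aggregate the window rows;
#'   [aspirin_reference_maxima()] for the index-maxima window pairs.
#' @export
aspirin_reference_stats <- function(level = c("window", "phase")) {
  level <- match.arg(level)
  f <- system.file("extdata",
                   sprintf("aspirin_%s_stats.tsv", level), package = "p3c",
                   mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, quote = "")
}

#' Reference index-maxima window pairs for the mechanism/side-effect entities
#'
#' For the nine biomedical entities whose popularity index peaked during the
#' mechanism-and-side-effect era of aspirin research: the window of maximum
#' P1 (`t1_label`), the window of maximum P3 (`t2_label`), and the published
#' interval in years between them.
#'
#' @return Data frame `entity`, `t1_label`, `t2_label`, `years`.
#' @export
aspirin_reference_maxima <- function() {
  f <- system.file("extdata", "aspirin_maxima_windows.tsv", package = "p3c",
                   mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, quote = "")
}

#' Aggregate window statistics to phases
#'
#' Sums additive per-window publication counts into phase totals (a window
#' belongs to the phase containing its start year). Only the publication
#' column is additive; distinct-author/journal columns are intentionally not
#' aggregated here.
#'
#' @param window_stats Data frame with `start_year` and `publications`
#'   columns (e.g. [aspirin_reference_stats()] or [corpus_summary()] output).
#' @param phases A [phase_scheme()].
#' @return Data frame `phase`, `publications`, plus a `Total` row.
#' @export
phase_totals <- function(window_stats, phases = phase_scheme()) {
  ph <- vapply(window_stats$start_year, function(y) {
    hit <- which(phases$start_year <= y & y <= phases$end_year)
    if (length(hit)) phases$phase[hit[1]] else NA_character_
  }, character(1))
  agg <- stats::aggregate(publications ~ phase,
                          data = data.frame(phase = ph,
                                            publications = window_stats$publications),
                          FUN = sum)
  agg <- agg[match(phases$phase[phases$phase %in% agg$phase], agg$phase), ]
  rbind(agg, data.frame(phase = "Total",
                        publications = sum(window_stats$publications)))
}
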