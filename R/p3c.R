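#' Fit the four entitymetric indices to a publication corpus
#'
#' The package's main entry point. Starting from a publication corpus and a
#' typed entity lexicon, it (1) filters records by type and language,
#' (2) tags document-level entity mentions by dictionary matching over
#' normalized titles and abstracts, (3) cuts the study span into fixed-width
#' windows and computes, per entity and window, the Popularity (P1),
#' Promising (P2), Prestige (P3) and Collaboration (CI) indices with their
#' 5% interest flags, and (4) locates each entity's index maxima, assigns a
#' research phase by the window of maximum P1, and reports the P1-vs-P3
#' maxima intervals.
#'
#' @param corpus A [corpus] (from [parse_medline_xml()], [read_fixture()],
#'   [as_corpus()] or [generate_corpus()]).
#' @param lexicon An [entity_lexicon].
#' @param top_journals Character vector of top-journal titles (the P3
#'   numerator criterion), or a path to a plain-text file with one title per
#'   line.
#' @param width Window width in years (default 5).
#' @param span Study span `c(first, last)`; defaults to the corpus span.
#' @param threshold Interest threshold in percent for the P3/CI flags
#'   (default 5, inclusive).
#' @param phases A [phase_scheme()] used for phase assignment.
#' @param key_fun Author keying function (default [author_key()]).
#' @param policy A [filter_policy()], or `NULL` to skip filtering.
#' @return An object of class `"p3c"`: a list with the filtered `corpus`,
#'   the `mentions` index, the windowing scheme, the per-window corpus
#'   `summary`, the index `table`, per-entity `maxima` (earliest window of
#'   the maximum of each index), `phase_by_p1` assignments, the maxima
#'   `intervals` report, and the inputs. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`, `simulate`.
#' @examples
#' spec <- corpus_spec(c(2001, 2020), m_w = 60, trends = list(
#'   trend_spec("D1", "disease", "exampleitis", baseline = 0.05,
#'              peak_window = 2, peak_height = 0.4)))
#' syn <- generate_corpus(spec, seed = 42)
#' fit <- p3c(syn$corpus, syn$lexicon, syn$top_journals)
#' fit
#' @export
p3c <- function(corpus, lexicon, top_journals, width = 5L, span = NULL,
                threshold = 5, phases = phase_scheme(),
                key_fun = author_key, policy = filter_policy()) {
  if (length(top_journals) == 1L && file.exists(top_journals))
    top_journals <- read_top_journals(top_journals)
  filtered <- if (is.null(policy)) corpus else filter_records(corpus, policy)
  if (!nrow(filtered$records)) stop("no records left after filtering")
  if (is.null(span)) span <- filtered$span
  windows <- make_windows(span, width)
  mentions <- build_mention_index(filtered, lexicon)
  table <- compute_index_table(filtered, mentions, windows, top_journals,
                               key_fun = key_fun, threshold = threshold)
  summary_tab <- corpus_summary(filtered, windows, key_fun = key_fun)

  ents <- unique(table$entity_id)
  maxima <- list()
  for (idx in c("p1", "p2", "p3", "ci")) {
    for (ent in ents) {
      m <- tryCatch(argmax_window(table, ent, idx), error = function(e) NULL)
      if (!is.null(m)) maxima[[paste(ent, idx)]] <- m
    }
  }
  maxima <- if (length(maxima)) do.call(rbind, maxima) else NULL
  if (!is.null(maxima)) rownames(maxima) <- NULL

  phase_by_p1 <- NULL
  if (!is.null(maxima)) {
    p1max <- maxima[maxima$index_name == "p1", , drop = FALSE]
    if (nrow(p1max)) {
      ph <- vapply(seq_len(nrow(p1max)), function(i)
        tryCatch(assign_phase(p1max[i, ], phases),
                 error = function(e) NA_character_), character(1))
      phase_by_p1 <- data.frame(entity_id = p1max$entity_id,
                                label = p1max$label, p1 = p1max$value,
                                phase = ph, stringsAsFactors = FALSE)
    }
  }

  structure(list(corpus = filtered, lexicon = lexicon,
                 top_journals = top_journals, windows = windows,
                 mentions = mentions, table = table, summary = summary_tab,
                 maxima = maxima, phase_by_p1 = phase_by_p1,
                 intervals = interval_report(table),
                 threshold = threshold, phases = phases, width = width,
                 key_fun = key_fun, call = match.call()),
            class = "p3c")
}

#' Read a top-journal list file
#'
#' Plain text, one journal title per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return Character vector of journal titles.
#' @export
read_top_journals <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @export
print.p3c <- function(x, ...) {
  cat("Entitymetric index fit (P1/P2/P3/CI)\n")
  cat("  corpus: ", nrow(x$corpus$records), " records, span ",
      x$corpus$span[1], "-", x$corpus$span[2], "\n", sep = "")
  cat("  windows: ", nrow(x$windows), " x ", x$width, "-year (",
      x$windows$label[1], " ... ", x$windows$label[nrow(x$windows)], ")\n",
      sep = "")
  cat("  entities: ", length(unique(x$table$entity_id)),
      "; threshold ", x$threshold, "%\n", sep = "")
  if (!is.null(x$phase_by_p1)) {
    cat("  phase of maximum P1:\n")
    for (i in seq_len(nrow(x$phase_by_p1)))
      cat(sprintf("    %-12s %s (P1 = %.2f%%) -> %s\n",
                  x$phase_by_p1$entity_id[i], x$phase_by_p1$label[i],
                  x$phase_by_p1$p1[i],
                  ifelse(is.na(x$phase_by_p1$phase[i]), "outside phases",
                         x$phase_by_p1$phase[i])))
  }
  invisible(x)
}

#' @export
summary.p3c <- function(object, ...) {
  structure(list(fit = object), class = "summary.p3c")
}

#' @export
print.summary.p3c <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-window corpus statistics:\n")
  print(f$summary, row.names = FALSE)
  if (nrow(f$intervals$intervals)) {
    cat("\nMaxima intervals (window of max P1 vs max P3, start-year years):\n")
    print(f$intervals$intervals, row.names = FALSE)
    cat(sprintf("mean interval: %.1f years\n", f$intervals$mean_years))
  }
  invisible(x)
}

#' @export
as.data.frame.p3c <- function(x, ...) {
  df <- x$table
  class(df) <- "data.frame"
  df
}

#' Plot entity index trajectories
#'
#' Draws the per-window trajectory of one or more indices for a single
#' entity, with research phases shaded in the background — the standard
#' exhibit for reading an entity's rise, peak and decline around a drug's
#' repurposing history. P2 (a fraction difference) is drawn on its own scale;
#' the percent indices share one panel.
#'
#' @param x A `"p3c"` fit.
#' @param entity_id Entity to plot (default: first in the table).
#' @param indices Which of `"p1"`, `"p2"`, `"p3"`, `"ci"` to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.p3c <- function(x, entity_id = NULL,
                     indices = c("p1", "p3", "ci"), ...) {
  if (is.null(entity_id)) entity_id <- x$table$entity_id[1]
  sub <- x$table[x$table$entity_id == entity_id, , drop = FALSE]
  sub <- sub[order(sub$start_year), , drop = FALSE]
  mid <- (sub$start_year + sub$end_year) / 2
  pct <- intersect(indices, c("p1", "p3", "ci"))
  y <- as.matrix(sub[pct])
  graphics::matplot(mid, y, type = "b", pch = 19, lty = 1,
                    xlab = "year", ylab = "index (%)",
                    main = paste("Entitymetric indices:", entity_id), ...)
  for (i in seq_len(nrow(x$phases)))
    graphics::abline(v = x$phases$start_year[i] - 0.5, col = "grey80",
                     lty = 3)
  graphics::legend("topright", legend = toupper(pct), col = seq_along(pct),
                   pch = 19, bty = "n")
  if ("p2" %in% indices) {
    graphics::plot(mid, sub$p2, type = "b", pch = 19, col = "grey30",
                   xlab = "year", ylab = "P2 (fraction change)",
                   main = paste("Promising index:", entity_id))
    graphics::abline(h = 0, lty = 2, col = "grey70")
  }
  invisible(x)
}

#' Simulate corpora from a fitted index model
#'
#' Uses the fitted per-window popularity fractions (`p1 / 100`) as the
#' mention probabilities of a synthetic-corpus specification with the same
#' windowing and per-window publication counts, and generates new corpora
#' from it. Refitting a simulated corpus recovers the original P1 profile up
#' to binomial noise, which makes this a direct parametric-bootstrap check of
#' the pipeline.
#'
#' @param object A `"p3c"` fit.
#' @param nsim Number of corpora to generate.
#' @param seed Integer seed; simulation `i` uses `seed + i - 1`.
#' @param ... Ignored.
#' @return A list of `nsim` [generate_corpus()] results.
#' @export
simulate.p3c <- function(object, nsim = 1, seed = 1L, ...) {
  tab <- object$table
  ents <- unique(tab$entity_id)
  trends <- lapply(ents, function(ent) {
    sub <- tab[tab$entity_id == ent, , drop = FALSE]
    sub <- sub[order(sub$start_year), , drop = FALSE]
    q <- ifelse(is.na(sub$p1), 0, sub$p1 / 100)
    syn <- object$lexicon$synonym[match(ent, object$lexicon$entity_id)]
    trend_spec(ent, unname(object$mentions$entity_type[ent]), syn, q = q)
  })
  m_w <- tab$n_T[match(object$windows$label, tab$label)]
  spec <- corpus_spec(c(object$windows$start_year[1],
                        object$windows$end_year[nrow(object$windows)]),
                      width = object$width, m_w = m_w, trends = trends)
  lapply(seq_len(nsim), function(i) generate_corpus(spec, seed = seed + i - 1L))
}
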