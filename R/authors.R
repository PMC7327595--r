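#' Deterministic author disambiguation key
#'
#' Collapses an author name to a normalized key: accent-folded, lower-cased
#' surname, a `|` separator, then the upper-cased first letters of each
#' given-name token. Two author slots are treated as the same person exactly
#' when their keys coincide. This surname + initials blocking is a simple,
#' fully reproducible surrogate for probabilistic author-name disambiguation;
#' any alternative keying can be passed wherever a `key_fun` argument is
#' accepted.
#'
#' @param surname Family name (non-empty) or a data frame with columns
#'   `surname`, `given` (rows are keyed individually).
#' @param given Given name(s); may be empty.
#' @return Character vector of keys, e.g. `"garcia|MJ"`.
#' @examples
#' author_key("García", "María J")   # "garcia|MJ"
#' author_key("Smith", "")           # "smith|"
#' @export
author_key <- function(surname, given = "") {
  if (is.data.frame(surname)) {
    return(author_key(surname$surname, surname$given))
  }
  if (any(is.na(surname)) || any(!nzchar(trimws(surname))))
    stop("author surname must be non-empty")
  sur <- gsub(" ", "", normalize_text(surname))
  given[is.na(given)] <- ""
  ini <- vapply(strsplit(normalize_text(given), " ", fixed = TRUE),
                function(toks) paste(toupper(substr(toks, 1L, 1L)),
                                     collapse = ""),
                character(1))
  paste0(sur, "|", ini)
}

#' Count distinct authors over records
#'
#' Cardinality of the set of author keys over every author slot of every
#' record. Used both for per-window descriptive statistics and for the
#' collaboration index denominators/numerators.
#'
#' @param records A `corpus`, or its `records` data frame (with the `authors`
#'   list column).
#' @param key_fun Keying function; defaults to [author_key()].
#' @return Integer count (0 for no records).
#' @export
distinct_authors <- function(records, key_fun = author_key) {
  if (inherits(records, "corpus")) records <- records$records
  if (!nrow(records)) return(0L)
  keys <- unlist(lapply(records$authors, function(au) {
    if (is.null(au) || !nrow(au)) character(0) else key_fun(au)
  }))
  length(unique(keys))
}
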