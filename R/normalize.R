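# Latin accent folding done by explicit character map: iconv's //TRANSLIT is
# locale-dependent and inserts apostrophes for combining accents, which would
# then be eaten by the punctuation rule and split tokens apart.
.accent_from <- paste0(
  "áàâäãåāăą",      # a variants
  "çćčĉ",                                    # c variants
  "đď",                                                # d variants
  "éèêëēėęě",            # e variants
  "ğġ",                                                # g variants
  "íìîïīįı",                  # i variants
  "ñńň",                                          # n variants
  "óòôöõøōő",            # o variants
  "ŕř",                                                # r variants
  "śšş",                                          # s variants
  "ťţ",                                                # t variants
  "úùûüūůűų",            # u variants
  "ýÿ",                                                # y variants
  "žźż"                                           # z variants
)
.accent_to <- paste0(
  "aaaaaaaaa", "cccc", "dd", "eeeeeeee", "gg", "iiiiiii",
  "nnn", "oooooooo", "rr", "sss", "tt", "uuuuuuuu", "yy", "zzz"
)

fold_accents <- function(x) {
  x <- gsub("æ", "ae", x, fixed = TRUE)
  x <- gsub("œ", "oe", x, fixed = TRUE)
  x <- gsub("ß", "ss", x, fixed = TRUE)
  chartr(.accent_from, .accent_to, x)
}

#' Normalize free text for dictionary matching
#'
#' Applies the deterministic normalization used throughout the package before
#' any dictionary lookup: lower-casing, Latin accent folding, removal of
#' subscript underscore markup (so `P2Y_12_` becomes `p2y12`), replacement of
#' punctuation by single spaces, and whitespace collapsing. ASCII hyphens
#' flanked by alphanumerics on both sides are kept (so `cox-2` survives as one
#' token), while any other hyphen or dash becomes a space.
#'
#' The function is idempotent: `normalize_text(normalize_text(x))` equals
#' `normalize_text(x)`.
#'
#' @param x Character vector of raw text (UTF-8). `NA` is treated as `""`.
#' @return Character vector of normalized text, same length as `x`.
#' @examples
#' normalize_text("Acetylsalicylic Acid,")
#' normalize_text("COX-2–dependent")  # en dash is punctuation
#' @export
normalize_text <- function(x) {
  x[is.na(x)] <- ""
  x <- tolower(fold_accents(tolower(x)))
  x <- gsub("_", "", x, fixed = TRUE)
  # everything outside [a-z0-9-] (including any remaining non-ASCII) -> space
  x <- gsub("[^a-z0-9-]", " ", x, useBytes = FALSE)
  # hyphens are kept only between alphanumerics
  x <- gsub("(?<![a-z0-9])-", " ", x, perl = TRUE)
  x <- gsub("-(?![a-z0-9])", " ", x, perl = TRUE)
  x <- gsub("[ ]+", " ", x)
  trimws(x)
}

# TRUE where the character at position i (1-based) of `text` is a word
# character under the matcher's boundary rule; positions outside the string
# count as boundaries.
.is_word_char <- function(text, pos) {
  n <- nchar(text)
  ok <- pos >= 1L & pos <= n
  out <- logical(length(pos))
  if (any(ok))
    out[ok] <- grepl("[a-z0-9]", substring(text, pos[ok], pos[ok]))
  out
}
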