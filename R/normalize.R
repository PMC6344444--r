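# Text normalization: publisher-independent clean-up applied to every
# document before sentence splitting. PDF extractions differ wildly across
# publishers (hard line wraps, end-of-line hyphenation, typographic
# ligatures, mixed newline conventions); downstream annotation assumes none
# of these artifacts survive.

# Typographic ligature codepoints expanded to ASCII letter pairs/triples.
LIGATURES <- c(
  "ﬀ" = "ff", "ﬁ" = "fi", "ﬂ" = "fl",
  "ﬃ" = "ffi", "ﬄ" = "ffl", "ﬅ" = "st", "ﬆ" = "st",
  "Ĳ" = "IJ", "ĳ" = "ij"
)

#' Normalize extracted document text
#'
#' Repairs the extraction artifacts that make PDF-derived text heterogeneous
#' across publishers, producing the canonical text that sentence splitting,
#' tokenization and name recognition operate on:
#'
#' * Unicode is normalized to NFC; carriage returns become newlines; other
#'   C0 control characters are dropped.
#' * Typographic ligatures (fi, fl, ff, ...) are expanded to ASCII letter
#'   pairs and soft hyphens (U+00AD) are removed.
#' * Line-break hyphenation is repaired: a word fragment ending in a hyphen
#'   at the end of a line followed by a lowercase fragment is joined into
#'   one word (`"disper-\\nsal"` becomes `"dispersal"`).
#' * Whitespace runs collapse to a single space, except that runs containing
#'   two or more newlines are preserved as a paragraph separator (`"\\n\\n"`),
#'   which the sentence splitter treats as a hard boundary.
#'
#' The function is total (never errors) and idempotent:
#' `normalize_text(normalize_text(x))` equals `normalize_text(x)`.
#'
#' @param raw_text Character vector of raw extracted text.
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_text("seed disper-\nsal")
#' normalize_text("a  b\tc")
normalize_text <- function(raw_text) {
  x <- as.character(raw_text)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_nfc(x)
  # newline conventions, then strip remaining control chars (keep \n, \t)
  x <- stringi::stri_replace_all_regex(x, "\r\n?", "\n")
  x <- stringi::stri_replace_all_regex(x, "[\\x00-\\x08\\x0B\\x0C\\x0E-\\x1F]", "")
  # ligatures and soft hyphens
  x <- stringi::stri_replace_all_fixed(
    x, names(LIGATURES), unname(LIGATURES),
    vectorize_all = FALSE
  )
  x <- stringi::stri_replace_all_fixed(x, "\u00AD", "")
  # line-break hyphenation: fragment + "-" + newline + lowercase fragment
  x <- stringi::stri_replace_all_regex(
    x, "(\\p{L})-[ \\t]*\\n[ \\t]*(\\p{Ll})", "$1$2"
  )
  # whitespace: paragraph breaks (>= 2 newlines in a run) survive as \n\n,
  # every other whitespace run collapses to a single space; U+E000 is a
  # private-use placeholder that cannot occur after the control strip above
  x <- stringi::stri_replace_all_fixed(x, "\uE000", "")
  x <- stringi::stri_replace_all_regex(x, "\\s*\\n\\s*\\n\\s*", "\uE000")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  x <- stringi::stri_replace_all_fixed(x, "\uE000", "\n\n")
  stringi::stri_trim_both(x)
}
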