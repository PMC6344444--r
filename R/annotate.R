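# Sentence splitting, tokenization and content-word tagging.
#
# Sentences are the atomic snippet unit, so the splitter is conservative:
# a boundary needs sentence-final punctuation followed by whitespace and
# an uppercase letter or digit, and is vetoed after single-letter
# abbreviations ("M. huberi" must stay one sentence), after common
# scholarly abbreviations (et al., Fig., sp., cf., ...), and inside
# parentheses. A paragraph break always forces a boundary.

# lowercase abbreviation stems that never end a sentence (match on the
# word immediately before the period, case-insensitive)
SENT_ABBREV <- c(
  "al", "cf", "fig", "figs", "sp", "spp", "var", "subsp", "ssp",
  "vs", "ca", "approx", "no", "nos", "pers", "comm", "obs", "ed", "eds",
  "vol", "pp", "st", "dr", "prof", "mr", "mrs", "ms"
)

#' Split a document into sentences
#'
#' @param text A normalized text string (see [normalize_text()]); pass a
#'   readable document's `text`.
#' @param doc_id Document identifier recorded on each sentence.
#' @return A tibble with one row per sentence: `doc_id`, `sent_index`
#'   (1-based), `start`, `end` (1-based inclusive character offsets into
#'   `text`, so `substr(text, start, end)` equals `text` of the row) and
#'   `text`.
#' @export
#' @examples
#' split_sentences("Monkeys eat fruit. Seeds are dispersed.")
#' split_sentences("Fruits of M. huberi are swallowed by monkeys.")
split_sentences <- function(text, doc_id = NA_character_) {
  stopifnot(length(text) == 1)
  empty <- tibble::tibble(
    doc_id = character(), sent_index = integer(),
    start = integer(), end = integer(), text = character()
  )
  if (is.na(text) || !nzchar(stringi::stri_trim_both(text))) return(empty)

  n <- stringi::stri_length(text)
  chars <- stringi::stri_sub(text, seq_len(n), seq_len(n))
  # candidate boundaries: position AFTER which a new sentence starts
  breaks <- integer(0)
  depth <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- max(0L, depth - 1L)
    # paragraph break: "\n\n" forces a boundary
    if (ch == "\n" && i < n && chars[i + 1L] == "\n") {
      breaks <- c(breaks, i - 1L)
      i <- i + 2L
      next
    }
    if (ch %in% c(".", "!", "?") && depth == 0L) {
      # absorb a run of terminal punctuation (e.g. "?!", "...")
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      # require whitespace then uppercase/digit (closing quote allowed)
      k <- j + 1L
      if (k <= n && chars[k] %in% c(" ", "\n")) {
        m <- k
        while (m <= n && chars[m] %in% c(" ", "\n")) m <- m + 1L
        nxt <- if (m <= n) chars[m] else ""
        if (stringi::stri_detect_regex(nxt, "[\\p{Lu}\\p{N}]")) {
          veto <- ch == "." && abbrev_before(text, i)
          if (!veto) breaks <- c(breaks, j)
        }
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }

  bounds <- unique(sort(breaks))
  starts_at <- c(1L, bounds + 1L)
  ends_at <- c(bounds, n)
  rows <- list()
  for (s in seq_along(starts_at)) {
    seg <- stringi::stri_sub(text, starts_at[s], ends_at[s])
    trimmed <- stringi::stri_locate_first_regex(seg, "\\S(?s:.*\\S)?|\\S")
    if (is.na(trimmed[1, 1])) next
    st <- starts_at[s] + trimmed[1, 1] - 1L
    en <- starts_at[s] + trimmed[1, 2] - 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = doc_id, sent_index = NA_integer_,
      start = st, end = en,
      text = stringi::stri_sub(text, st, en)
    )
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out$sent_index <- seq_len(nrow(out))
  out
}

# TRUE when the period at position `pos` follows a word that never ends a
# sentence: a single letter ("M.", the "g" of "e.g.") or a scholarly
# abbreviation ("al", "Fig", "sp", ...)
abbrev_before <- function(text, pos) {
  prefix <- stringi::stri_sub(text, max(1L, pos - 15L), pos - 1L)
  word <- stringi::stri_match_last_regex(prefix, "([\\p{L}]+)$")[1, 2]
  if (is.na(word)) return(FALSE)
  stringi::stri_length(word) == 1L ||
    stringi::stri_trans_tolower(word) %in% SENT_ABBREV
}

#' Tokenize a sentence
#'
#' Tokens are maximal runs of letters/digits, with internal hyphens and
#' apostrophes kept ("seed-dispersal" is one token); punctuation is
#' discarded. Offsets are 1-based inclusive and index into the document
#' text when `offset` is the sentence's `start`.
#'
#' @param sentence_text Sentence string.
#' @param offset Character offset of the sentence's first character in the
#'   document text (1 for standalone strings).
#' @return A tibble with `surface`, `norm` (lowercased), `start`, `end`.
#' @export
#' @examples
#' tokenize("(Ateles paniscus) eats seed-dispersal syndromes!")$surface
tokenize <- function(sentence_text, offset = 1L) {
  loc <- stringi::stri_locate_all_regex(
    sentence_text,
    "[\\p{L}\\p{N}]+(?:[-'’][\\p{L}\\p{N}]+)*"
  )[[1]]
  if (nrow(loc) == 0 || is.na(loc[1, 1])) {
    return(tibble::tibble(
      surface = character(), norm = character(),
      start = integer(), end = integer()
    ))
  }
  surface <- stringi::stri_sub(sentence_text, loc[, 1], loc[, 2])
  tibble::tibble(
    surface = surface,
    norm = stringi::stri_trans_tolower(surface),
    start = as.integer(loc[, 1] + offset - 1L),
    end = as.integer(loc[, 2] + offset - 1L)
  )
}

#' Flag content words (nouns, verbs, adjectives)
#'
#' Only content words enter the co-occurrence window. With a `tagger`
#' (plug-in contract: a function mapping a character vector of token
#' surfaces to an equal-length vector of coarse tags), a token is content
#' iff its tag is `NOUN`, `VERB` or `ADJ` — proper nouns count as `NOUN`,
#' since scientific names are the application's anchors. Without a tagger,
#' a deterministic fallback is used: a token is content iff it is not in
#' the bundled stop-word list ([obsmine_stopwords()]), has at least 2
#' characters, and is not purely numeric. In both modes stop words are
#' never content. If the tagger errors on a sentence, that sentence falls
#' back to the stop-word rule with a warning.
#'
#' @param tokens Token tibble from [tokenize()].
#' @param tagger Optional tagging function (see above); `NULL` for the
#'   stop-word fallback.
#' @param stopwords Stop-word list; defaults to the bundled one.
#' @return `tokens` with added `pos` (`"NOUN" "VERB" "ADJ" "OTHER"` or
#'   `NA` in fallback mode) and `is_content` columns.
#' @export
#' @examples
#' tok <- tokenize("However the monkeys swallow ripe fruits")
#' tag_content_words(tok)$is_content
tag_content_words <- function(tokens, tagger = NULL, stopwords = obsmine_stopwords()) {
  fallback <- function(norm) {
    !(norm %in% stopwords) &
      stringi::stri_length(norm) >= 2 &
      !stringi::stri_detect_regex(norm, "^\\p{N}+$")
  }
  if (nrow(tokens) == 0) {
    tokens$pos <- character(0)
    tokens$is_content <- logical(0)
    return(tokens)
  }
  if (is.null(tagger)) {
    tokens$pos <- NA_character_
    tokens$is_content <- fallback(tokens$norm)
    return(tokens)
  }
  tags <- tryCatch(
    {
      out <- as.character(tagger(tokens$surface))
      if (length(out) != nrow(tokens)) stop("tagger returned wrong length")
      out
    },
    error = function(e) {
      warning(
        "tagger failed (", conditionMessage(e),
        "); falling back to the stop-word rule for this sentence",
        call. = FALSE
      )
      NULL
    }
  )
  if (is.null(tags)) {
    tokens$pos <- NA_character_
    tokens$is_content <- fallback(tokens$norm)
  } else {
    tags[tags == "PROPN"] <- "NOUN"
    tags[!tags %in% c("NOUN", "VERB", "ADJ")] <- "OTHER"
    tokens$pos <- tags
    # stop words are never content even if the tagger says otherwise
    tokens$is_content <- tags %in% c("NOUN", "VERB", "ADJ") &
      !(tokens$norm %in% stopwords)
  }
  tokens
}

#' Annotate a corpus: sentences, tokens, content flags
#'
#' Runs sentence splitting, tokenization and content-word tagging over
#' every machine-readable document of a corpus. Unreadable documents are
#' excluded (they have no text).
#'
#' @param corpus An `obs_corpus` from [load_corpus()].
#' @param tagger Optional part-of-speech tagger plug-in, see
#'   [tag_content_words()].
#' @param stopwords Stop-word list for the content filter.
#' @return An `obs_annotations`: list with `corpus`, `sentences` (tibble:
#'   `doc_id`, `sent_index`, `start`, `end`, `text`) and `tokens` (tibble:
#'   `doc_id`, `sent_index`, `surface`, `norm`, `start`, `end`, `pos`,
#'   `is_content`).
#' @export
annotate_corpus <- function(corpus, tagger = NULL, stopwords = obsmine_stopwords()) {
  stopifnot(inherits(corpus, "obs_corpus"))
  docs <- readable_docs(corpus)
  sent_list <- list()
  tok_list <- list()
  for (i in seq_len(nrow(docs))) {
    sents <- split_sentences(docs$text[i], doc_id = docs$doc_id[i])
    sent_list[[length(sent_list) + 1L]] <- sents
    for (s in seq_len(nrow(sents))) {
      tok <- tokenize(sents$text[s], offset = sents$start[s])
      tok <- tag_content_words(tok, tagger = tagger, stopwords = stopwords)
      if (nrow(tok) > 0) {
        tok$doc_id <- docs$doc_id[i]
        tok$sent_index <- sents$sent_index[s]
        tok_list[[length(tok_list) + 1L]] <- tok
      }
    }
  }
  sentences <- if (length(sent_list)) {
    dplyr::bind_rows(sent_list)
  } else {
    split_sentences("")
  }
  tokens <- dplyr::bind_rows(tok_list)
  if (nrow(tokens) == 0) {
    tokens <- tibble::tibble(
      surface = character(), norm = character(), start = integer(),
      end = integer(), pos = character(), is_content = logical(),
      doc_id = character(), sent_index = integer()
    )
  }
  tokens <- tokens[, c(
    "doc_id", "sent_index", "surface", "norm",
    "start", "end", "pos", "is_content"
  )]
  structure(
    list(corpus = corpus, sentences = sentences, tokens = tokens),
    class = "obs_annotations"
  )
}

#' @export
print.obs_annotations <- function(x, ...) {
  cat(sprintf(
    "<obs_annotations> %d sentence%s, %d tokens (%d content) across %d document%s\n",
    nrow(x$sentences), if (nrow(x$sentences) == 1) "" else "s",
    nrow(x$tokens), sum(x$tokens$is_content),
    length(unique(x$sentences$doc_id)),
    if (length(unique(x$sentences$doc_id)) == 1) "" else "s"
  ))
  invisible(x)
}

# content tokens of one sentence, in order, with their content-position
content_stream <- function(tokens) {
  ct <- tokens[tokens$is_content, , drop = FALSE]
  ct[order(ct$start), , drop = FALSE]
}
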