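# Skip-n-gram co-occurrence counting over content words.
#
# A moving window of n content words slides over each sentence; every
# unordered pair of words co-occurring inside some window position is one
# pair occurrence, pooled regardless of the distance separating the two
# words. Counting every position pair (i, j) with j - i <= n - 1 is the
# deterministic equivalent: each forward window contributes its focus word
# paired with every other member, deduplicated per position pair. Pairs
# are pooled corpus-wide and ranked by frequency.

#' Co-occurrence configuration
#'
#' @param n Window size in content words (default 6, the setting used for
#'   mining biodiversity literature); two words co-occur when at most
#'   `n - 1` content-word positions apart.
#' @param within_sentence Confine windows to sentences (default `TRUE`).
#'   `FALSE` lets windows span a whole document's content-word stream —
#'   an experimental setting, off by default, since the sentence is the
#'   snippet unit.
#' @return A `cooccurrence_config` list.
#' @export
cooccurrence_config <- function(n = 6, within_sentence = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("window size n must be an integer >= 2", call. = FALSE)
  structure(
    list(n = n, within_sentence = isTRUE(within_sentence)),
    class = "cooccurrence_config"
  )
}

#' Skip-n-gram pairs of one content-word stream
#'
#' Returns the multiset of unordered word pairs produced by a skip-n-gram
#' window of size `n` over one ordered stream of content words: one pair
#' occurrence for every position pair `(i, j)`, `i < j`,
#' `j - i <= n - 1`. Identical forms at different positions pair like any
#' other words (a repeated word can co-occur with itself).
#'
#' @param content_tokens Character vector of content-word forms in
#'   sentence order (lowercased).
#' @param n Window size (>= 2).
#' @return A tibble `term_a`, `term_b` (with `term_a <= term_b`), `count`,
#'   sorted by count descending then alphabetically.
#' @export
#' @examples
#' skipgram_pairs(c("monkeys", "swallow", "seeds"), n = 2)
#' skipgram_pairs(c("a", "b", "c"), n = 3)
skipgram_pairs <- function(content_tokens, n = 6) {
  n <- as.integer(n)
  stopifnot(n >= 2)
  L <- length(content_tokens)
  if (L < 2) {
    return(tibble::tibble(
      term_a = character(), term_b = character(), count = integer()
    ))
  }
  a_all <- character(0)
  b_all <- character(0)
  for (d in seq_len(min(n - 1L, L - 1L))) {
    i <- seq_len(L - d)
    a_all <- c(a_all, content_tokens[i])
    b_all <- c(b_all, content_tokens[i + d])
  }
  lo <- pmin(a_all, b_all)
  hi <- pmax(a_all, b_all)
  key <- paste(lo, hi, sep = "\u001F")
  tab <- table(key)
  parts <- stringi::stri_split_fixed(names(tab), "\u001F")
  out <- tibble::tibble(
    term_a = vapply(parts, `[[`, character(1), 1),
    term_b = vapply(parts, `[[`, character(1), 2),
    count = as.integer(tab)
  )
  out[order(-out$count, out$term_a, out$term_b), , drop = FALSE]
}

#' Count and rank word co-occurrences over a corpus
#'
#' Pools skip-n-gram pair occurrences over every sentence of every
#' machine-readable document (windows never cross sentence boundaries
#' under the default configuration) and ranks pairs by pooled frequency,
#' ties broken alphabetically — the ranking a user scans, optionally
#' filtered through a biodiversity dictionary
#' ([filter_pairs_by_dictionary()]), to discover observation-bearing word
#' combinations.
#'
#' @param ann An `obs_annotations` from [annotate_corpus()].
#' @param config A [cooccurrence_config()].
#' @return A tibble `term_a`, `term_b`, `count`, `n_docs` (number of
#'   documents contributing at least one occurrence), `doc_ids`
#'   (list-column), sorted by `count` descending, ties by `term_a`,
#'   `term_b`.
#' @export
count_cooccurrences <- function(ann, config = cooccurrence_config()) {
  stopifnot(inherits(ann, "obs_annotations"), inherits(config, "cooccurrence_config"))
  toks <- ann$tokens[ann$tokens$is_content, , drop = FALSE]
  empty <- tibble::tibble(
    term_a = character(), term_b = character(), count = integer(),
    n_docs = integer(), doc_ids = list()
  )
  if (nrow(toks) == 0) return(empty)
  unit <- if (config$within_sentence) {
    paste(toks$doc_id, toks$sent_index, sep = "\u001F")
  } else {
    toks$doc_id
  }
  per_unit <- list()
  for (u in unique(unit)) {
    sel <- toks[unit == u, , drop = FALSE]
    sel <- sel[order(sel$sent_index, sel$start), , drop = FALSE]
    pairs <- skipgram_pairs(sel$norm, n = config$n)
    if (nrow(pairs) > 0) {
      pairs$doc_id <- sel$doc_id[1]
      per_unit[[length(per_unit) + 1L]] <- pairs
    }
  }
  if (length(per_unit) == 0) return(empty)
  all_pairs <- dplyr::bind_rows(per_unit)
  grouped <- dplyr::group_by(all_pairs, .data$term_a, .data$term_b)
  out <- dplyr::summarise(
    grouped,
    count = sum(.data$count),
    n_docs = dplyr::n_distinct(.data$doc_id),
    doc_ids = list(sort(unique(.data$doc_id))),
    .groups = "drop"
  )
  out[order(-out$count, out$term_a, out$term_b), , drop = FALSE]
}

#' Look up one unordered pair in a ranked co-occurrence table
#'
#' Order-insensitive: `(a, b)` and `(b, a)` retrieve the same row.
#'
#' @param pairs Ranked pair tibble from [count_cooccurrences()].
#' @param term_a,term_b The two (lowercased) terms.
#' @return The matching row (zero rows when the pair never co-occurs).
#' @export
lookup_pair <- function(pairs, term_a, term_b) {
  lo <- min(term_a, term_b)
  hi <- max(term_a, term_b)
  pairs[pairs$term_a == lo & pairs$term_b == hi, , drop = FALSE]
}

#' Per-taxon co-occurrence table (experimental)
#'
#' Ranks word co-occurrences computed only over the sentences that mention
#' a given taxon, characterizing the semantic context in which the taxon
#' appears. Experimental: with few mentioning sentences the ranking is
#' noisy.
#'
#' @param ann An `obs_annotations`.
#' @param mentions Corpus mention tibble from [find_names()].
#' @param name_query Canonical name (or bare genus) to restrict to.
#' @param config A [cooccurrence_config()].
#' @return A ranked pair tibble as in [count_cooccurrences()].
#' @export
taxon_cooccurrences <- function(ann, mentions, name_query,
                                config = cooccurrence_config()) {
  sel <- taxon_sites(mentions, name_query)
  keep <- paste(ann$tokens$doc_id, ann$tokens$sent_index) %in%
    paste(sel$doc_id, sel$sent_index)
  sub <- ann
  sub$tokens <- ann$tokens[keep, , drop = FALSE]
  count_cooccurrences(sub, config)
}

#' Export a ranked co-occurrence table as TSV
#'
#' Columns `term_a`, `term_b`, `count`, `n_docs`; UTF-8; deterministic row
#' order (the table's ranking).
#'
#' @param pairs Pair tibble from [count_cooccurrences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs[, c("term_a", "term_b", "count", "n_docs")])
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
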