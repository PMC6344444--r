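# Snippet retrieval — the tool's primary output. A snippet is exactly one
# sentence, annotated with the scientific names and dictionary/pair terms
# it contains, retrieved either by taxon (byTaxa) or by word pair
# (byKeywords).

empty_snippets <- function() {
  tibble::tibble(
    doc_id = character(), sent_index = integer(),
    start = integer(), end = integer(), text = character(),
    matched_names = list(), matched_terms = list(), query = character()
  )
}

# sentences (doc_id, sent_index) mentioning a canonical name or genus
taxon_sites <- function(mentions, name_query) {
  if (nrow(mentions) == 0) {
    return(tibble::tibble(doc_id = character(), sent_index = integer()))
  }
  is_genus_query <- !stringi::stri_detect_fixed(name_query, " ")
  hit <- if (is_genus_query) {
    genus_of <- vapply(
      stringi::stri_split_fixed(mentions$canonical, " "),
      `[[`, character(1), 1
    )
    genus_of == name_query
  } else {
    mentions$canonical == name_query
  }
  dplyr::distinct(mentions[hit, c("doc_id", "sent_index"), drop = FALSE])
}

#' Filter a ranked co-occurrence table through a biodiversity dictionary
#'
#' Keeps exactly the pairs in which at least one member term belongs to
#' the dictionary, preserving the input ranking (the output is a
#' subsequence of the input). Single-member matching is deliberate: a
#' dictionary term like "eat" surfaces both "eat + fruit" (frugivory) and
#' "eat + prey" (predation); disambiguating is the user's call.
#'
#' @param pairs Ranked pair tibble from [count_cooccurrences()].
#' @param dict An `obs_dictionary`, or a name/path accepted by
#'   [load_dictionary()].
#' @return The filtered pair tibble, original order preserved.
#' @export
filter_pairs_by_dictionary <- function(pairs, dict) {
  dict <- as_dictionary(dict)
  keep <- pairs$term_a %in% dict$terms | pairs$term_b %in% dict$terms
  pairs[keep, , drop = FALSE]
}

# dictionary-term occurrences (any token) within given sentences
dict_matches <- function(tokens, dict) {
  hits <- tokens[tokens$norm %in% dict$terms, , drop = FALSE]
  tibble::tibble(
    doc_id = hits$doc_id, sent_index = hits$sent_index,
    term = hits$norm, start = hits$start, end = hits$end
  )
}

snippet_row <- function(sent, names_tbl, terms_tbl, query) {
  tibble::tibble(
    doc_id = sent$doc_id, sent_index = sent$sent_index,
    start = sent$start, end = sent$end, text = sent$text,
    matched_names = list(names_tbl), matched_terms = list(terms_tbl),
    query = query
  )
}

#' Retrieve snippets by taxon (byTaxa)
#'
#' Returns one snippet per sentence whose recognized names include the
#' queried canonical name (exact match, e.g. `"Ateles paniscus"`) or whose
#' genus equals a bare-genus query (e.g. `"Ateles"`). Each snippet carries
#' the matching name mentions with their spans; when a dictionary is
#' given, occurrences of its terms in the sentence are annotated too.
#' An unknown name yields an empty snippet set, not an error.
#'
#' @param ann An `obs_annotations`.
#' @param mentions Corpus mention tibble from [find_names()].
#' @param name_query Canonical binomial, or bare genus for a genus-level
#'   query.
#' @param dict Optional dictionary (object, built-in name or path) whose
#'   term occurrences are annotated on each snippet.
#' @return A snippet tibble, ordered by `(doc_id, sent_index)`: `doc_id`,
#'   `sent_index`, `start`, `end`, `text`, `matched_names` and
#'   `matched_terms` (list-columns of span tibbles), `query`.
#' @export
snippets_by_taxa <- function(ann, mentions, name_query, dict = NULL) {
  stopifnot(inherits(ann, "obs_annotations"))
  sites <- taxon_sites(mentions, name_query)
  if (nrow(sites) == 0) return(empty_snippets())
  if (!is.null(dict)) dict <- as_dictionary(dict)
  sites <- sites[order(sites$doc_id, sites$sent_index), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(sites))) {
    sent <- ann$sentences[
      ann$sentences$doc_id == sites$doc_id[r] &
        ann$sentences$sent_index == sites$sent_index[r], ,
      drop = FALSE
    ]
    if (nrow(sent) == 0) next
    men <- mentions[
      mentions$doc_id == sites$doc_id[r] &
        mentions$sent_index == sites$sent_index[r], ,
      drop = FALSE
    ]
    names_tbl <- tibble::tibble(
      canonical = men$canonical, verbatim = men$verbatim,
      start = men$start, end = men$end
    )
    terms_tbl <- if (is.null(dict)) {
      tibble::tibble(term = character(), start = integer(), end = integer())
    } else {
      toks <- ann$tokens[
        ann$tokens$doc_id == sites$doc_id[r] &
          ann$tokens$sent_index == sites$sent_index[r], ,
        drop = FALSE
      ]
      m <- dict_matches(toks, dict)
      tibble::tibble(term = m$term, start = m$start, end = m$end)
    }
    out[[length(out) + 1L]] <- snippet_row(
      sent[1, ], names_tbl, terms_tbl,
      paste0("byTaxa:", name_query)
    )
  }
  if (length(out) == 0) return(empty_snippets())
  dplyr::bind_rows(out)
}

# qualifying position pairs of (term_a, term_b) in one sentence's content
# stream under the window constraint |i - j| <= n - 1; returns the index
# pairs (positions in the content stream)
qualifying_pairs <- function(norms, term_a, term_b, n) {
  pos_a <- which(norms == term_a)
  pos_b <- which(norms == term_b)
  if (length(pos_a) == 0 || length(pos_b) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  grid <- expand.grid(i = pos_a, j = pos_b)
  if (term_a == term_b) {
    grid <- grid[grid$i < grid$j, , drop = FALSE]
  }
  grid <- grid[abs(grid$j - grid$i) <= n - 1 & grid$i != grid$j, , drop = FALSE]
  if (term_a == term_b) {
    # unordered: (i, j) and (j, i) are one occurrence
    grid <- grid[grid$i < grid$j, , drop = FALSE]
  }
  as.matrix(grid)
}

#' Retrieve snippets by word pair (byKeywords)
#'
#' Returns every sentence in which both terms occur as content words
#' within the same window constraint used for counting (at most `n - 1`
#' content-word positions apart), so the snippet list is exactly the
#' evidence behind the pair's count in [count_cooccurrences()]. Both
#' terms' participating occurrences are recorded in `matched_terms`; the
#' number of qualifying position pairs is reported in `n_occurrences`.
#'
#' @param ann An `obs_annotations`.
#' @param pair Character vector of the two (lowercased) terms.
#' @param config The [cooccurrence_config()] used for counting.
#' @param mentions Optional mention tibble; when given, name mentions in
#'   each returned sentence are annotated in `matched_names`.
#' @return A snippet tibble as in [snippets_by_taxa()], plus an
#'   `n_occurrences` column, ordered by `(doc_id, sent_index)`.
#' @export
snippets_by_pair <- function(ann, pair, config = cooccurrence_config(),
                             mentions = NULL) {
  stopifnot(inherits(ann, "obs_annotations"), length(pair) == 2)
  term_a <- stringi::stri_trans_tolower(pair[1])
  term_b <- stringi::stri_trans_tolower(pair[2])
  sents <- ann$sentences
  out <- list()
  for (r in seq_len(nrow(sents))) {
    toks <- ann$tokens[
      ann$tokens$doc_id == sents$doc_id[r] &
        ann$tokens$sent_index == sents$sent_index[r], ,
      drop = FALSE
    ]
    ct <- content_stream(toks)
    qp <- qualifying_pairs(ct$norm, term_a, term_b, config$n)
    if (nrow(qp) == 0) next
    involved <- sort(unique(c(qp[, 1], qp[, 2])))
    terms_tbl <- tibble::tibble(
      term = ct$norm[involved],
      start = ct$start[involved], end = ct$end[involved]
    )
    names_tbl <- if (is.null(mentions)) {
      tibble::tibble(
        canonical = character(), verbatim = character(),
        start = integer(), end = integer()
      )
    } else {
      men <- mentions[
        mentions$doc_id == sents$doc_id[r] &
          mentions$sent_index == sents$sent_index[r], ,
        drop = FALSE
      ]
      tibble::tibble(
        canonical = men$canonical, verbatim = men$verbatim,
        start = men$start, end = men$end
      )
    }
    row <- snippet_row(
      sents[r, ], names_tbl, terms_tbl,
      sprintf("byKeywords:%s+%s", term_a, term_b)
    )
    row$n_occurrences <- nrow(qp)
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0) {
    res <- empty_snippets()
    res$n_occurrences <- integer(0)
    return(res)
  }
  res <- dplyr::bind_rows(out)
  res[order(res$doc_id, res$sent_index), , drop = FALSE]
}

join_bar <- function(x) paste(x, collapse = "|")

#' Export snippets as TSV or JSONL
#'
#' TSV columns: `doc_id`, `sent_index`, `start`, `end`, `snippet`,
#' `matched_names`, `matched_terms`, `query` — list fields joined with
#' `"|"`. JSONL: one object per snippet with the same fields
#' (`matched_names` / `matched_terms` as arrays of strings). UTF-8,
#' deterministic row order (the input order).
#'
#' @param snippets Snippet tibble.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
export_snippets <- function(snippets, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  names_chr <- vapply(
    snippets$matched_names,
    function(m) join_bar(unique(m$canonical)), character(1)
  )
  terms_chr <- vapply(
    snippets$matched_terms,
    function(m) join_bar(unique(m$term)), character(1)
  )
  flat <- data.frame(
    doc_id = snippets$doc_id,
    sent_index = snippets$sent_index,
    start = snippets$start,
    end = snippets$end,
    snippet = snippets$text,
    matched_names = names_chr,
    matched_terms = terms_chr,
    query = snippets$query,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "tsv") {
    utils::write.table(flat, con,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = TRUE
    )
  } else {
    for (r in seq_len(nrow(flat))) {
      obj <- list(
        doc_id = flat$doc_id[r],
        sent_index = flat$sent_index[r],
        start = flat$start[r],
        end = flat$end[r],
        snippet = flat$snippet[r],
        matched_names = unique(snippets$matched_names[[r]]$canonical),
        matched_terms = unique(snippets$matched_terms[[r]]$term),
        query = flat$query[r]
      )
      writeLines(
        jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"),
        con
      )
    }
    if (nrow(flat) == 0) invisible(NULL) # empty file for zero snippets
  }
  invisible(path)
}
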