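# Local rule-based scientific-name recognition.
#
# Mimics the input/output behavior of name-finding services (recognize
# Latin names in free text, tolerate false positives over false
# negatives) without a network dependency. Three shapes are recognized:
#   binomial               "Alouatta seniculus"
#   abbreviated binomial   "M. huberi" (genus initial + period + epithet)
#   uninomial              a capitalized word with a rank suffix
#                          (-idae, -aceae, -ales, -inae)
# Latin scholarly phrases, months and journal-title vocabulary are
# blacklisted because they mimic the binomial shape; sentence-initial
# candidates additionally need a Latinate epithet ending to suppress
# "The monkeys"-type bigrams.

LATIN_ENDINGS <- c(
  "us", "a", "um", "is", "ii", "i", "ensis", "oides", "ata", "atus",
  "ella", "ianus", "iana", "icus", "ica", "alis", "aris", "osa", "osus"
)

RANK_SUFFIX_RE <- "(idae|aceae|ales|inae)$"

has_latin_ending <- function(epithet) {
  stringi::stri_detect_regex(
    epithet,
    paste0("(", paste(LATIN_ENDINGS, collapse = "|"), ")$")
  )
}

empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(), sent_index = integer(),
    start = integer(), end = integer(),
    verbatim = character(), canonical = character(),
    rank_guess = character(), resolved = logical()
  )
}

title_case <- function(x) {
  paste0(
    stringi::stri_trans_toupper(stringi::stri_sub(x, 1, 1)),
    stringi::stri_trans_tolower(stringi::stri_sub(x, 2))
  )
}

#' Find scientific names in one sentence
#'
#' Applies the rule-based recognizer to a sentence. Candidates:
#'
#' * **binomial** — a capitalized Latin-compatible word of length >= 3
#'   followed by a lowercase word of length >= 3, neither word
#'   blacklisted; when the candidate opens the sentence, the epithet must
#'   carry a Latinate ending (-us, -a, -um, -is, -ensis, ...) so that
#'   ordinary "Capitalized English + noun" openings are not matched.
#' * **abbreviated binomial** — single capital + period + lowercase word
#'   of length >= 3 (e.g. `"M. huberi"`), epithet not blacklisted.
#' * **uninomial** — capitalized word with a rank suffix
#'   (-idae, -aceae, -ales, -inae).
#'
#' Overlapping candidates are resolved longest-first. The recognizer is
#' deliberately biased toward false positives rather than false
#' negatives, matching the behavior of name-recognition services on
#' literature text; vernacular names are not recognized.
#'
#' @param sentence_text Sentence string.
#' @param doc_id,sent_index Provenance recorded on each mention.
#' @param offset Offset of the sentence in the document text (1-based).
#' @param blacklist Lowercased words barred from genus/epithet position;
#'   defaults to the bundled list ([obsmine_blacklist()]).
#' @return A mention tibble: `doc_id`, `sent_index`, `start`, `end`,
#'   `verbatim`, `canonical`, `rank_guess` (`"binomial"`,
#'   `"abbreviated_binomial"` or `"uninomial"`) and `resolved` (abbreviated
#'   mentions start unresolved; see [resolve_abbreviations()]).
#' @export
#' @examples
#' find_scientific_names("Alouatta seniculus and Ateles paniscus eat fruits.")
#' find_scientific_names("In situ observations at the site")
find_scientific_names <- function(sentence_text, doc_id = NA_character_,
                                  sent_index = NA_integer_, offset = 1L,
                                  blacklist = obsmine_blacklist()) {
  stopifnot(length(sentence_text) == 1)
  if (is.na(sentence_text) || !nzchar(sentence_text)) return(empty_mentions())
  cands <- list()
  push <- function(start, end, verbatim, canonical, rank_guess, resolved) {
    cands[[length(cands) + 1L]] <<- tibble::tibble(
      doc_id = doc_id, sent_index = sent_index,
      start = as.integer(start), end = as.integer(end),
      verbatim = verbatim, canonical = canonical,
      rank_guess = rank_guess, resolved = resolved
    )
  }
  first_word_at <- stringi::stri_locate_first_regex(sentence_text, "\\p{Lu}")[1, 1]

  # (a) full binomials
  loc <- stringi::stri_locate_all_regex(
    sentence_text,
    "(?<![\\p{L}\\p{N}.-])\\p{Lu}[\\p{L}-]{2,}[ ]\\p{Ll}[\\p{Ll}-]{2,}(?![\\p{L}\\p{N}])"
  )[[1]]
  if (!is.na(loc[1, 1])) {
    for (r in seq_len(nrow(loc))) {
      verb <- stringi::stri_sub(sentence_text, loc[r, 1], loc[r, 2])
      parts <- stringi::stri_split_fixed(verb, " ")[[1]]
      genus <- parts[1]
      epithet <- parts[2]
      # a rank-suffixed first word is a uninomial, not a genus ("Rosaceae
      # flowers" must not parse as a binomial)
      if (stringi::stri_detect_regex(genus, RANK_SUFFIX_RE)) next
      if (stringi::stri_trans_tolower(genus) %in% blacklist) next
      if (epithet %in% blacklist) next
      sent_initial <- !is.na(first_word_at) && loc[r, 1] == first_word_at &&
        loc[r, 1] <= 2
      if (sent_initial && !has_latin_ending(epithet)) next
      push(
        loc[r, 1] + offset - 1L, loc[r, 2] + offset - 1L, verb,
        paste(title_case(genus), stringi::stri_trans_tolower(epithet)),
        "binomial", TRUE
      )
    }
  }

  # (b) abbreviated binomials: "M. huberi"
  loc <- stringi::stri_locate_all_regex(
    sentence_text,
    "(?<![\\p{L}\\p{N}.])\\p{Lu}\\.[ ]?\\p{Ll}[\\p{Ll}-]{2,}(?![\\p{L}\\p{N}])"
  )[[1]]
  if (!is.na(loc[1, 1])) {
    for (r in seq_len(nrow(loc))) {
      verb <- stringi::stri_sub(sentence_text, loc[r, 1], loc[r, 2])
      m <- stringi::stri_match_first_regex(verb, "^(\\p{Lu})\\.[ ]?(.+)$")
      epithet <- m[1, 3]
      if (epithet %in% blacklist) next
      push(
        loc[r, 1] + offset - 1L, loc[r, 2] + offset - 1L, verb,
        paste0(m[1, 2], ". ", epithet),
        "abbreviated_binomial", FALSE
      )
    }
  }

  # (c) uninomials with a rank suffix
  loc <- stringi::stri_locate_all_regex(
    sentence_text,
    "(?<![\\p{L}\\p{N}.-])\\p{Lu}\\p{Ll}{2,}(?:idae|aceae|ales|inae)(?![\\p{L}\\p{N}])"
  )[[1]]
  if (!is.na(loc[1, 1])) {
    for (r in seq_len(nrow(loc))) {
      verb <- stringi::stri_sub(sentence_text, loc[r, 1], loc[r, 2])
      if (stringi::stri_trans_tolower(verb) %in% blacklist) next
      push(
        loc[r, 1] + offset - 1L, loc[r, 2] + offset - 1L, verb,
        title_case(verb), "uninomial", TRUE
      )
    }
  }

  if (length(cands) == 0) return(empty_mentions())
  out <- dplyr::bind_rows(cands)
  # longest-first resolution of overlaps, then document order
  out <- out[order(out$start, -(out$end - out$start)), , drop = FALSE]
  keep <- logical(nrow(out))
  for (r in order(-(out$end - out$start), out$start)) {
    kept <- which(keep)
    overlaps <- any(
      out$start[r] <= out$end[kept] & out$end[r] >= out$start[kept]
    )
    if (!overlaps) keep[r] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Resolve abbreviated genus names against earlier full mentions
#'
#' Within one document, an abbreviated binomial (`"F. vesca"`) whose
#' initial matches the genus initial of the nearest *preceding* full
#' binomial or uninomial acquires that genus: canonical becomes
#' `"Fragaria vesca"` and `resolved` becomes `TRUE`. Abbreviations with no
#' same-initial antecedent keep their abbreviated canonical form and stay
#' unresolved. Full binomial mentions are never modified.
#'
#' @param mentions Mention tibble for one document, any order (sorted
#'   internally by `sent_index`, `start`).
#' @return The mention tibble, ordered by position, with abbreviated
#'   mentions resolved where possible.
#' @export
resolve_abbreviations <- function(mentions) {
  if (nrow(mentions) == 0) return(mentions)
  stopifnot(length(unique(mentions$doc_id)) <= 1)
  mentions <- mentions[order(mentions$sent_index, mentions$start), , drop = FALSE]
  last_genus <- character(0) # initial -> most recent genus
  for (r in seq_len(nrow(mentions))) {
    rg <- mentions$rank_guess[r]
    if (rg %in% c("binomial", "uninomial")) {
      genus <- stringi::stri_split_fixed(mentions$canonical[r], " ")[[1]][1]
      last_genus[stringi::stri_sub(genus, 1, 1)] <- genus
    } else if (rg == "abbreviated_binomial") {
      m <- stringi::stri_match_first_regex(
        mentions$canonical[r], "^(\\p{Lu})\\. (.+)$"
      )
      if (!is.na(m[1, 1]) && m[1, 2] %in% names(last_genus)) {
        mentions$canonical[r] <- paste(last_genus[[m[1, 2]]], m[1, 3])
        mentions$resolved[r] <- TRUE
      }
    }
  }
  mentions
}

#' Find and resolve scientific names across an annotated corpus
#'
#' Runs [find_scientific_names()] on every sentence and
#' [resolve_abbreviations()] within every document. A custom recognizer
#' honouring the same mention contract may be plugged in.
#'
#' @param ann An `obs_annotations` from [annotate_corpus()].
#' @param blacklist Recognizer blacklist, see [find_scientific_names()].
#' @param recognizer Optional plug-in replacing the built-in recognizer: a
#'   function with the signature of [find_scientific_names()] returning
#'   the same mention tibble.
#' @return A mention tibble over the whole corpus, ordered by document,
#'   sentence and position.
#' @export
find_names <- function(ann, blacklist = obsmine_blacklist(), recognizer = NULL) {
  stopifnot(inherits(ann, "obs_annotations"))
  rec <- if (is.null(recognizer)) find_scientific_names else recognizer
  sents <- ann$sentences
  per_sent <- lapply(seq_len(nrow(sents)), function(i) {
    rec(
      sents$text[i],
      doc_id = sents$doc_id[i], sent_index = sents$sent_index[i],
      offset = sents$start[i], blacklist = blacklist
    )
  })
  mentions <- dplyr::bind_rows(c(list(empty_mentions()), per_sent))
  if (nrow(mentions) == 0) return(mentions)
  resolved <- lapply(
    split(mentions, mentions$doc_id),
    resolve_abbreviations
  )
  out <- dplyr::bind_rows(resolved)
  out[order(match(out$doc_id, ann$sentences$doc_id), out$sent_index, out$start), ,
    drop = FALSE
  ]
}

#' Build a taxon index over recognized names
#'
#' Maps every canonical name to the sentences mentioning it, one entry per
#' (name, document, sentence) triple. Names are ordered by total snippet
#' count (descending), ties alphabetically — the presentation order for
#' browsing a corpus by taxon.
#'
#' @param mentions Corpus-wide mention tibble from [find_names()].
#' @return An `obs_taxon_index`: list with `names`, a tibble of
#'   `canonical`, `rank_guess`, `n_snippets` and a `sites` list-column of
#'   `(doc_id, sent_index)` tibbles; plus `family`/`class` columns after
#'   [attach_higher_ranks()].
#' @export
build_taxon_index <- function(mentions) {
  if (nrow(mentions) == 0) {
    return(structure(
      list(names = tibble::tibble(
        canonical = character(), rank_guess = character(),
        n_snippets = integer(), sites = list()
      )),
      class = "obs_taxon_index"
    ))
  }
  uni <- dplyr::distinct(mentions[, c("canonical", "doc_id", "sent_index")])
  sites <- split(
    tibble::as_tibble(uni[, c("doc_id", "sent_index")]),
    uni$canonical
  )
  tab <- tibble::tibble(
    canonical = names(sites),
    rank_guess = mentions$rank_guess[match(names(sites), mentions$canonical)],
    sites = unname(sites)
  )
  tab$n_snippets <- vapply(tab$sites, nrow, integer(1))
  tab <- tab[order(-tab$n_snippets, tab$canonical), , drop = FALSE]
  tab <- tab[, c("canonical", "rank_guess", "n_snippets", "sites")]
  structure(list(names = tab), class = "obs_taxon_index")
}

#' @export
print.obs_taxon_index <- function(x, ...) {
  cat(sprintf(
    "<obs_taxon_index> %d name%s\n",
    nrow(x$names), if (nrow(x$names) == 1) "" else "s"
  ))
  print(utils::head(x$names[, setdiff(names(x$names), "sites")], 10))
  invisible(x)
}

#' Annotate indexed genera with family and class from a taxonomy table
#'
#' Attaches higher taxonomic ranks from a local CSV table with header
#' `genus,family,class`. Genera absent from the table simply remain
#' unannotated.
#'
#' @param index An `obs_taxon_index`.
#' @param table_path Path to the taxonomy CSV.
#' @return The index with `family` and `class` columns on `names`.
#' @export
attach_higher_ranks <- function(index, table_path) {
  stopifnot(inherits(index, "obs_taxon_index"))
  lines <- readLines(table_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(stringi::stri_trim_both(lines))]
  if (length(lines) == 0) stop("taxonomy table is empty: ", table_path, call. = FALSE)
  fields <- stringi::stri_split_fixed(lines, ",")
  header <- stringi::stri_trim_both(stringi::stri_trans_tolower(fields[[1]]))
  if (!identical(header, c("genus", "family", "class"))) {
    stop(
      "taxonomy table line 1: header must be 'genus,family,class', got '",
      lines[1], "'",
      call. = FALSE
    )
  }
  bad <- which(lengths(fields) != 3)
  bad <- setdiff(bad, 1L)
  if (length(bad) > 0) {
    stop(
      "taxonomy table line ", bad[1], " is malformed (expected 3 fields): '",
      lines[bad[1]], "'",
      call. = FALSE
    )
  }
  if (length(fields) == 1) { # header only
    index$names$family <- NA_character_
    index$names$class <- NA_character_
    return(index)
  }
  tab <- do.call(rbind, fields[-1])
  genus_of <- vapply(
    stringi::stri_split_fixed(index$names$canonical, " "),
    `[[`, character(1), 1
  )
  hit <- match(genus_of, stringi::stri_trim_both(tab[, 1]))
  index$names$family <- ifelse(is.na(hit), NA_character_,
    stringi::stri_trim_both(tab[hit, 2])
  )
  index$names$class <- ifelse(is.na(hit), NA_character_,
    stringi::stri_trim_both(tab[hit, 3])
  )
  index
}
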