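# Seeded synthetic-corpus generator with ground-truth manifest.
#
# Documents are assembled from templated interaction sentences using an
# invented (but morphologically valid) Latin lexicon — never real claims
# about real species — padded with stop-word-rich filler. The manifest
# records every planted name, the expected abbreviation resolutions, the
# per-sentence content-word streams (computed by the generator's own
# simple filter) and the expected co-occurrence table for a given window,
# computed by a brute-force all-pairs oracle rather than by the windowed
# implementation the fixtures exist to check.

# invented genera, all distinct initials, morphologically Latinate
FIXTURE_GENERA <- c(
  "Arbofructus", "Baccivora", "Cortexia", "Dulcifera", "Erythrosema",
  "Fructilia", "Glabridens", "Hesperocarpa", "Insulivora", "Jubatophila",
  "Kalotheca", "Lianomorpha", "Maturifolia", "Nectorhyncha", "Ochrosperma",
  "Pomilexa", "Quercimima", "Ramulistra", "Silvamora", "Truncosema",
  "Umbraticola", "Velutifolia", "Xanthocalyx", "Zonotricta"
)

# epithets all carry Latinate endings so sentence-initial plants pass the
# recognizer's first-word guard
FIXTURE_EPITHETS <- c(
  "sylvatica", "grandiflorus", "parvifolia", "montanus", "rubricata",
  "aurantiacus", "velutina", "cordata", "insularis", "maculatus",
  "fenestrata", "umbrosa", "nitidulus", "pallida", "spinosus",
  "littoralis", "riparia", "collinus", "saxicola", "arenosa"
)

FIXTURE_FILLERS <- c(
  "It was however not at all clear that they would all be there again.",
  "However these were only a few of the many that could have been seen.",
  "There would have been more of them if it had not rained so much.",
  "All of this was done so that it could be repeated again and again.",
  "Most of what was there had already been described once before."
)

NEGATIVE_SENTENCES <- c(
  "In situ observations were recorded throughout the study period.",
  "The protocols were designed a priori and amended ad hoc in the field.",
  "Sampling began in January and was repeated de novo in March.",
  "These findings appeared in the Proceedings of the Royal Society.",
  "The results were printed in Biological Conservation and discussed per se.",
  "In vitro and in vivo assays were impossible in situ during May.",
  "Voucher material was archived sensu lato at the National Museum."
)

# the generator's own tokenizer/content filter: deliberately simple and
# separate from the annotate module, so fixtures state their expectations
# independently
fixture_content_stream <- function(sentence, stopwords = obsmine_stopwords()) {
  words <- stringi::stri_split_regex(
    stringi::stri_trans_tolower(sentence), "[^a-z0-9'-]+"
  )[[1]]
  words <- gsub("^[-']+|[-']+$", "", words)
  words <- words[nzchar(words)]
  words[!(words %in% stopwords) &
    stringi::stri_length(words) >= 2 &
    !grepl("^[0-9]+$", words)]
}

# brute-force all-pairs-within-distance oracle over content streams; the
# reference the windowed skip-n-gram implementation is tested against
fixture_oracle_pairs <- function(streams, n) {
  counts <- new.env(parent = emptyenv())
  for (s in streams) {
    L <- length(s)
    if (L < 2) next
    for (i in seq_len(L - 1)) {
      for (j in seq(i + 1, min(L, i + n - 1))) {
        key <- paste(min(s[i], s[j]), max(s[i], s[j]), sep = "\u001F")
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    return(tibble::tibble(
      term_a = character(), term_b = character(), count = integer()
    ))
  }
  parts <- stringi::stri_split_fixed(keys, "\u001F")
  out <- tibble::tibble(
    term_a = vapply(parts, `[[`, character(1), 1),
    term_b = vapply(parts, `[[`, character(1), 2),
    count = vapply(keys, function(k) counts[[k]], integer(1))
  )
  out[order(-out$count, out$term_a, out$term_b), , drop = FALSE]
}

# inject PDF-extraction artifacts: wrap to short lines, hyphenate a word
# across a line break, swap "fi" for the typographic ligature
inject_artifacts <- function(text) {
  text <- stringi::stri_replace_first_fixed(text, "fi", "\uFB01")
  words <- stringi::stri_split_fixed(text, " ")[[1]]
  lines <- character(0)
  cur <- ""
  for (w in words) {
    candidate <- if (nzchar(cur)) paste(cur, w) else w
    if (stringi::stri_length(candidate) > 58 && nzchar(cur)) {
      lines <- c(lines, cur)
      cur <- w
    } else {
      cur <- candidate
    }
  }
  if (nzchar(cur)) lines <- c(lines, cur)
  # hyphenate the first line that ends in a long lowercase word
  for (k in seq_along(lines)) {
    m <- stringi::stri_match_last_regex(lines[k], "(\\p{Ll}{8,})$")
    if (!is.na(m[1, 2]) && k <= length(lines)) {
      word <- m[1, 2]
      cut <- 4L
      head_part <- stringi::stri_sub(word, 1, cut)
      tail_part <- stringi::stri_sub(word, cut + 1)
      lines[k] <- stringi::stri_replace_last_fixed(
        lines[k], word, paste0(head_part, "-")
      )
      lines <- append(lines, tail_part, after = k)
      break
    }
  }
  paste(lines, collapse = "\n")
}

#' Generate a seeded synthetic literature corpus with ground truth
#'
#' Writes a small corpus of documents assembled from templated
#' plant-animal interaction sentences (frugivory and pollination) with
#' planted scientific names drawn from an invented Latin lexicon, padded
#' with stop-word-rich filler, and returns a manifest stating exactly what
#' was planted — so recognition recall, abbreviation resolution,
#' co-occurrence counts and snippet retrieval can all be checked against
#' ground truth without any downloads.
#'
#' Documents are built in 3-sentence blocks: an interaction sentence
#' planting two full binomials, a filler sentence, and (when
#' `plant_abbreviations` is on) a follow-up sentence re-mentioning the
#' first binomial as an abbreviated genus (`"A. sylvatica"` style). All
#' genera within a document have distinct initials, so each abbreviation's
#' expected resolution is its block's full binomial.
#'
#' @param dir Output directory (created if needed).
#' @param n_docs Number of documents (>= 1).
#' @param sentences_per_doc Sentences per document; rounded up to a
#'   multiple of 3 (the block size).
#' @param seed Integer seed; the same seed reproduces byte-identical files
#'   and manifest.
#' @param pdf Also write each document as a machine-readable PDF with
#'   injected line-wrap, line-break hyphenation and a typographic
#'   ligature — the artifacts [normalize_text()] must repair.
#' @param plant_abbreviations Plant abbreviated re-mentions (see above).
#' @param negative_control Emit prose containing blacklisted Latin
#'   phrases, months and journal-title vocabulary and zero planted names
#'   instead of interaction sentences.
#' @param include_unreadable Additionally write one image-only (no text
#'   layer) PDF stub, expected to trigger exactly one corpus notification.
#' @param n Window size for the manifest's expected co-occurrence table.
#' @return A `fixture_manifest`: list with `seed`, `n`, `paths` (text
#'   files), `pdf_paths`, `unreadable_path`, `documents` (per document:
#'   `doc_id`, `sentences`, `planted` mention tibble with
#'   `expected_canonical`, `content_streams`) and `expected` (tibbles
#'   `name_counts` and `pairs`, the latter from the brute-force oracle).
#'   The manifest is also written as `manifest.json` in `dir`.
#' @export
generate_fixture_corpus <- function(dir, n_docs = 3, sentences_per_doc = 9,
                                    seed = 1, pdf = FALSE,
                                    plant_abbreviations = TRUE,
                                    negative_control = FALSE,
                                    include_unreadable = FALSE,
                                    n = 6) {
  stopifnot(n_docs >= 1, sentences_per_doc >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(as.integer(seed), {
    documents <- list()
    paths <- character(0)
    pdf_paths <- character(0)
    for (d in seq_len(n_docs)) {
      doc_id <- sprintf("doc%02d", d)
      if (negative_control) {
        idx <- ((seq_len(sentences_per_doc) - 1) %% length(NEGATIVE_SENTENCES)) + 1
        sentences <- NEGATIVE_SENTENCES[idx]
        planted <- tibble::tibble(
          sent_index = integer(), verbatim = character(),
          rank_guess = character(), expected_canonical = character()
        )
      } else {
        n_blocks <- ceiling(sentences_per_doc / 3)
        # genera with distinct initials within the document
        shuffled <- sample(FIXTURE_GENERA)
        initials <- stringi::stri_sub(shuffled, 1, 1)
        genera <- shuffled[!duplicated(initials)]
        if (2 * n_blocks > length(genera)) {
          stop(
            "too many blocks for the fixture genus lexicon (",
            n_blocks, " blocks need ", 2 * n_blocks, " distinct initials)",
            call. = FALSE
          )
        }
        genera <- genera[seq_len(2 * n_blocks)]
        epithets <- sample(FIXTURE_EPITHETS, 2 * n_blocks, replace = TRUE)
        sentences <- character(0)
        planted_rows <- list()
        for (b in seq_len(n_blocks)) {
          ga <- genera[2 * b - 1]
          gb <- genera[2 * b]
          ea <- epithets[2 * b - 1]
          eb <- epithets[2 * b]
          name_a <- paste(ga, ea)
          name_b <- paste(gb, eb)
          if (b %% 2 == 1) {
            inter <- sprintf(
              "Individuals of %s consumed ripe fruits of %s and later dispersed the seeds.",
              name_a, name_b
            )
          } else {
            inter <- sprintf(
              "%s visited the flowers of %s and carried pollen between them.",
              name_a, name_b
            )
          }
          s_inter <- length(sentences) + 1L
          sentences <- c(sentences, inter)
          planted_rows[[length(planted_rows) + 1L]] <- tibble::tibble(
            sent_index = s_inter,
            verbatim = c(name_a, name_b),
            rank_guess = "binomial",
            expected_canonical = c(name_a, name_b)
          )
          sentences <- c(
            sentences,
            FIXTURE_FILLERS[((b - 1) %% length(FIXTURE_FILLERS)) + 1]
          )
          if (plant_abbreviations) {
            abbr <- sprintf("%s. %s", stringi::stri_sub(ga, 1, 1), ea)
            s_abbr <- length(sentences) + 1L
            sentences <- c(sentences, sprintf(
              "Fruits of %s were swallowed whole and the pulp was eaten quickly.",
              abbr
            ))
            planted_rows[[length(planted_rows) + 1L]] <- tibble::tibble(
              sent_index = s_abbr,
              verbatim = abbr,
              rank_guess = "abbreviated_binomial",
              expected_canonical = name_a
            )
          } else {
            sentences <- c(
              sentences,
              FIXTURE_FILLERS[(b %% length(FIXTURE_FILLERS)) + 1]
            )
          }
        }
        planted <- dplyr::bind_rows(planted_rows)
      }
      text <- paste(sentences, collapse = " ")
      path <- file.path(dir, paste0(doc_id, ".txt"))
      writeLines(text, path, useBytes = TRUE)
      paths <- c(paths, path)
      if (pdf) {
        pdf_path <- file.path(dir, paste0(doc_id, ".pdf"))
        write_fixture_pdf(inject_artifacts(text), pdf_path)
        pdf_paths <- c(pdf_paths, pdf_path)
      }
      documents[[doc_id]] <- list(
        doc_id = doc_id,
        sentences = sentences,
        planted = planted,
        content_streams = lapply(sentences, fixture_content_stream)
      )
    }
    unreadable_path <- NA_character_
    if (include_unreadable) {
      unreadable_path <- file.path(dir, "scanned_legacy.pdf")
      write_fixture_pdf("ignored", unreadable_path, text_layer = FALSE)
    }
    all_streams <- unlist(
      lapply(documents, `[[`, "content_streams"),
      recursive = FALSE
    )
    name_counts <- {
      rows <- lapply(documents, function(doc) {
        if (nrow(doc$planted) == 0) {
          return(NULL)
        }
        tibble::tibble(
          doc_id = doc$doc_id,
          sent_index = doc$planted$sent_index,
          canonical = doc$planted$expected_canonical
        )
      })
      all <- dplyr::bind_rows(rows)
      if (nrow(all) == 0) {
        tibble::tibble(canonical = character(), n_snippets = integer())
      } else {
        uni <- dplyr::distinct(all)
        cnt <- dplyr::count(uni, .data$canonical, name = "n_snippets")
        cnt[order(-cnt$n_snippets, cnt$canonical), , drop = FALSE]
      }
    }
    manifest <- structure(
      list(
        seed = as.integer(seed),
        n = as.integer(n),
        paths = paths,
        pdf_paths = pdf_paths,
        unreadable_path = unreadable_path,
        documents = documents,
        expected = list(
          name_counts = name_counts,
          pairs = fixture_oracle_pairs(all_streams, n)
        )
      ),
      class = "fixture_manifest"
    )
    jsonlite::write_json(
      manifest_as_json(manifest),
      file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
    manifest
  })
}

# plain-list view of a manifest for JSON serialization
manifest_as_json <- function(m) {
  list(
    seed = m$seed,
    n = m$n,
    paths = m$paths,
    pdf_paths = m$pdf_paths,
    unreadable_path = m$unreadable_path,
    documents = lapply(m$documents, function(doc) {
      list(
        doc_id = doc$doc_id,
        sentences = doc$sentences,
        planted = as.data.frame(doc$planted),
        content_streams = doc$content_streams
      )
    }),
    expected = list(
      name_counts = as.data.frame(m$expected$name_counts),
      pairs = as.data.frame(m$expected$pairs)
    )
  )
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf(
    "<fixture_manifest> seed %d: %d document%s, %d planted mention%s, %d expected pair%s (n = %d)\n",
    x$seed, length(x$documents),
    if (length(x$documents) == 1) "" else "s",
    sum(vapply(x$documents, function(d) nrow(d$planted), integer(1))),
    if (sum(vapply(x$documents, function(d) nrow(d$planted), integer(1))) == 1) "" else "s",
    nrow(x$expected$pairs),
    if (nrow(x$expected$pairs) == 1) "" else "s",
    x$n
  ))
  invisible(x)
}
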