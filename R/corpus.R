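# Corpus loading: one Document per input file, unreadable files flagged
# (never dropped) with one human-readable notification each.

#' Extract raw text from a corpus file
#'
#' Plain-text files are decoded as UTF-8 with replacement-character
#' fallback (corpora are heterogeneous; decoding is fail-soft). PDF files
#' go through the embedded-text-layer extractor ([read_pdf_text()]), pages
#' concatenated with paragraph separators. A file counts as
#' machine-readable when its extracted text has at least `min_word_chars`
#' word characters (letters or digits); image-only, encrypted, corrupt or
#' near-empty files fall below the threshold and are flagged instead of
#' raising an error.
#'
#' @param path Path to a `.txt` or `.pdf` file (anything that is not a PDF
#'   is treated as plain text).
#' @param min_word_chars Minimum number of word characters for a file to
#'   count as machine-readable (default 20).
#' @param ocr_hook Optional function `path -> text` tried when a PDF has no
#'   extractable text layer (an OCR engine binding, for example). Its
#'   output is subject to the same readability threshold.
#' @return A list with `raw_text` (string), `readable` (flag) and `reason`
#'   (`NA` or a short explanation for unreadable files).
#' @export
extract_text <- function(path, min_word_chars = 20, ocr_hook = NULL) {
  stopifnot(length(path) == 1)
  if (!file.exists(path)) {
    return(list(raw_text = "", readable = FALSE, reason = "file not found"))
  }
  is_pdf <- tolower(tools::file_ext(path)) == "pdf"
  raw_text <- ""
  reason <- NA_character_
  if (is_pdf) {
    raw_text <- tryCatch(read_pdf_text(path), error = function(e) {
      reason <<- conditionMessage(e)
      ""
    })
    if (n_word_chars(raw_text) < min_word_chars && is.function(ocr_hook)) {
      raw_text <- tryCatch(as.character(ocr_hook(path))[1],
        error = function(e) raw_text
      )
    }
  } else {
    size <- file.size(path)
    bytes <- if (size > 0) readBin(path, "raw", size) else raw(0)
    raw_text <- decode_utf8_lossy(bytes)
  }
  readable <- n_word_chars(raw_text) >= min_word_chars
  if (!readable && is.na(reason)) {
    reason <- if (is_pdf) {
      "no machine-readable text layer (image-only or compressed PDF?)"
    } else {
      "too little text"
    }
  }
  list(
    raw_text = raw_text,
    readable = readable,
    reason = if (readable) NA_character_ else reason
  )
}

n_word_chars <- function(x) {
  if (!length(x) || is.na(x)) return(0L)
  stringi::stri_count_regex(x, "[\\p{L}\\p{N}]")
}

# filename stem as doc_id, numeric suffix on collision
make_doc_ids <- function(paths) {
  stems <- tools::file_path_sans_ext(basename(paths))
  ids <- stems
  for (i in seq_along(ids)) {
    if (sum(stems[seq_len(i)] == stems[i]) > 1) {
      ids[i] <- paste0(stems[i], "_", sum(stems[seq_len(i)] == stems[i]))
    }
  }
  ids
}

#' Load a literature corpus
#'
#' Reads every file in `paths` into one document, preserving order and
#' never silently dropping a file: files whose text cannot be extracted
#' (scanned image-only PDFs, encrypted or corrupt files, missing paths)
#' are kept with `readable = FALSE`, an empty normalized text, and exactly
#' one entry in the corpus `notifications` — mirroring the notification a
#' user needs before deciding to OCR those files. Extracted text is passed
#' through [normalize_text()].
#'
#' @param paths Character vector of `.txt` / `.pdf` file paths.
#' @inheritParams extract_text
#' @return An `obs_corpus`: a list with
#'   * `documents` — tibble with columns `doc_id`, `source_path`,
#'     `readable`, `note`, `text` (normalized; `""` when unreadable) and
#'     `raw_text`;
#'   * `notifications` — character vector, one warning per unreadable file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("Alouatta seniculus swallows fruits and disperses seeds.", f)
#' corp <- load_corpus(f)
#' corp$documents$text
load_corpus <- function(paths, min_word_chars = 20, ocr_hook = NULL) {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  extracted <- lapply(paths, extract_text,
    min_word_chars = min_word_chars, ocr_hook = ocr_hook
  )
  readable <- vapply(extracted, `[[`, logical(1), "readable")
  if (!any(readable)) {
    stop("empty corpus: none of the ", length(paths),
      " input file(s) contained machine-readable text",
      call. = FALSE
    )
  }
  docs <- tibble::tibble(
    doc_id = make_doc_ids(paths),
    source_path = as.character(paths),
    readable = readable,
    note = vapply(extracted, `[[`, character(1), "reason"),
    raw_text = vapply(extracted, `[[`, character(1), "raw_text"),
    text = ifelse(readable, normalize_text(vapply(extracted, `[[`, character(1), "raw_text")), "")
  )
  notifications <- sprintf(
    "'%s' is not machine-readable (%s); it was excluded from mining.",
    basename(docs$source_path[!docs$readable]), docs$note[!docs$readable]
  )
  structure(
    list(documents = docs, notifications = notifications),
    class = "obs_corpus"
  )
}

#' @export
print.obs_corpus <- function(x, ...) {
  n <- nrow(x$documents)
  cat(sprintf(
    "<obs_corpus> %d document%s (%d machine-readable)\n",
    n, if (n == 1) "" else "s", sum(x$documents$readable)
  ))
  for (m in x$notifications) cat(" ! ", m, "\n", sep = "")
  invisible(x)
}

readable_docs <- function(corpus) {
  stopifnot(inherits(corpus, "obs_corpus"))
  corpus$documents[corpus$documents$readable, , drop = FALSE]
}
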