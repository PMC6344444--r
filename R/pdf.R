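# Minimal PDF support: a matched writer/reader pair for machine-readable
# (text-layer) PDFs.
#
# The writer emits uncompressed PDF 1.4 with one content stream per page,
# text shown line-by-line with the ' (move-to-next-line-and-show) operator.
# Non-ASCII text is stored as escaped UTF-8 bytes, so extraction (not
# on-screen rendering fidelity) is the contract — exactly what the fixture
# generator needs to plant ligatures and line-break hyphenation.
#
# The reader extracts the embedded text layer from uncompressed PDFs: it
# walks content streams in file order, collects BT..ET text blocks, and
# interprets the Tj / ' / " / TJ show operators plus Td/TD/T* line moves.
# Compressed (/Filter) or encrypted streams carry no extractable text for
# this reader; such files surface as readable = FALSE upstream, where an
# OCR hook can take over.

pdf_escape_string <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  out <- vapply(bytes, function(b) {
    if (b %in% c(0x28L, 0x29L, 0x5CL)) paste0("\\", rawToChar(as.raw(b)))
    else if (b < 0x20L || b > 0x7EL) sprintf("\\%03o", b)
    else rawToChar(as.raw(b))
  }, character(1))
  paste0(out, collapse = "")
}

#' Write a minimal machine-readable PDF
#'
#' Writes `pages` (one string per page, lines separated by `"\n"`) into an
#' uncompressed single-font PDF whose text layer round-trips exactly
#' through [extract_text()]. Intended for fixture generation and tests;
#' layout is a plain line-by-line rendering, not typeset output.
#'
#' @param pages Character vector, one element per page.
#' @param path Output file path.
#' @param text_layer If `FALSE`, pages carry only vector graphics and no
#'   text operators, emulating a scanned image-only PDF (used to exercise
#'   the unreadable-file notification).
#' @return `path`, invisibly.
#' @export
#' @examples
#' pdf <- tempfile(fileext = ".pdf")
#' write_fixture_pdf("Alouatta seniculus swallows fruits.", pdf)
#' read_pdf_text(pdf)
write_fixture_pdf <- function(pages, path, text_layer = TRUE) {
  stopifnot(is.character(pages), length(pages) >= 1)
  n_pages <- length(pages)
  # object numbering: 1 catalog, 2 pages, 3 font, then (page, stream) pairs
  objs <- character(3 + 2 * n_pages)
  page_obj_ids <- 4 + 2 * (seq_len(n_pages) - 1)
  objs[1] <- "<< /Type /Catalog /Pages 2 0 R >>"
  objs[2] <- sprintf(
    "<< /Type /Pages /Kids [%s] /Count %d >>",
    paste(sprintf("%d 0 R", page_obj_ids), collapse = " "), n_pages
  )
  objs[3] <- "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>"
  for (i in seq_len(n_pages)) {
    if (text_layer) {
      lines <- stringi::stri_split_fixed(pages[[i]], "\n")[[1]]
      shown <- paste(
        sprintf("(%s) '", vapply(lines, pdf_escape_string, character(1))),
        collapse = "\n"
      )
      stream <- paste0("BT /F1 11 Tf 14 TL 72 756 Td\n", shown, "\nET")
    } else {
      stream <- "0.8 g 100 400 400 300 re f"
    }
    objs[page_obj_ids[i]] <- paste0(
      "<< /Type /Page /Parent 2 0 R /MediaBox [0 0 612 792] ",
      sprintf("/Resources << /Font << /F1 3 0 R >> >> /Contents %d 0 R >>",
              page_obj_ids[i] + 1)
    )
    objs[page_obj_ids[i] + 1] <- sprintf(
      "<< /Length %d >>\nstream\n%s\nendstream",
      nchar(stream, type = "bytes"), stream
    )
  }
  body <- "%PDF-1.4\n"
  offsets <- integer(length(objs))
  for (i in seq_along(objs)) {
    offsets[i] <- nchar(body, type = "bytes")
    body <- paste0(body, sprintf("%d 0 obj\n%s\nendobj\n", i, objs[i]))
  }
  xref_at <- nchar(body, type = "bytes")
  xref <- paste0(
    "xref\n0 ", length(objs) + 1, "\n",
    "0000000000 65535 f \n",
    paste(sprintf("%010d 00000 n ", offsets), collapse = "\n"), "\n"
  )
  trailer <- sprintf(
    "trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
    length(objs) + 1, xref_at
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(body, xref, trailer)), con)
  invisible(path)
}

# Decode a raw vector (or bytes-in-latin1 string) as UTF-8, replacing
# invalid sequences rather than erroring; embedded NULs are dropped.
decode_utf8_lossy <- function(bytes) {
  if (is.character(bytes)) bytes <- charToRaw(iconv(bytes, "UTF-8", "latin1", sub = "?"))
  bytes <- bytes[bytes != as.raw(0)]
  if (length(bytes) == 0) return("")
  s <- rawToChar(bytes)
  out <- iconv(s, "UTF-8", "UTF-8", sub = "?")
  if (is.na(out)) out <- iconv(s, "latin1", "UTF-8")
  out
}

pdf_unescape_string <- function(x) {
  # x holds one byte per codepoint (latin1-decoded); interpret PDF
  # literal-string escapes, then decode the resulting bytes as UTF-8
  bytes <- charToRaw(iconv(x, "UTF-8", "latin1", sub = "?"))
  out <- raw(0)
  i <- 1L
  n <- length(bytes)
  while (i <= n) {
    b <- bytes[i]
    if (b == as.raw(0x5C) && i < n) {
      nxt <- rawToChar(bytes[i + 1L])
      if (nxt %in% c("n", "r", "t", "b", "f")) {
        out <- c(out, charToRaw(switch(nxt,
          n = "\n", r = "\r", t = "\t", b = "\b", f = "\f"
        )))
        i <- i + 2L
      } else if (grepl("[0-7]", nxt)) {
        j <- i + 1L
        oct <- character(0)
        while (j <= n && length(oct) < 3 && grepl("[0-7]", rawToChar(bytes[j]))) {
          oct <- c(oct, rawToChar(bytes[j]))
          j <- j + 1L
        }
        out <- c(out, as.raw(strtoi(paste(oct, collapse = ""), base = 8L)))
        i <- j
      } else if (nxt == "\n") {
        i <- i + 2L # escaped line break = continuation
      } else {
        out <- c(out, bytes[i + 1L])
        i <- i + 2L
      }
    } else {
      out <- c(out, b)
      i <- i + 1L
    }
  }
  decode_utf8_lossy(out)
}

# Reconstruct the text shown by one BT..ET block.
pdf_block_text <- function(block) {
  toks <- stringi::stri_match_all_regex(
    block,
    paste0(
      "\\(((?:[^()\\\\]|\\\\.)*)\\)\\s*(Tj|'|\")", # string + show op
      "|\\(((?:[^()\\\\]|\\\\.)*)\\)",             # bare string (TJ arrays)
      "|(T\\*|Td|TD)"                              # line moves
    )
  )[[1]]
  pieces <- character(0)
  for (r in seq_len(nrow(toks))) {
    if (!is.na(toks[r, 3])) {
      if (toks[r, 3] %in% c("'", "\"")) pieces <- c(pieces, "\n")
      pieces <- c(pieces, pdf_unescape_string(toks[r, 2]))
    } else if (!is.na(toks[r, 4])) {
      pieces <- c(pieces, pdf_unescape_string(toks[r, 4]))
    } else if (!is.na(toks[r, 5])) {
      pieces <- c(pieces, "\n")
    }
  }
  paste(pieces, collapse = "")
}

#' Extract the text layer of a PDF file
#'
#' Reads an uncompressed PDF's content streams in file order and
#' reconstructs the shown text, pages separated by `"\n\n"`. Returns an
#' empty string for files whose streams are compressed, encrypted or
#' image-only — callers treat those as not machine-readable.
#'
#' @param path PDF file path.
#' @return A single character string (possibly `""`).
#' @export
read_pdf_text <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  raw <- raw[raw != as.raw(0)]
  # latin1 decoding is byte-faithful: one codepoint per byte
  txt <- iconv(rawToChar(raw), "latin1", "UTF-8")
  if (!stringi::stri_startswith_fixed(txt, "%PDF")) {
    stop("not a PDF file: ", path, call. = FALSE)
  }
  streams <- stringi::stri_match_all_regex(
    txt, "(?s)stream\r?\n(.*?)endstream"
  )[[1]]
  if (nrow(streams) == 0) return("")
  pages <- character(0)
  for (s in streams[, 2]) {
    blocks <- stringi::stri_match_all_regex(s, "(?s)BT(.*?)ET")[[1]]
    if (nrow(blocks) == 0) next
    page_txt <- paste(
      vapply(blocks[, 2], pdf_block_text, character(1)),
      collapse = "\n"
    )
    pages <- c(pages, stringi::stri_replace_first_regex(page_txt, "^\\n+", ""))
  }
  paste(pages, collapse = "\n\n")
}
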