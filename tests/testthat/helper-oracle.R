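# Independent brute-force oracle for skip-n-gram pair counting: all
# position pairs (i, j), i < j, j - i <= n - 1, counted by a plain double
# loop. Written before and independently of the windowed implementation.
oracle_pair_multiset <- function(tokens, n) {
  counts <- list()
  L <- length(tokens)
  if (L >= 2) {
    for (i in 1:(L - 1)) {
      for (j in (i + 1):L) {
        if (j - i <= n - 1) {
          key <- paste(min(tokens[i], tokens[j]), max(tokens[i], tokens[j]),
            sep = "\u001F"
          )
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  if (length(counts) == 0) {
    return(tibble::tibble(
      term_a = character(), term_b = character(), count = integer()
    ))
  }
  keys <- sort(names(counts))
  parts <- strsplit(keys, "\u001F", fixed = TRUE)
  out <- tibble::tibble(
    term_a = vapply(parts, `[[`, character(1), 1),
    term_b = vapply(parts, `[[`, character(1), 2),
    count = vapply(keys, function(k) as.integer(counts[[k]]), integer(1))
  )
  out[order(-out$count, out$term_a, out$term_b), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random content-word stream over a small alphabet
random_stream <- function(len, alphabet_size) {
  if (len == 0) return(character(0))
  sample(paste0("w", seq_len(alphabet_size)), len, replace = TRUE)
}

# rank-insensitive comparison of two pair tables (same pairs, same counts)
expect_same_pair_table <- function(got, want) {
  got <- as.data.frame(got[, c("term_a", "term_b", "count")])
  want <- as.data.frame(want[, c("term_a", "term_b", "count")])
  got <- got[order(got$term_a, got$term_b), ]
  want <- want[order(want$term_a, want$term_b), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
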