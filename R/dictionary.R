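# Biodiversity dictionaries: curated term lists describing one observation
# type (frugivory, pollination, ...), used to filter ranked co-occurrence
# pairs — not to index snippets directly. The user makes the final call on
# ambiguous terms ("eat" + "fruit" suggests frugivory, "eat" + "prey"
# predation).

#' Load a biodiversity dictionary
#'
#' Loads either a built-in dictionary (`"frugivory"` or `"pollination"`)
#' or a custom plain-text dictionary file: one term per line, `#` comment
#' lines ignored. Terms are lowercased and deduplicated, keeping first
#' occurrence order. Matching everywhere in the package is exact on
#' lowercased token surface forms (no stemming), so dictionaries list
#' inflected and derived forms explicitly ("disperse" and "dispersal" are
#' distinct terms).
#'
#' @param path_or_name Built-in dictionary name or path to a term file.
#' @return An `obs_dictionary`: list with `name` and `terms` (character).
#' @export
#' @examples
#' frug <- load_dictionary("frugivory")
#' c("fruit", "swallow", "dispersal") %in% frug$terms
load_dictionary <- function(path_or_name) {
  stopifnot(is.character(path_or_name), length(path_or_name) == 1)
  builtin <- c(
    frugivory = "dict_frugivory.txt",
    pollination = "dict_pollination.txt"
  )
  if (path_or_name %in% names(builtin)) {
    path <- pkg_extdata(builtin[[path_or_name]])
    name <- path_or_name
  } else if (file.exists(path_or_name)) {
    path <- path_or_name
    name <- tools::file_path_sans_ext(basename(path_or_name))
  } else {
    stop(
      "unknown dictionary '", path_or_name, "': not a file, and built-in ",
      "dictionaries are: ", paste(names(builtin), collapse = ", "),
      call. = FALSE
    )
  }
  terms <- unique(stringi::stri_trans_tolower(read_wordlist(path)))
  if (length(terms) == 0) {
    stop("empty dictionary: ", path, call. = FALSE)
  }
  structure(list(name = name, terms = terms), class = "obs_dictionary")
}

#' @export
print.obs_dictionary <- function(x, ...) {
  cat(sprintf(
    "<obs_dictionary> '%s': %d terms (%s, ...)\n",
    x$name, length(x$terms),
    paste(utils::head(x$terms, 5), collapse = ", ")
  ))
  invisible(x)
}

as_dictionary <- function(x) {
  if (inherits(x, "obs_dictionary")) x else load_dictionary(x)
}
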