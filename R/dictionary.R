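STRENGTH_LEVELS <- c("strong", "moderate", "weak", "unclassified")

new_dictionary <- function(entries) {
  structure(entries, class = "hf_dictionary")
}

#' Read a speculative-pattern dictionary
#'
#' One entry per line: the representative pattern, an optional TAB followed
#' by pipe-delimited synonymous patterns, and an optional TAB followed by a
#' strength token (`strong`, `moderate` or `weak`). Lines that are blank or
#' start with `#` are skipped. Duplicate surface forms within an entry are
#' removed after case folding; entry order is preserved.
#'
#' @param path Path to a UTF-8 dictionary file.
#' @return An `hf_dictionary`: a list of entries, each with elements
#'   `representative`, `synonyms` (character vector, possibly empty) and
#'   `strength`.
#' @seealso [seed_dictionary()], [dict_stats()]
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stopf("dictionary file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    rep <- trimws(fields[[1L]])
    if (!nzchar(rep)) stopf("line %d: empty representative pattern", i)
    synonyms <- character(0)
    if (length(fields) >= 2L && nzchar(trimws(fields[[2L]]))) {
      synonyms <- trimws(strsplit(fields[[2L]], "|", fixed = TRUE)[[1L]])
      synonyms <- synonyms[nzchar(synonyms)]
    }
    strength <- "unclassified"
    if (length(fields) >= 3L && nzchar(trimws(fields[[3L]]))) {
      strength <- trimws(fields[[3L]])
      if (!strength %in% c("strong", "moderate", "weak")) {
        stopf("line %d: unknown strength token '%s'", i, strength)
      }
    }
    # fold-aware dedup: drop synonyms repeating the representative or each
    # other; keep first spelling seen
    keep <- !duplicated(tolower(c(rep, synonyms)))[-1L]
    synonyms <- synonyms[keep]
    entries[[length(entries) + 1L]] <-
      list(representative = rep, synonyms = synonyms, strength = strength)
  }
  new_dictionary(entries)
}

#' Write a dictionary in the line-oriented format read by [read_dictionary()]
#'
#' @param dictionary An `hf_dictionary`.
#' @param path Output path.
#' @export
write_dictionary <- function(dictionary, path) {
  lines <- vapply(dictionary, function(e) {
    syn <- paste(e$synonyms, collapse = "|")
    strength <- if (identical(e$strength, "unclassified")) "" else e$strength
    sub("\t+$", "", paste(e$representative, syn, strength, sep = "\t"))
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Dictionary summary counts
#'
#' @param dictionary An `hf_dictionary`.
#' @return List with `representatives`, `synonyms` and `surface_forms`
#'   (distinct case-folded forms over all entries).
#' @export
dict_stats <- function(dictionary) {
  forms <- unlist(lapply(dictionary, function(e) {
    tolower(c(e$representative, e$synonyms))
  }))
  list(representatives = length(dictionary),
       synonyms = sum(vapply(dictionary, function(e) length(e$synonyms),
                             integer(1))),
       surface_forms = length(unique(forms)))
}

#' @export
print.hf_dictionary <- function(x, ...) {
  s <- dict_stats(x)
  cat(sprintf("<hf_dictionary: %d representative / %d synonymous patterns>\n",
              s$representatives, s$synonyms))
  invisible(x)
}

#' The bundled seed dictionary of speculative patterns
#'
#' The originally curated lexicon this method was developed with is not
#' publicly available, so the package ships a synthetic reconstruction
#' (`seed_dictionary_synthetic.tsv`): every pattern string printed in the
#' publication is included verbatim, padded with systematic modal-verb
#' compositions to the documented size of 156 representative and 392
#' synonymous patterns. Bare weak terms ("potential", "possibility",
#' "should", "would") are deliberately absent in standalone form and occur
#' only inside composed patterns such as "could be a potential".
#'
#' @return An `hf_dictionary`.
#' @export
seed_dictionary <- function() {
  read_dictionary(seed_dictionary_path())
}

#' @rdname seed_dictionary
#' @export
seed_dictionary_path <- function() {
  system.file("extdata", "seed_dictionary_synthetic.tsv",
              package = "hypofinder", mustWork = TRUE)
}
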