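# Shared test helpers: tiny in-code fixtures, no files needed.

# Single-sentence document -> its hf_sentence
make_sentence <- function(text, doc_id = "t1") {
  sents <- segment_sentences(new_document(doc_id, text))
  stopifnot(length(sents) == 1L)
  sents[[1L]]
}

# Dictionary built directly from representative -> synonyms pairs
make_dictionary <- function(...) {
  pairs <- list(...)
  entries <- lapply(names(pairs), function(rep) {
    list(representative = rep, synonyms = pairs[[rep]],
         strength = "unclassified")
  })
  structure(entries, class = "hf_dictionary")
}

make_index <- function(...) compile_index(build_patterns(make_dictionary(...)))

# Random sentence over a small token alphabet (forces dictionary overlap)
RANDOM_ALPHABET <- c("may", "be", "involved", "seems", "to", "play", "tau",
                     "amyloid", "could", "a", "potential", "role", "that",
                     "suggest", "in", "disease")

random_sentence <- function(n_tokens = 12) {
  text <- paste(sample(RANDOM_ALPHABET, n_tokens, replace = TRUE),
                collapse = " ")
  make_sentence(paste0(toupper(substr(text, 1, 1)), substr(text, 2, nchar(text))))
}

random_dictionary <- function(n_entries = 6, max_len = 3) {
  pairs <- list()
  for (i in seq_len(n_entries)) {
    form <- paste(sample(RANDOM_ALPHABET, sample.int(max_len, 1),
                         replace = TRUE), collapse = " ")
    nsyn <- sample.int(3L, 1L) - 1L
    syns <- character(0)
    if (nsyn > 0) {
      syns <- vapply(seq_len(nsyn), function(j) {
        paste(sample(RANDOM_ALPHABET, sample.int(max_len, 1), replace = TRUE),
              collapse = " ")
      }, character(1))
    }
    pairs[[form]] <- syns
  }
  # map may collapse duplicate representatives; keep unique names
  pairs <- pairs[!duplicated(names(pairs))]
  do.call(make_dictionary, pairs)
}

match_fields <- function(m) m[, c("start", "end", "pattern", "surface")]

# Minimal BioScope-dialect XML fixture written to a temp file
write_bioscope_fixture <- function(path, with_negation_only = FALSE) {
  if (with_negation_only) {
    body <- paste0(
      "<Document><DocID>neg1</DocID>",
      "<sentence>The effect was <cue type=\"negation\" ref=\"x1\">not</cue> observed.</sentence>",
      "</Document>")
  } else {
    body <- paste0(
      "<Document><DocID>doc1</DocID>",
      "<sentence>Tau <cue type=\"speculation\" ref=\"s1\">may</cue> drive decline.</sentence>",
      "<sentence><xcope id=\"x1\">This <cue type=\"speculation\" ref=\"s2\">appears to</cue> hold</xcope> in mice.</sentence>",
      "</Document>",
      "<Document><DocID>doc2</DocID>",
      "<sentence>Levels were <cue type=\"negation\" ref=\"n1\">not</cue> elevated.</sentence>",
      "<sentence>Amyloid <cue type=\"speculation\" ref=\"s3\">might be</cue> causal.</sentence>",
      "</Document>")
  }
  writeLines(paste0("<DocumentSet>", body, "</DocumentSet>"), path)
  path
}
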