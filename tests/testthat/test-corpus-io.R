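test_that("plain corpus blocks parse into documents in file order", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PMID\t14699432", "CSF tau may be a biomarker.", "",
               "PMID\t99999999", "Second abstract line one", "line two"), path)
  corpus <- read_plain_corpus(path)
  expect_length(corpus, 2L)
  expect_identical(corpus[[1]]$doc_id, "14699432")
  expect_identical(corpus[[2]]$doc_id, "99999999")
  # line joins are normalized to a single space
  expect_identical(corpus[[2]]$text, "Second abstract line one line two")
})

test_that("plain corpus edge cases: empty file, missing id line", {
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_length(read_plain_corpus(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("no header here", "text"), bad)
  expect_error(read_plain_corpus(bad), "PMID")
})

test_that("plain corpus round-trips through write_plain_corpus", {
  corpus <- as_corpus(list(new_document("a1", "Alpha text."),
                           new_document("b2", "Beta text.")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_plain_corpus(corpus, path)
  back <- read_plain_corpus(path)
  expect_identical(lapply(back, `[[`, "text"), lapply(corpus, `[[`, "text"))
})

test_that("dictionary lines parse representatives, synonyms and strengths", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("appear to\tappeared to be|appears to be|appear that",
               "may be",
               "could be a potential\t\tweak"), path)
  dict <- read_dictionary(path)
  expect_length(dict, 3L)
  expect_identical(dict[[1]]$representative, "appear to")
  expect_length(dict[[1]]$synonyms, 3L)
  expect_identical(dict[[2]]$synonyms, character(0))
  expect_identical(dict[[3]]$strength, "weak")
})

test_that("dictionary parse errors carry line numbers; duplicates fold away", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("may be", "\tno rep here"), bad)
  expect_error(read_dictionary(bad), "line 2")

  badstr <- withr::local_tempfile(fileext = ".tsv")
  writeLines("may be\t\tSOLID", badstr)
  expect_error(read_dictionary(badstr), "strength")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines("may be\tMay Be|may have been|may have been", dup)
  expect_identical(read_dictionary(dup)[[1]]$synonyms, "may have been")
})

test_that("dictionary round-trips through write_dictionary", {
  dict <- make_dictionary("appear to" = c("appears to", "appeared to"),
                          "may be" = character(0))
  dict[[1]]$strength <- "strong"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(dict, path)
  back <- read_dictionary(path)
  expect_identical(lapply(back, `[[`, "representative"),
                   lapply(dict, `[[`, "representative"))
  expect_identical(back[[1]]$synonyms, dict[[1]]$synonyms)
  expect_identical(back[[1]]$strength, "strong")
})

test_that("standoff matches round-trip and zero matches give a header-only file", {
  doc <- new_document("d1", "Tau may be involved in decline. It is stable.")
  idx <- make_index("may be involved" = character(0))
  res <- classify_corpus(as_corpus(list(doc)), idx)
  path <- withr::local_tempfile(fileext = ".tsv")

  write_matches(res$matches[0, ], path)
  expect_length(readLines(path), 1L)

  write_matches(res$matches, path)
  back <- read_annotations(path, corpus = as_corpus(list(doc)))
  expect_identical(back$start, res$matches$start)
  expect_identical(back$end, res$matches$end)
  expect_identical(back$surface, res$matches$surface)
})

test_that("annotation whose surface disagrees with the document is rejected", {
  doc <- new_document("d1", "Tau may be involved in decline.")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("doc_id\tstart\tend\tsurface",
               "d1\t4\t10\twrong!"), path)
  expect_error(read_annotations(path, corpus = as_corpus(list(doc))),
               "d1.*\\[4,10\\)")
})

test_that("BioScope reader extracts speculation cues with faithful offsets", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_bioscope_fixture(path)
  bs <- read_bioscope(path)
  expect_length(bs$documents, 2L)
  expect_identical(nrow(bs$annotations), 3L)
  expect_setequal(bs$annotations$surface, c("may", "appears to", "might be"))
  # offset fidelity: every span surface equals the document text slice
  for (k in seq_len(nrow(bs$annotations))) {
    doc <- bs$documents[[bs$annotations$doc_id[k]]]
    expect_identical(
      substr(doc$text, bs$annotations$start[k] + 1, bs$annotations$end[k]),
      bs$annotations$surface[k])
  }
})

test_that("BioScope documents with only negation cues yield no annotations", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_bioscope_fixture(path, with_negation_only = TRUE)
  bs <- read_bioscope(path)
  expect_length(bs$documents, 1L)
  expect_identical(nrow(bs$annotations), 0L)
})

test_that("malformed BioScope XML is a parse error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<DocumentSet><sentence>unclosed", path)
  expect_error(read_bioscope(path), "malformed XML")
})
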