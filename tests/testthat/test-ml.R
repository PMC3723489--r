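test_that("feature families are namespaced and separable", {
  s <- make_sentence("proteins may regulate tau")
  base <- extract_features(s, "base")
  expect_setequal(names(base), c("base:proteins", "base:may",
                                 "base:regulate", "base:tau"))

  idx <- make_index("may" = character(0))
  spec <- extract_features(s, "spec", index = idx)
  expect_identical(names(spec), "spec:may")

  both <- extract_features(s, c("base", "spec"), index = idx)
  expect_setequal(names(both), c(names(base), names(spec)))
  # removing a namespace removes exactly its features
  expect_setequal(setdiff(names(both), names(base)), names(spec))
})

test_that("lex features cover lemma n-grams and noun affixes", {
  lexicon <- data.frame(surface = c("proteins", "may", "regulate", "tau"),
                        lemma = c("protein", "may", "regulate", "tau"),
                        is_noun = c(TRUE, FALSE, FALSE, TRUE))
  prov <- lexicon_linguistic_provider(lexicon)
  s <- make_sentence("proteins may regulate tau")
  f <- names(extract_features(s, "lex", provider = prov))
  expect_true(all(c("lex:uni:protein", "lex:bi:protein|may",
                    "lex:tri:protein|may|regulate") %in% f))
  # 2/3/4-character prefixes and suffixes of the noun "proteins"
  expect_true(all(c("lex:pre2:pr", "lex:pre3:pro", "lex:pre4:prot",
                    "lex:suf2:ns", "lex:suf3:ins", "lex:suf4:eins") %in% f))
  expect_false(any(grepl("^lex:pre", f) & grepl(":ma$", f)))  # non-noun skipped
  expect_error(extract_features(s, "lex"), "provider")
})

test_that("dependency triples appear only when the provider supplies them", {
  deps <- function(tokens) data.frame(gov = "regulate", rel = "nsubj",
                                      dep = "proteins")
  prov <- rule_linguistic_provider(dependencies = deps)
  f <- names(extract_features(make_sentence("proteins regulate tau"),
                              "lex", provider = prov))
  expect_true("lex:dep:regulate|nsubj|proteins" %in% f)
  f0 <- names(extract_features(make_sentence("proteins regulate tau"),
                               "lex", provider = rule_linguistic_provider()))
  expect_false(any(grepl("^lex:dep:", f0)))
})

test_that("instances label sentences by gold-span overlap", {
  text <- paste("First sentence is plain. Tau may be involved here.",
                "Third is plain. Fourth closes the abstract.")
  doc <- new_document("d1", text)
  start <- regexpr("may be", text, fixed = TRUE) - 1L
  gold <- data.frame(doc_id = "d1", start = start, end = start + 6L,
                     surface = "may be")
  bi <- build_instances(as_corpus(list(doc)), gold)
  expect_identical(bi$instances$label,
                   c("NEGATIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"))

  expect_identical(build_instances(as_corpus(list(doc)),
                                   gold[0, ])$instances$label,
                   rep("NEGATIVE", 4L))

  straddle <- data.frame(doc_id = "d1", start = 20L, end = 40L,
                         surface = "x")
  expect_error(build_instances(as_corpus(list(doc)), straddle), "straddles")
})

test_that("training is deterministic and fits separable data perfectly", {
  fx <- generate_corpus(synthetic_corpus_spec(
    n_documents = 40, positive_rate = 0.25, seed = 19))
  bi <- build_instances(fx$documents, fx$gold_spans)
  idx <- compile_index(build_patterns(seed_dictionary()))
  m1 <- train_sentence_classifier(bi$instances, bi$sentences,
                                  modes = c("base", "spec"), index = idx,
                                  seed = 7)
  p1 <- predict(m1, bi$sentences)
  m2 <- train_sentence_classifier(bi$instances, bi$sentences,
                                  modes = c("base", "spec"), index = idx,
                                  seed = 7)
  expect_identical(p1, predict(m2, bi$sentences))
  # training-set predictions on separable data are all correct
  expect_identical(p1$label, bi$instances$label)

  onlyneg <- bi$instances[bi$instances$label == "NEGATIVE", ]
  expect_error(train_sentence_classifier(
    onlyneg, bi$sentences[bi$instances$label == "NEGATIVE"]), "both labels")
})

test_that("spec features alone reach F = 1 when every cue type is seen in training", {
  # a compact dictionary guarantees cue-type coverage across the split
  dict <- make_dictionary("may be" = "may be involved",
                          "seems to" = "seems to play",
                          "could be" = character(0),
                          "suggest that" = "suggests that",
                          "appears to" = character(0))
  fx <- generate_corpus(synthetic_corpus_spec(
    n_documents = 80, positive_rate = 0.25, dictionary = dict, seed = 31))
  bi <- build_instances(fx$documents, fx$gold_spans)
  idx <- compile_index(build_patterns(dict))
  n <- nrow(bi$instances)
  test <- seq_len(n) %% 5L == 0L
  model <- train_sentence_classifier(bi$instances[!test, ],
                                     bi$sentences[!test], modes = "spec",
                                     index = idx, seed = 7)
  pred <- predict(model, bi$sentences[test])
  expect_equal(sentence_prf(pred, bi$instances[test, ])$f_score, 1)
})

test_that("all switchable algorithms honour the training contract", {
  dict <- make_dictionary("may be" = character(0))
  fx <- generate_corpus(synthetic_corpus_spec(
    n_documents = 20, positive_rate = 0.3, dictionary = dict, seed = 5))
  bi <- build_instances(fx$documents, fx$gold_spans)
  idx <- compile_index(build_patterns(dict))
  for (algo in c("maxent", "naive_bayes", "knn", "decision_tree", "svm")) {
    model <- train_sentence_classifier(bi$instances, bi$sentences,
                                       algorithm = algo,
                                       modes = "spec", index = idx, seed = 2)
    pred <- predict(model, bi$sentences)
    expect_identical(pred$label, bi$instances$label)
  }
})

test_that("sentences without known features fall back to the majority class", {
  dict <- make_dictionary("may be" = character(0))
  fx <- generate_corpus(synthetic_corpus_spec(
    n_documents = 20, positive_rate = 0.3, dictionary = dict, seed = 5))
  bi <- build_instances(fx$documents, fx$gold_spans)
  idx <- compile_index(build_patterns(dict))
  model <- train_sentence_classifier(bi$instances, bi$sentences,
                                     modes = "spec", index = idx, seed = 2)
  blank <- make_sentence("Zzz qqq www", doc_id = "x")
  expect_identical(predict(model, list(blank))$label, model$majority)
})
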