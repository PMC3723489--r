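mk_spans <- function(doc_id, start, end, surface = strrep("x", end - start)) {
  data.frame(doc_id = doc_id, start = start, end = end, surface = surface,
             stringsAsFactors = FALSE)
}

mk_labels <- function(labels, doc_id = "d") {
  data.frame(doc_id = doc_id, sentence_index = seq_along(labels),
             label = labels, stringsAsFactors = FALSE)
}

test_that("span precision/recall/F follow the counting formulas", {
  gold <- mk_spans("d", c(0L, 10L, 20L), c(5L, 15L, 25L))
  expect_equal(span_prf(gold, gold)$f_score, 1)

  pred <- mk_spans("d", c(0L, 10L, 40L), c(5L, 15L, 45L))  # tp=2 fp=1 fn=1
  r <- span_prf(pred, gold)
  expect_identical(c(r$tp, r$fp, r$fn), c(2L, 1L, 1L))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f_score, 2 / 3)

  # order invariance under the exact criterion
  r2 <- span_prf(pred[c(3, 1, 2), ], gold[c(2, 3, 1), ])
  expect_equal(r2$f_score, r$f_score)
})

test_that("exact and overlap criteria disagree on partial spans", {
  gold <- mk_spans("d", 4L, 21L, "might be involved")
  pred <- mk_spans("d", 4L, 12L, "might be")
  exact <- span_prf(pred, gold, criterion = "exact")
  expect_identical(c(exact$tp, exact$fp, exact$fn), c(0L, 1L, 1L))
  overlap <- span_prf(pred, gold, criterion = "overlap")
  expect_identical(c(overlap$tp, overlap$fp, overlap$fn), c(1L, 0L, 0L))
  expect_equal(overlap$f_score, 1)
})

test_that("sentence metrics score the POSITIVE class", {
  gold <- mk_labels(c(rep("POSITIVE", 12), rep("NEGATIVE", 8)))
  pred <- mk_labels(c(rep("POSITIVE", 8), rep("NEGATIVE", 4),
                      rep("POSITIVE", 2), rep("NEGATIVE", 6)))
  r <- sentence_prf(pred, gold)          # tp=8 fp=2 fn=4
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 2 / 3)

  allneg <- mk_labels(rep("NEGATIVE", 20))
  expect_warning(r0 <- sentence_prf(allneg, gold), "undefined")
  expect_equal(r0$precision, 0)
  expect_equal(r0$recall, 0)
  expect_equal(r0$f_score, 0)

  expect_error(sentence_prf(mk_labels(rep("NEGATIVE", 3)), gold), "universe")
})

test_that("F is bounded by the larger of P and R and symmetric in them", {
  set.seed(12)
  for (i in 1:30) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    r <- suppressWarnings(hypofinder:::prf_report(tp, fp, fn, "sentence"))
    expect_gte(r$precision, 0); expect_lte(r$precision, 1)
    expect_gte(r$recall, 0); expect_lte(r$recall, 1)
    expect_lte(r$f_score, max(r$precision, r$recall) + 1e-12)
    swapped <- suppressWarnings(hypofinder:::prf_report(tp, fn, fp, "sentence"))
    expect_equal(r$f_score, swapped$f_score)
  }
})

test_that("Cohen's kappa matches hand-computed agreement", {
  a <- c(rep("POSITIVE", 20), rep("POSITIVE", 5), rep("NEGATIVE", 5),
         rep("NEGATIVE", 20))
  b <- c(rep("POSITIVE", 20), rep("NEGATIVE", 5), rep("POSITIVE", 5),
         rep("NEGATIVE", 20))
  # hand calculation: po = 40/50 = 0.8; both marginals 0.5/0.5 so pe = 0.5;
  # kappa = (0.8 - 0.5) / 0.5 = 0.6
  r <- cohen_kappa(a, b)
  expect_equal(r$observed_agreement, 0.8)
  expect_equal(r$expected_agreement, 0.5)
  expect_equal(r$kappa, 0.6)

  expect_equal(cohen_kappa(a, a)$kappa, 1)
  expect_lte(cohen_kappa(rep("POSITIVE", 10), rep("NEGATIVE", 10))$kappa, 0)
  expect_error(cohen_kappa(character(0), character(0)), "empty")
})

test_that("kappa concentrates near zero for independent random labelings", {
  set.seed(2718)
  ks <- replicate(200, {
    a <- sample(c("POSITIVE", "NEGATIVE"), 200, replace = TRUE)
    b <- sample(c("POSITIVE", "NEGATIVE"), 200, replace = TRUE)
    cohen_kappa(a, b)$kappa
  })
  expect_lt(mean(abs(ks)), 0.1)
})

test_that("adjudication keeps agreements, intersects partial overlaps, and honours decisions", {
  a <- data.frame(doc_id = "d", start = 4L, end = 21L,
                  surface = "might be involved")
  b <- data.frame(doc_id = "d", start = 4L, end = 12L, surface = "might be")
  merged <- adjudicate_spans(a, b)
  expect_identical(merged$surface, "might be")   # "involved" removed
  expect_identical(merged$start, 4L)
  expect_identical(merged$end, 12L)

  same <- rbind(a, data.frame(doc_id = "d", start = 30L, end = 35L,
                              surface = "might"))
  expect_identical(adjudicate_spans(same, same)[, c("start", "end")],
                   same[order(same$start), c("start", "end")])

  only_a <- data.frame(doc_id = "d", start = 50L, end = 55L,
                       surface = "maybe")
  expect_error(adjudicate_spans(rbind(a, only_a), b), "\\[50,55\\)")
  dec <- data.frame(doc_id = "d", start = 50L, end = 55L,
                    decision = "reject")
  m2 <- adjudicate_spans(rbind(a, only_a), b, decisions = dec)
  expect_false(any(m2$start == 50L))
  dec$decision <- "accept"
  m3 <- adjudicate_spans(rbind(a, only_a), b, decisions = dec)
  expect_true(any(m3$start == 50L))
})

test_that("adjudication never invents spans nor deletes agreed ones", {
  set.seed(314)
  for (rep in 1:40) {
    n_a <- sample(1:6, 1); n_b <- sample(1:6, 1)
    mk <- function(n) {
      start <- sort(sample(seq(0, 90, by = 5), n))
      end <- start + sample(3:9, n, replace = TRUE)
      data.frame(doc_id = "d", start = start, end = end,
                 surface = vapply(end - start, strrep, character(1),
                                  x = "w"), stringsAsFactors = FALSE)
    }
    a <- mk(n_a); b <- mk(n_b)
    dec <- rbind(a, b); dec$decision <- "accept"
    merged <- suppressWarnings(adjudicate_spans(a, b, decisions = dec))
    if (nrow(merged) > 0) {
      inside_union <- vapply(seq_len(nrow(merged)), function(i) {
        any(merged$start[i] >= a$start & merged$end[i] <= a$end) ||
          any(merged$start[i] >= b$start & merged$end[i] <= b$end)
      }, logical(1))
      expect_true(all(inside_union))   # no invention beyond input extents
    }
    agreed <- merge(a[, c("start", "end")], b[, c("start", "end")])
    if (nrow(agreed) > 0) {
      kept <- paste(merged$start, merged$end)
      expect_true(all(paste(agreed$start, agreed$end) %in% kept))
    }
  }
})
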