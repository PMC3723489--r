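# Evaluation: span- and sentence-level precision/recall/F over the POSITIVE
# class, two-rater Cohen's kappa, and rule-based adjudication of dual
# annotations.

prf_report <- function(tp, fp, fn, level, criterion = NA_character_) {
  precision <- if (tp + fp == 0L) { warnf("precision undefined (tp+fp=0); reporting 0"); 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) { warnf("recall undefined (tp+fn=0); reporting 0"); 0 } else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_score = f, level = level,
                 criterion = criterion),
            class = "hf_eval")
}

#' @export
print.hf_eval <- function(x, ...) {
  cat(sprintf("<hf_eval %s%s> TP=%d FP=%d FN=%d  P=%.3f R=%.3f F=%.3f\n",
              x$level,
              if (is.na(x$criterion)) "" else paste0("/", x$criterion),
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Span-level precision, recall and F-score
#'
#' Under the `exact` criterion a predicted span is a true positive iff an
#' unmatched gold span with identical `(doc_id, start, end)` exists. Under
#' `overlap`, spans sharing at least one character are paired one-to-one,
#' greedily by position. False positives are unpaired predictions, false
#' negatives unpaired gold spans.
#'
#' @param predicted,gold Span data.frames (`doc_id`, `start`, `end`).
#' @param criterion `"exact"` (default) or `"overlap"`.
#' @param corpus Optional `hf_corpus`; if supplied both span sets are
#'   validated against it first.
#' @return An `hf_eval` report.
#' @export
span_prf <- function(predicted, gold, criterion = c("exact", "overlap"),
                     corpus = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(corpus)) {
    validate_spans(predicted, corpus)
    validate_spans(gold, corpus)
  }
  tp <- 0L
  if (criterion == "exact") {
    pk <- span_key(predicted$doc_id, predicted$start, predicted$end)
    gk <- span_key(gold$doc_id, gold$start, gold$end)
    # multiset matching: each gold span consumed at most once
    avail <- table(gk)
    for (k in pk) {
      if (!is.na(avail[k]) && avail[k] > 0L) {
        tp <- tp + 1L
        avail[k] <- avail[k] - 1L
      }
    }
  } else {
    for (id in unique(c(predicted$doc_id, gold$doc_id))) {
      p <- predicted[predicted$doc_id == id, , drop = FALSE]
      g <- gold[gold$doc_id == id, , drop = FALSE]
      p <- p[order(p$start, p$end), , drop = FALSE]
      g <- g[order(g$start, g$end), , drop = FALSE]
      used <- rep(FALSE, nrow(g))
      for (i in seq_len(nrow(p))) {
        for (j in seq_len(nrow(g))) {
          if (!used[j] && p$start[i] < g$end[j] && g$start[j] < p$end[i]) {
            tp <- tp + 1L
            used[j] <- TRUE
            break
          }
        }
      }
    }
  }
  prf_report(tp, nrow(predicted) - tp, nrow(gold) - tp,
             level = "span", criterion = criterion)
}

#' Sentence-level precision, recall and F-score over the POSITIVE class
#'
#' @param predicted,gold Label data.frames (`doc_id`, `sentence_index`,
#'   `label` in `{"POSITIVE","NEGATIVE"}`) over the identical sentence
#'   universe; a universe mismatch is an error.
#' @return An `hf_eval` report.
#' @export
sentence_prf <- function(predicted, gold) {
  pk <- sentence_key(predicted$doc_id, predicted$sentence_index)
  gk <- sentence_key(gold$doc_id, gold$sentence_index)
  if (anyDuplicated(pk) || anyDuplicated(gk) || !setequal(pk, gk)) {
    stopf("predicted and gold labels must cover the identical sentence universe")
  }
  g <- gold$label[match(pk, gk)]
  p <- predicted$label
  tp <- sum(p == "POSITIVE" & g == "POSITIVE")
  fp <- sum(p == "POSITIVE" & g == "NEGATIVE")
  fn <- sum(p == "NEGATIVE" & g == "POSITIVE")
  prf_report(tp, fp, fn, level = "sentence")
}

#' Two-rater Cohen's kappa
#'
#' Chance-corrected agreement between two annotators' labels over the same
#' units: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed
#' agreement and `p_e` the agreement expected from the raters' marginal
#' label frequencies. Identical labelings with both classes present give 1;
#' if `p_e = 1` (both raters constant and identical) kappa is reported as 1.
#'
#' @param labels_a,labels_b Equal-length character/factor vectors, or label
#'   data.frames as in [sentence_prf()] (joined on their sentence keys).
#' @param unit Unit description stored in the report (default
#'   `"sentence"`).
#' @return An `hf_agreement` report: `observed_agreement`,
#'   `expected_agreement`, `kappa`, `unit`, `n`.
#' @export
cohen_kappa <- function(labels_a, labels_b, unit = "sentence") {
  if (is.data.frame(labels_a)) {
    ka <- sentence_key(labels_a$doc_id, labels_a$sentence_index)
    kb <- sentence_key(labels_b$doc_id, labels_b$sentence_index)
    if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb)) {
      stopf("both annotators must label the identical unit set")
    }
    labels_b <- labels_b$label[match(ka, kb)]
    labels_a <- labels_a$label
  }
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (length(a) == 0L) stopf("cannot compute agreement over an empty unit set")
  if (length(a) != length(b)) stopf("label vectors differ in length")
  po <- mean(a == b)
  classes <- union(a, b)
  pe <- sum(vapply(classes, function(cl) mean(a == cl) * mean(b == cl),
                   numeric(1)))
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  structure(list(observed_agreement = po, expected_agreement = pe,
                 kappa = kappa, unit = unit, n = length(a)),
            class = "hf_agreement")
}

#' @export
print.hf_agreement <- function(x, ...) {
  cat(sprintf("<hf_agreement %s, n=%d> p_o=%.3f p_e=%.3f kappa=%.3f\n",
              x$unit, x$n, x$observed_agreement, x$expected_agreement,
              x$kappa))
  invisible(x)
}

#' Merge two annotators' spans under the four adjudication rules
#'
#' Rules: (1) spans marked identically by both annotators are kept
#' unconditionally; (2) partially overlapping pairs are replaced by their
#' character intersection — only the conflicting words are removed — snapped
#' to token boundaries (e.g. "might be involved" vs "might be" merges to
#' "might be"); (3) spans marked by exactly one annotator are kept iff the
#' consensus decision is `accept`; (4) no span absent from both inputs ever
#' appears. A missing decision for a disputed span is an error listing the
#' disputed spans.
#'
#' @param spans_a,spans_b Span data.frames (`doc_id`, `start`, `end`,
#'   `surface`).
#' @param decisions Decision table for disputed (single-annotator,
#'   non-overlapping) spans: data.frame with `doc_id`, `start`, `end`,
#'   `decision` in `{"accept","reject"}`. May be `NULL` when no span is
#'   disputed.
#' @return Merged span data.frame, sorted by document and offset.
#' @export
adjudicate_spans <- function(spans_a, spans_b, decisions = NULL) {
  cols <- c("doc_id", "start", "end", "surface")
  spans_a <- spans_a[, cols, drop = FALSE]
  spans_b <- spans_b[, cols, drop = FALSE]
  out <- list()
  disputed <- list()
  for (id in unique(c(spans_a$doc_id, spans_b$doc_id))) {
    a <- spans_a[spans_a$doc_id == id, , drop = FALSE]
    b <- spans_b[spans_b$doc_id == id, , drop = FALSE]
    ka <- paste(a$start, a$end)
    kb <- paste(b$start, b$end)
    agreed <- ka %in% kb
    for (i in which(agreed)) out[[length(out) + 1L]] <- a[i, , drop = FALSE]
    a2 <- a[!agreed, , drop = FALSE]
    b2 <- b[!(kb %in% ka), , drop = FALSE]
    used_b <- rep(FALSE, nrow(b2))
    for (i in seq_len(nrow(a2))) {
      j <- which(!used_b & a2$start[i] < b2$end & b2$start < a2$end[i])
      if (length(j) > 0L) {
        j <- j[[1L]]
        used_b[j] <- TRUE
        s <- max(a2$start[i], b2$start[j])
        e <- min(a2$end[i], b2$end[j])
        snapped <- snap_to_tokens(a2[i, , drop = FALSE], s, e)
        if (!is.null(snapped)) out[[length(out) + 1L]] <- snapped
      } else {
        disputed[[length(disputed) + 1L]] <- a2[i, , drop = FALSE]
      }
    }
    for (j in which(!used_b)) {
      disputed[[length(disputed) + 1L]] <- b2[j, , drop = FALSE]
    }
  }
  if (length(disputed) > 0L) {
    dis <- do.call(rbind, disputed)
    dk <- span_key(dis$doc_id, dis$start, dis$end)
    if (is.null(decisions)) {
      stopf("decisions required for disputed span(s): %s",
            paste(sprintf("%s[%d,%d)", dis$doc_id, dis$start, dis$end),
                  collapse = ", "))
    }
    deck <- span_key(decisions$doc_id, decisions$start, decisions$end)
    miss <- setdiff(dk, deck)
    if (length(miss) > 0L) {
      bad <- dis[dk %in% miss, , drop = FALSE]
      stopf("missing decision for disputed span(s): %s",
            paste(sprintf("%s[%d,%d)", bad$doc_id, bad$start, bad$end),
                  collapse = ", "))
    }
    dec <- decisions$decision[match(dk, deck)]
    if (!all(dec %in% c("accept", "reject"))) {
      stopf("decisions must be 'accept' or 'reject'")
    }
    for (i in which(dec == "accept")) {
      out[[length(out) + 1L]] <- dis[i, , drop = FALSE]
    }
  }
  if (length(out) == 0L) return(empty_spans()[, c("doc_id", "start", "end", "surface")])
  merged <- do.call(rbind, out)[, c("doc_id", "start", "end", "surface")]
  merged <- unique(merged)
  merged <- merged[order(merged$doc_id, merged$start, merged$end), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

# Restrict span [s, e) to whole tokens of the carrier annotation row; the
# carrier's surface plus offsets suffice to re-tokenize locally.
snap_to_tokens <- function(row, s, e) {
  toks <- tokenize(row$surface, base_offset = row$start)
  keep <- toks$start >= s & toks$end <= e
  if (!any(keep)) {
    warnf("adjudication intersection [%d,%d) in %s covers no whole token; pair dropped",
          s, e, row$doc_id)
    return(NULL)
  }
  ns <- min(toks$start[keep])
  ne <- max(toks$end[keep])
  data.frame(doc_id = row$doc_id, start = ns, end = ne,
             surface = slice_text(row$surface, ns - row$start, ne - row$start),
             stringsAsFactors = FALSE)
}
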