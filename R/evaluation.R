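# Strict/lenient scoring of predictions against a gold standard, at mention
# and document level: P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R).

new_counts <- function(TP = 0L, FP = 0L, FN = 0L) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  list(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN))
}

add_counts <- function(a, b) {
  new_counts(a$TP + b$TP, a$FP + b$FP, a$FN + b$FN)
}

# greedy one-to-one matching of overlapping spans within one document:
# pairs ordered by overlap size (desc), then leftmost gold, then leftmost
# prediction; each gold matches at most one prediction and vice versa
match_spans_lenient <- function(gold, pred) {
  if (nrow(gold) == 0L || nrow(pred) == 0L) return(new_counts(0L, nrow(pred), nrow(gold)))
  pairs <- list()
  for (g in seq_len(nrow(gold))) {
    for (p in seq_len(nrow(pred))) {
      ov <- min(gold$end[g], pred$end[p]) - max(gold$start[g], pred$start[p])
      if (ov > 0L) pairs[[length(pairs) + 1L]] <- c(g, p, ov)
    }
  }
  if (!length(pairs)) return(new_counts(0L, nrow(pred), nrow(gold)))
  m <- do.call(rbind, pairs)
  m <- m[order(-m[, 3L], gold$start[m[, 1L]], pred$start[m[, 2L]]), ,
         drop = FALSE]
  gold_used <- logical(nrow(gold)); pred_used <- logical(nrow(pred))
  tp <- 0L
  for (r in seq_len(nrow(m))) {
    g <- m[r, 1L]; p <- m[r, 2L]
    if (!gold_used[g] && !pred_used[p]) {
      gold_used[g] <- TRUE; pred_used[p] <- TRUE
      tp <- tp + 1L
    }
  }
  new_counts(tp, sum(!pred_used), sum(!gold_used))
}

#' Mention-level confusion counts
#'
#' Strict: a true positive needs identical `(start, end)` offsets. Lenient:
#' any character overlap suffices, with greedy one-to-one pairing (largest
#' overlap first). Counts are summed over documents.
#'
#' @param gold,predicted Standoff data.frames (doc_id, start, end, ...).
#' @param mode `"strict"` or `"lenient"`.
#' @return list(TP, FP, FN).
#' @export
match_mentions <- function(gold, predicted, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  total <- new_counts()
  for (id in union(gold$doc_id, predicted$doc_id)) {
    g <- gold[gold$doc_id == id, , drop = FALSE]
    p <- predicted[predicted$doc_id == id, , drop = FALSE]
    cnt <- if (mode == "strict") {
      gk <- paste(g$start, g$end)
      pk <- paste(p$start, p$end)
      tp <- length(intersect(gk, pk))
      new_counts(tp, length(unique(pk)) - tp, length(unique(gk)) - tp)
    } else {
      match_spans_lenient(g, p)
    }
    total <- add_counts(total, cnt)
  }
  total
}

#' Document-level confusion counts
#'
#' Per-document resource-name sets are compared after [normalize_name()];
#' strict comparison is case-sensitive, lenient case-insensitive. TP/FP/FN
#' are set intersection/difference sizes summed over documents.
#'
#' @param gold,predicted data.frames with columns doc_id, name.
#' @param mode `"strict"` or `"lenient"`.
#' @return list(TP, FP, FN).
#' @export
match_documents <- function(gold, predicted, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  norm <- function(x) {
    x <- normalize_name(x)
    if (mode == "lenient") tolower(x) else x
  }
  total <- new_counts()
  for (id in union(gold$doc_id, predicted$doc_id)) {
    g <- unique(norm(gold$name[gold$doc_id == id]))
    p <- unique(norm(predicted$name[predicted$doc_id == id]))
    tp <- length(intersect(g, p))
    total <- add_counts(total, new_counts(tp, length(p) - tp,
                                          length(g) - tp))
  }
  total
}

#' Precision, recall and F-measure from confusion counts
#'
#' Zero denominators yield 0 by convention.
#'
#' @param counts list(TP, FP, FN).
#' @return list(precision, recall, f_measure).
#' @export
compute_scores <- function(counts) {
  p <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP) else 0
  r <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_measure = f)
}

#' Evaluate predictions against gold at one level and mode
#'
#' @param gold,predicted Mention-level standoff data.frames, or
#'   document-level (doc_id, name) data.frames when `level = "document"`.
#' @param level `"mention"` or `"document"`.
#' @param mode `"strict"` or `"lenient"`.
#' @return data.frame(level, mode, TP, FP, FN, precision, recall, f_measure).
#' @export
evaluate_predictions <- function(gold, predicted,
                                 level = c("mention", "document"),
                                 mode = c("strict", "lenient")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  counts <- if (level == "mention") {
    match_mentions(gold, predicted, mode)
  } else {
    match_documents(gold, predicted, mode)
  }
  s <- compute_scores(counts)
  data.frame(level = level, mode = mode, TP = counts$TP, FP = counts$FP,
             FN = counts$FN, precision = s$precision, recall = s$recall,
             f_measure = s$f_measure, stringsAsFactors = FALSE)
}
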