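# Cross-mention weak evidence, thresholding, and document-wide propagation of
# accepted names.

#' Normalize a resource name
#'
#' Collapses internal whitespace, maps dashes to spaces, trims. Case is
#' preserved: mention grouping within a document is case-sensitive; survey
#' grouping additionally case-folds.
#'
#' @param surface Character vector of surfaces.
#' @return Normalized names.
#' @export
normalize_name <- function(surface) {
  squish(gsub("[-–—]", " ", surface))
}

#' Tally weak clues per resource name
#'
#' A weak firing is recorded whenever a weak-indicator term (verbs like
#' "use"/"ran", ambiguous heads like "interface"/"platform") occurs in the
#' same sentence within a 4-token window of a candidate. Tallies are
#' aggregated per normalized name over the whole document.
#'
#' @param candidates Candidate data.frame.
#' @param tokens POS-tagged sentence-split tokens.
#' @param lexicon Lexicon (weak-indicator list).
#' @param window Token window on each side (default 4).
#' @return data.frame(normalized_name, weak_count).
#' @export
tally_weak_clues <- function(candidates, tokens, lexicon, window = 4L) {
  counts <- integer(nrow(candidates))
  n <- nrow(tokens)
  for (ci in seq_len(nrow(candidates))) {
    lo <- max(1L, candidates$first_tok[ci] - window)
    hi <- min(n, candidates$last_tok[ci] + window)
    # window spans the candidate itself too, so an ambiguous head absorbed
    # into the noun run ("the FooTool platform") still counts
    idx <- seq(lo, hi)
    idx <- idx[tokens$sentence[idx] == candidates$sentence[ci]]
    counts[ci] <- sum(is_weak_indicator(lexicon, tokens$surface[idx]))
  }
  names_norm <- normalize_name(candidates$surface)
  agg <- tapply(counts, names_norm, sum)
  data.frame(normalized_name = names(agg), weak_count = as.integer(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Add document-wide weak evidence to local scores
#'
#' `final_score = local_score + weak_count(name) * weak_score`, applied to
#' every mention of that name.
#'
#' @param candidates Candidates with `local_score` (from
#'   [fire_local_clues()]).
#' @param tallies Output of [tally_weak_clues()].
#' @param config A [clue_config()].
#' @return `candidates` with a `final_score` column.
#' @export
apply_weak_scores <- function(candidates, tallies, config = clue_config()) {
  wk <- stats::setNames(tallies$weak_count, tallies$normalized_name)
  nm <- normalize_name(candidates$surface)
  extra <- ifelse(nm %in% names(wk), wk[nm], 0L)
  candidates$weak_count <- as.integer(extra)
  candidates$final_score <- candidates$local_score +
    as.numeric(extra) * config$Weak
  candidates
}

# keep the highest-scoring span among overlaps; ties -> longer span, then
# leftmost
resolve_overlaps <- function(cands) {
  if (nrow(cands) <= 1L) return(cands)
  ord <- order(-cands$final_score, -(cands$end - cands$start), cands$start)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(cands$start[kept] < cands$end[i] &
                 cands$end[kept] > cands$start[i])
    if (!clash) kept <- c(kept, i)
  }
  cands[sort(kept), , drop = FALSE]
}

#' Threshold candidates and propagate accepted names document-wide
#'
#' Accepts candidates whose final score strictly exceeds the threshold
#' (a score of exactly +5.00 under the defaults is rejected). Among
#' overlapping accepted spans the highest-scoring wins (ties go to the
#' longer span). Every verbatim, case-sensitive occurrence of an accepted
#' surface on token boundaries elsewhere in the document is then tagged as a
#' propagated mention carrying the accepting mention's score.
#'
#' @param candidates Candidates with `final_score`.
#' @param tokens Token table.
#' @param doc Document.
#' @param config A [clue_config()].
#' @return list with `mentions` (doc_id, start, end, surface, score,
#'   propagated) and `resources` (normalized_name, mention_count, max_score,
#'   spans list-column).
#' @export
threshold_and_propagate <- function(candidates, tokens, doc,
                                    config = clue_config()) {
  acc <- candidates[candidates$final_score > config$threshold, , drop = FALSE]
  acc <- resolve_overlaps(acc)
  mentions <- data.frame(doc_id = character(0), start = integer(0),
                         end = integer(0), surface = character(0),
                         score = numeric(0), propagated = logical(0),
                         stringsAsFactors = FALSE)
  resources <- data.frame(normalized_name = character(0),
                          mention_count = integer(0), max_score = numeric(0),
                          stringsAsFactors = FALSE)
  resources$spans <- list()
  if (nrow(acc) == 0L) {
    return(list(mentions = mentions, resources = resources))
  }
  mentions <- data.frame(doc_id = doc$doc_id, start = acc$start,
                         end = acc$end, surface = acc$surface,
                         score = acc$final_score, propagated = FALSE,
                         stringsAsFactors = FALSE)
  tok_starts <- tokens$start
  tok_ends <- tokens$end
  for (surf in unique(acc$surface)) {
    best <- max(acc$final_score[acc$surface == surf])
    occ <- gregexpr(surf, doc$text, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) next
    for (p in as.integer(occ)) {
      s0 <- p - 1L
      e0 <- s0 + nchar(surf, type = "chars")
      if (!(s0 %in% tok_starts) || !(e0 %in% tok_ends)) next
      if (any(mentions$start == s0 & mentions$end == e0)) next
      overlaps_accepted <- any(mentions$start < e0 & mentions$end > s0 &
                               !mentions$propagated)
      if (overlaps_accepted) next
      mentions <- rbind(mentions, data.frame(
        doc_id = doc$doc_id, start = s0, end = e0, surface = surf,
        score = best, propagated = TRUE, stringsAsFactors = FALSE))
    }
  }
  mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
  rownames(mentions) <- NULL
  nm <- normalize_name(mentions$surface)
  by <- split(seq_len(nrow(mentions)), nm)
  resources <- data.frame(
    normalized_name = names(by),
    mention_count = vapply(by, length, 0L),
    max_score = vapply(by, function(i) max(mentions$score[i]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  resources$spans <- lapply(by, function(i)
    mentions[i, c("start", "end"), drop = FALSE])
  list(mentions = mentions, resources = resources)
}

#' Annotate one document end-to-end
#'
#' Runs preprocessing, dictionary and noun-run candidate generation, local
#' clue scoring, cross-mention weak evidence, thresholding and propagation.
#'
#' @param doc A `bionerds_document`.
#' @param lexicon A `bionerds_lexicon` (default: the bundled fixture lists).
#' @param config A [clue_config()].
#' @param tagger POS tagger plug-in (default [heuristic_tagger()]).
#' @param max_run Maximum noun-run length in tokens.
#' @return list(mentions, resources, candidates) — `candidates` retains the
#'   full clue trace (`clues`, `local_score`, `weak_count`, `final_score`)
#'   for error analysis.
#' @export
annotate_document <- function(doc, lexicon = default_lexicon(),
                              config = clue_config(),
                              tagger = heuristic_tagger, max_run = 6L) {
  tokens <- preprocess_document(doc, tagger = tagger)
  cands <- extract_candidates(doc, tokens, lexicon, max_run = max_run)
  cands <- fire_local_clues(cands, tokens, doc, lexicon, config)
  tallies <- tally_weak_clues(cands, tokens, lexicon)
  cands <- apply_weak_scores(cands, tallies, config)
  res <- threshold_and_propagate(cands, tokens, doc, config)
  res$candidates <- cands
  res
}

#' Annotate a corpus
#'
#' @param corpus Named list of documents.
#' @inheritParams annotate_document
#' @param quiet Suppress per-document progress messages.
#' @return list(mentions = one standoff data.frame over all documents,
#'   doc_lists = data.frame(doc_id, name, mention_count)).
#' @export
annotate_corpus <- function(corpus, lexicon = default_lexicon(),
                            config = clue_config(),
                            tagger = heuristic_tagger, quiet = TRUE) {
  mention_list <- list()
  doc_rows <- list()
  for (doc in corpus) {
    res <- tryCatch(
      annotate_document(doc, lexicon, config, tagger),
      error = function(e) {
        warning("skipping document ", doc$doc_id, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    if (!quiet) {
      message(sprintf("%s: %d mentions, %d resources", doc$doc_id,
                      nrow(res$mentions), nrow(res$resources)))
    }
    mention_list[[doc$doc_id]] <- res$mentions
    if (nrow(res$resources)) {
      doc_rows[[doc$doc_id]] <- data.frame(
        doc_id = doc$doc_id, name = res$resources$normalized_name,
        mention_count = res$resources$mention_count,
        stringsAsFactors = FALSE)
    }
  }
  mentions <- if (length(mention_list)) {
    do.call(rbind, c(mention_list, list(make.row.names = FALSE)))
  } else {
    data.frame(doc_id = character(0), start = integer(0), end = integer(0),
               surface = character(0), score = numeric(0),
               propagated = logical(0), stringsAsFactors = FALSE)
  }
  doc_lists <- if (length(doc_rows)) {
    do.call(rbind, c(doc_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(doc_id = character(0), name = character(0),
               mention_count = integer(0), stringsAsFactors = FALSE)
  }
  list(mentions = mentions, doc_lists = doc_lists)
}

#' Write document-level resource lists as JSON
#'
#' One object per document: `doc_id -> [{name, count}, ...]`.
#'
#' @param doc_lists data.frame(doc_id, name, mention_count).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_doc_lists <- function(doc_lists, path) {
  by <- split(doc_lists[c("name", "mention_count")], doc_lists$doc_id)
  obj <- lapply(by, function(df) {
    data.frame(name = df$name, count = df$mention_count,
               stringsAsFactors = FALSE)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read document-level resource lists written by [write_doc_lists()]
#'
#' @param path JSON path.
#' @return data.frame(doc_id, name, mention_count).
#' @export
read_doc_lists <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- lapply(names(obj), function(id) {
    df <- obj[[id]]
    if (length(df) == 0L || nrow(df) == 0L) return(NULL)
    data.frame(doc_id = id, name = df$name,
               mention_count = as.integer(df$count),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), name = character(0),
                      mention_count = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
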