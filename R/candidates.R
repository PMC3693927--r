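# Candidate mention generation: noun-only token runs plus dictionary matches.

empty_candidates <- function() {
  data.frame(start = integer(0), end = integer(0), surface = character(0),
             sentence = integer(0), first_tok = integer(0),
             last_tok = integer(0), origin = character(0),
             good_head = logical(0), neg_head = logical(0),
             src_resource = logical(0), src_bioc = logical(0),
             stringsAsFactors = FALSE)
}

#' Extract noun-run candidates
#'
#' Every maximal run of consecutive noun tokens (`NN`, `NNS`, `NNP`, `NNPS`)
#' within a sentence becomes a candidate. Runs made up solely of positive
#' keywords are descriptors, not names, and are discarded. When a run's final
#' token is a positive keyword ("good head") or a blacklisted head, the
#' candidate is the run minus that head token, and the pending head is
#' recorded for the head clues. Runs longer than `max_run` tokens are
#' discarded as improbable names.
#'
#' @param doc Document.
#' @param tokens POS-tagged, sentence-split tokens.
#' @param lexicon A `bionerds_lexicon` (for keyword/blacklist heads).
#' @param max_run Maximum run length in tokens (default 6).
#' @return Candidate data.frame (`origin = "noun_run"`).
#' @export
extract_noun_runs <- function(doc, tokens, lexicon, max_run = 6L) {
  out <- empty_candidates()
  if (nrow(tokens) == 0L) return(out)
  runs <- rle(paste(tokens$is_noun, tokens$sentence))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  keep <- tokens$is_noun[idx_start]
  rows <- list()
  for (k in which(keep)) {
    a <- idx_start[k]; b <- idx_end[k]
    if (b - a + 1L > max_run) next
    surfaces <- tokens$surface[a:b]
    # a run that is verbatim a dictionary name keeps its trailing token even
    # when that token doubles as a keyword ("Gene Ontology")
    full_key <- squish(doc_slice(doc, tokens$start[a], tokens$end[b]))
    in_dict <- !is.null(lexicon$dict_env[[full_key]])
    kw <- is_pos_keyword(lexicon, surfaces)
    if (all(kw) && !in_dict) next
    gh <- FALSE; nh <- FALSE
    if (in_dict) {
      # no head stripping
    } else if (kw[length(kw)]) {
      gh <- TRUE
      b <- b - 1L
    } else if (is_neg_head(lexicon, surfaces[length(surfaces)]) &&
               length(surfaces) > 1L) {
      nh <- TRUE
      b <- b - 1L
    }
    if (b < a) next
    if (all(is_pos_keyword(lexicon, tokens$surface[a:b]))) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = tokens$start[a], end = tokens$end[b],
      surface = doc_slice(doc, tokens$start[a], tokens$end[b]),
      sentence = tokens$sentence[a], first_tok = a, last_tok = b,
      origin = "noun_run", good_head = gh, neg_head = nh,
      src_resource = FALSE, src_bioc = FALSE, stringsAsFactors = FALSE)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out
}

#' Merge noun-run and dictionary candidates
#'
#' Dictionary matches become candidates (`origin = "dictionary"`); a noun run
#' whose span coincides exactly with a dictionary match collapses into one
#' candidate (`origin = "both"`). Overlapping but unequal spans both survive
#' — resolution happens at threshold time.
#'
#' @param noun_runs Output of [extract_noun_runs()].
#' @param dict_matches Output of [dict_tag()].
#' @param tokens The token table (for sentence lookup).
#' @return Combined candidate data.frame ordered by start offset.
#' @export
merge_candidates <- function(noun_runs, dict_matches, tokens) {
  cands <- noun_runs
  if (nrow(dict_matches)) {
    for (i in seq_len(nrow(dict_matches))) {
      src <- dict_matches$sources[[i]]
      hit <- which(cands$start == dict_matches$start[i] &
                   cands$end == dict_matches$end[i])
      if (length(hit)) {
        cands$origin[hit[1L]] <- "both"
        cands$src_resource[hit[1L]] <- "resource_dict" %in% src
        cands$src_bioc[hit[1L]] <- "bioconductor" %in% src
      } else {
        cands <- rbind(cands, data.frame(
          start = dict_matches$start[i], end = dict_matches$end[i],
          surface = dict_matches$surface[i],
          sentence = tokens$sentence[dict_matches$first_tok[i]],
          first_tok = dict_matches$first_tok[i],
          last_tok = dict_matches$last_tok[i],
          origin = "dictionary", good_head = FALSE, neg_head = FALSE,
          src_resource = "resource_dict" %in% src,
          src_bioc = "bioconductor" %in% src, stringsAsFactors = FALSE))
      }
    }
  }
  cands <- cands[order(cands$start, cands$end), , drop = FALSE]
  rownames(cands) <- NULL
  cands
}

#' Generate all candidates for a document
#'
#' Convenience wrapper: [dict_tag()] + [extract_noun_runs()] +
#' [merge_candidates()].
#'
#' @inheritParams extract_noun_runs
#' @return Candidate data.frame.
#' @export
extract_candidates <- function(doc, tokens, lexicon, max_run = 6L) {
  merge_candidates(extract_noun_runs(doc, tokens, lexicon, max_run),
                   dict_tag(doc, tokens, lexicon), tokens)
}
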