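# Local clues: every pattern of the default score table fired per candidate,
# plus the compound-factor scoring rule. Each fire_* function returns a
# data.frame (cand = candidate row index, clue = clue type); the orchestrator
# collapses repeats (a clue type fires at most once per candidate), attaches
# score contributions from the configuration and computes the local score.

.title_separators <- c(":", "-", "–", "—")

#' Title clue
#'
#' Fires for a candidate that starts the title at position 0, is immediately
#' followed by a separator token (colon or dash), where the remainder of the
#' title contains at least one positive keyword (case-insensitively) — the
#' "NewTool: a program for ..." naming convention.
#'
#' @param candidates Candidate data.frame.
#' @param tokens POS-tagged sentence-split tokens.
#' @param doc Document.
#' @param lexicon Lexicon (for positive keywords).
#' @return data.frame(cand, clue).
#' @export
fire_title_clue <- function(candidates, tokens, doc, lexicon) {
  hits <- integer(0)
  title_toks <- which(tokens$sentence == 1L & tokens$start <
                        nchar(doc$title, type = "chars"))
  if (length(title_toks) && nzchar(doc$title)) {
    for (ci in seq_len(nrow(candidates))) {
      if (candidates$sentence[ci] != 1L || candidates$start[ci] != 0L) next
      nxt <- candidates$last_tok[ci] + 1L
      if (!(nxt %in% title_toks)) next
      if (!(tokens$surface[nxt] %in% .title_separators)) next
      rest <- title_toks[title_toks > nxt]
      if (any(is_pos_keyword(lexicon, tokens$surface[rest]))) {
        hits <- c(hits, ci)
      }
    }
  }
  data.frame(cand = hits, clue = rep("Title", length(hits)),
             stringsAsFactors = FALSE)
}

# Candidates chained into a comma/and/or list, in token order. Returns a list
# of integer vectors of candidate row indices (chains of length >= 1).
candidate_chains <- function(candidates, tokens) {
  chains <- list()
  for (s in unique(candidates$sentence)) {
    rows <- which(candidates$sentence == s &
                  candidates$origin %in% c("noun_run", "both"))
    rows <- rows[order(candidates$first_tok[rows])]
    if (!length(rows)) next
    cur <- rows[1L]
    for (k in seq_along(rows)[-1L]) {
      prev <- rows[k - 1L]; this <- rows[k]
      gap <- seq(candidates$last_tok[prev] + 1L,
                 length.out = candidates$first_tok[this] -
                   candidates$last_tok[prev] - 1L)
      sep_only <- length(gap) > 0L &&
        all(tolower(tokens$surface[gap]) %in% c(",", "or", "and", "/"))
      if (sep_only) {
        cur <- c(cur, this)
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- this
      }
    }
    chains[[length(chains) + 1L]] <- cur
  }
  chains
}

#' Enumeration and Hearst-pattern clues
#'
#' Hearst fires for every member of "<keyword-NP> such as X, Y or Z",
#' "<keyword-NP> including X, ..." and "X, Y and other <keyword-NP>"
#' constructions. Enum fires for every member of a comma/and/or list of
#' noun-only phrases when at least one member carries a dictionary match.
#' One candidate may receive both.
#'
#' @inheritParams fire_title_clue
#' @return data.frame(cand, clue).
#' @export
fire_list_clues <- function(candidates, tokens, doc, lexicon) {
  out <- list()
  chains <- candidate_chains(candidates, tokens)
  lower <- tolower(tokens$surface)
  n <- nrow(tokens)
  kw_tok <- is_pos_keyword(lexicon, tokens$surface) & tokens$is_noun
  for (chain in chains) {
    first <- min(candidates$first_tok[chain])
    last <- max(candidates$last_tok[chain])
    hearst <- FALSE
    # "<kw-NP> such as X" / "<kw-NP>, including X"
    lead <- first - 1L
    trigger_end <- NA_integer_
    if (lead >= 2L && lower[lead] == "as" && lower[lead - 1L] == "such") {
      trigger_end <- lead - 2L
    } else if (lead >= 1L && lower[lead] == "including") {
      trigger_end <- lead - 1L
    }
    if (!is.na(trigger_end) && trigger_end >= 1L) {
      j <- trigger_end
      if (lower[j] == ",") j <- j - 1L
      if (j >= 1L && kw_tok[j]) hearst <- TRUE
    }
    # "X, Y and other <kw-NP>"
    if (!hearst && last + 3L <= n &&
        lower[last + 1L] %in% c("and", "or") &&
        lower[last + 2L] == "other" && kw_tok[last + 3L]) {
      hearst <- TRUE
    }
    if (hearst) {
      out[[length(out) + 1L]] <- data.frame(cand = chain, clue = "Hearst",
                                            stringsAsFactors = FALSE)
    }
    if (length(chain) >= 2L &&
        any(candidates$origin[chain] %in% c("dictionary", "both"))) {
      out[[length(out) + 1L]] <- data.frame(cand = chain, clue = "Enum",
                                            stringsAsFactors = FALSE)
    }
  }
  # dictionary-only candidates can be Hearst/Enum members too: treat spans
  # equal to noun runs as already covered; remaining dictionary-origin
  # candidates join a chain when they share its exact span — skipped for
  # simplicity (overlapping spans are resolved at threshold time).
  if (length(out) == 0L) {
    return(data.frame(cand = integer(0), clue = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Good-head and negative-head clues
#'
#' GoodHead fires when the token immediately following the candidate (the
#' stripped head of its noun run, or the next token in the sentence) is a
#' positive keyword; NegativeHead fires likewise for blacklisted heads
#' ("FASTA format", "UPGMA algorithm").
#'
#' @inheritParams fire_title_clue
#' @return data.frame(cand, clue).
#' @export
fire_head_clues <- function(candidates, tokens, doc, lexicon) {
  out <- list()
  for (ci in seq_len(nrow(candidates))) {
    gh <- isTRUE(candidates$good_head[ci])
    nh <- isTRUE(candidates$neg_head[ci])
    nxt <- candidates$last_tok[ci] + 1L
    if (!gh && !nh && nxt <= nrow(tokens) &&
        tokens$sentence[nxt] == candidates$sentence[ci]) {
      s <- tokens$surface[nxt]
      if (is_pos_keyword(lexicon, s)) gh <- TRUE
      else if (is_neg_head(lexicon, s)) nh <- TRUE
    }
    if (gh) out[[length(out) + 1L]] <-
        data.frame(cand = ci, clue = "GoodHead", stringsAsFactors = FALSE)
    if (nh) out[[length(out) + 1L]] <-
        data.frame(cand = ci, clue = "NegativeHead", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(cand = integer(0), clue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.version_shape <- "^v?[0-9]+(\\.[0-9]+)*$"
.url_prefix <- "^(https?://|ftp://|www\\.)"

#' Version, reference and hyperlink clues
#'
#' Version: the next non-punctuation token in the sentence is a version-like
#' string (`2.0`, `v1.2.3`, `3`), optionally introduced by "v"/"ver"/
#' "version". Reference: within two tokens, a bracketed citation (`[3]`,
#' `[3,7]`) or a parenthesised "... et al ..." citation. HyperLink: within
#' three tokens, a token starting `http://`, `https://`, `ftp://` or `www.`.
#'
#' @inheritParams fire_title_clue
#' @return data.frame(cand, clue).
#' @export
fire_context_clues <- function(candidates, tokens, doc, lexicon) {
  out <- list()
  n <- nrow(tokens)
  add <- function(ci, clue) {
    out[[length(out) + 1L]] <<- data.frame(cand = ci, clue = clue,
                                           stringsAsFactors = FALSE)
  }
  for (ci in seq_len(nrow(candidates))) {
    sent <- candidates$sentence[ci]
    after <- seq(candidates$last_tok[ci] + 1L, length.out = 6L)
    after <- after[after <= n & tokens$sentence[after] == sent]
    if (!length(after)) next
    surf <- tokens$surface[after]
    # Version: first non-punctuation following token
    nonpunct <- which(grepl("[A-Za-z0-9]", surf))
    if (length(nonpunct)) {
      k <- nonpunct[1L]
      v <- surf[k]
      if (grepl(.version_shape, v) ||
          (tolower(v) %in% c("v", "ver", "version") && k < length(surf) &&
           grepl("^[0-9]+(\\.[0-9]+)*$", surf[k + 1L]))) {
        add(ci, "Version")
      }
    }
    # Reference within 2 tokens
    win2 <- utils::head(surf, 3L)
    br <- which(win2 == "[")
    if (length(br) && br[1L] < length(surf) &&
        grepl("^[0-9]+$", surf[br[1L] + 1L])) {
      add(ci, "Reference")
    } else if (any(win2 == "(")) {
      paren <- which(surf == "(")[1L]
      look <- surf[seq(paren + 1L, length.out = min(6L, length(surf) - paren))]
      if (length(look) >= 2L &&
          any(tolower(look) == "et") &&
          any(tolower(look) == "al")) {
        add(ci, "Reference")
      }
    }
    # HyperLink within 3 tokens
    if (any(grepl(.url_prefix, utils::head(surf, 4L)))) add(ci, "HyperLink")
  }
  if (length(out) == 0L) {
    return(data.frame(cand = integer(0), clue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# case class of one token: "upper", "mixed", "lower" or NA
token_case_class <- function(s) {
  letters_only <- gsub("[^A-Za-z]", "", s)
  if (!nzchar(letters_only)) return(NA_character_)
  if (!grepl("[a-z]", letters_only) && nchar(letters_only) >= 2L) {
    return("upper")
  }
  if (grepl("[a-z]", letters_only) && grepl("^.+[A-Z]", s)) return("mixed")
  if (!grepl("[A-Z]", letters_only)) return("lower")
  NA_character_
}

#' Orthographic and list-based negative clues
#'
#' Exactly one case clue per candidate: UpperCase (all caps, two or more
#' letters), MixedCase (both cases with an uppercase after the first
#' character) or LowerCase (all lowercase); multi-token candidates take the
#' majority token class, ties yield no case clue. DictionaryWord fires when
#' every token is a common English word (case-insensitive); KnownAcronym
#' when the candidate string is in the acronym list; PartialWord when the
#' candidate is flanked without whitespace by an alphanumeric character or a
#' `:digit` continuation (the `GO` in `GO:001234`); Bioconductor when the
#' candidate's dictionary sources include the Bioconductor list.
#'
#' @inheritParams fire_title_clue
#' @return data.frame(cand, clue).
#' @export
fire_orthographic_clues <- function(candidates, tokens, doc, lexicon) {
  out <- list()
  add <- function(ci, clue) {
    out[[length(out) + 1L]] <<- data.frame(cand = ci, clue = clue,
                                           stringsAsFactors = FALSE)
  }
  text <- doc$text
  nch <- doc$char_count
  for (ci in seq_len(nrow(candidates))) {
    toks <- seq(candidates$first_tok[ci], candidates$last_tok[ci])
    surf <- tokens$surface[toks]
    classes <- vapply(surf, token_case_class, "")
    tab <- table(factor(classes, levels = c("upper", "mixed", "lower")))
    if (sum(tab) > 0L) {
      top <- which(tab == max(tab) & tab > 0L)
      if (length(top) == 1L) {
        add(ci, c(upper = "UpperCase", mixed = "MixedCase",
                  lower = "LowerCase")[[names(tab)[top]]])
      }
    }
    if (all(tolower(surf) %in% lexicon$english) && length(surf) > 0L) {
      add(ci, "DictionaryWord")
    }
    if (in_acronyms(lexicon, candidates$surface[ci])) add(ci, "KnownAcronym")
    before <- if (candidates$start[ci] > 0L)
      substr(text, candidates$start[ci], candidates$start[ci]) else ""
    after1 <- if (candidates$end[ci] < nch)
      substr(text, candidates$end[ci] + 1L, candidates$end[ci] + 1L) else ""
    after2 <- if (candidates$end[ci] + 1L < nch)
      substr(text, candidates$end[ci] + 2L, candidates$end[ci] + 2L) else ""
    partial <- grepl("[A-Za-z0-9]", before) || grepl("[A-Za-z0-9]", after1) ||
      (after1 == ":" && grepl("[0-9]", after2))
    if (partial) add(ci, "PartialWord")
    if (isTRUE(candidates$src_bioc[ci])) add(ci, "Bioconductor")
  }
  if (length(out) == 0L) {
    return(data.frame(cand = integer(0), clue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Sum a candidate's clue events into its local score
#'
#' The score is the sum of all fired clue contributions plus the number of
#' distinct positive clue types fired multiplied by the compound factor.
#' Weak evidence is excluded here — it is aggregated across mentions by the
#' document-resolution stage.
#'
#' @param clues Character vector of fired clue types for one candidate
#'   (repeats collapse to one firing).
#' @param config A [clue_config()].
#' @return Numeric local score.
#' @export
score_mention <- function(clues, config = clue_config()) {
  clues <- unique(as.character(clues))
  bad <- setdiff(clues, .clue_types)
  if (length(bad)) stop("unknown clue types: ", paste(bad, collapse = ", "))
  base <- sum(vapply(clues, function(cl) config[[cl]], 0))
  n_pos <- sum(clues %in% .positive_clues)
  base + n_pos * config$CompoundFactor
}

#' Fire all local clues and score every candidate
#'
#' Adds a Dictionary clue event for candidates of dictionary origin, fires
#' all local clue families, collapses repeats, and attaches a `clues`
#' list-column plus a `local_score` column.
#'
#' @inheritParams fire_title_clue
#' @param config A [clue_config()].
#' @return `candidates` with `clues` (list of character vectors) and
#'   `local_score` columns.
#' @export
fire_local_clues <- function(candidates, tokens, doc, lexicon,
                             config = clue_config()) {
  events <- rbind(
    fire_title_clue(candidates, tokens, doc, lexicon),
    fire_list_clues(candidates, tokens, doc, lexicon),
    fire_head_clues(candidates, tokens, doc, lexicon),
    fire_context_clues(candidates, tokens, doc, lexicon),
    fire_orthographic_clues(candidates, tokens, doc, lexicon)
  )
  dict_ci <- which(candidates$origin %in% c("dictionary", "both"))
  if (length(dict_ci)) {
    events <- rbind(events, data.frame(cand = dict_ci, clue = "Dictionary",
                                       stringsAsFactors = FALSE))
  }
  clue_sets <- rep(list(character(0)), nrow(candidates))
  if (nrow(events)) {
    by_cand <- split(events$clue, events$cand)
    for (nm in names(by_cand)) {
      clue_sets[[as.integer(nm)]] <- unique(by_cand[[nm]])
    }
  }
  candidates$clues <- clue_sets
  candidates$local_score <- vapply(clue_sets, score_mention, 0,
                                   config = config)
  candidates
}
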