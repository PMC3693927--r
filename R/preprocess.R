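# Tokenization, sentence splitting and part-of-speech tagging.
#
# Offsets everywhere are 0-based, half-open, into the canonical document
# string (title + "\n" + body).

# Alternation order matters (PCRE is leftmost, first-alternative):
# URLs stay atomic, version-like digit strings ("2.0", "v1.2.3") stay atomic,
# then alphanumeric runs, then any single non-space punctuation character.
.token_regex <- paste(
  "(?:https?|ftp)://[^][:space:](),;\"'<>]+",
  "www\\.[^][:space:](),;\"'<>]+",
  "v?[0-9]+(?:\\.[0-9]+)+",
  "[A-Za-z0-9]+",
  "[^[:space:]A-Za-z0-9]",
  sep = "|")

.noun_tags <- c("NN", "NNS", "NNP", "NNPS")

#' Tokenize a document
#'
#' Splits on whitespace; punctuation characters become single-character
#' tokens, except dots inside version-like digit strings (`2.0`, `v1.2.3`)
#' which stay atomic, and URLs (`http://...`, `www....`) which are kept as
#' one token so link clues can test the token prefix. Alphanumeric runs split
#' at the alphanumeric/punctuation boundary, so the `GO` in `GO:001234`
#' becomes its own token. Hyphenated words split at the hyphen.
#'
#' @param x A `bionerds_document` or a character scalar.
#' @return data.frame with columns `surface`, `start`, `end` (0-based
#'   half-open), `pos` (NA until tagged), `is_noun`, `sentence` (NA until
#'   split).
#' @export
tokenize <- function(x) {
  text <- if (inherits(x, "bionerds_document")) x$text else as.character(x)
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), pos = character(0),
                      is_noun = logical(0), sentence = integer(0),
                      stringsAsFactors = FALSE)
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  surface <- substring(text, start + 1L, start + len)
  # a URL token must not swallow a trailing sentence period
  trail <- grepl("^(https?|ftp)://|^www\\.", surface) & grepl("\\.$", surface)
  while (any(trail)) {
    surface[trail] <- sub("\\.$", "", surface[trail])
    len[trail] <- len[trail] - 1L
    extra <- data.frame(surface = ".", start = start[trail] + len[trail],
                        end = start[trail] + len[trail] + 1L,
                        stringsAsFactors = FALSE)
    surface <- c(surface, extra$surface)
    start <- c(start, extra$start)
    len <- c(len, rep(1L, nrow(extra)))
    trail <- rep(FALSE, length(surface))
  }
  ord <- order(start)
  data.frame(surface = surface[ord], start = start[ord],
             end = start[ord] + len[ord], pos = NA_character_,
             is_noun = FALSE, sentence = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Split tokens into sentences
#'
#' The title (everything before the first newline of the canonical string) is
#' always its own sentence (index 1). In the body, a boundary is placed after
#' a `.`, `!` or `?` token when it is followed — across whitespace — by a
#' token starting with a capital letter, or at end of text. `ver. 2.0`
#' therefore does not split.
#'
#' @param tokens Output of [tokenize()].
#' @param doc The source `bionerds_document` (for the title length).
#' @return `tokens` with the `sentence` column filled (1-based).
#' @export
split_sentences <- function(tokens, doc) {
  n <- nrow(tokens)
  if (n == 0L) return(tokens)
  title_len <- nchar(doc$title, type = "chars")
  sent <- integer(n)
  in_title <- tokens$start < title_len
  sent[in_title] <- 1L
  cur <- if (any(in_title)) 2L else 1L
  body_idx <- which(!in_title)
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    sent[i] <- cur
    if (tokens$surface[i] %in% c(".", "!", "?")) {
      if (k == length(body_idx)) next
      nxt <- body_idx[k + 1L]
      gap <- tokens$start[nxt] > tokens$end[i]
      if (gap && grepl("^[A-Z\"([]", tokens$surface[nxt])) cur <- cur + 1L
    }
  }
  tokens$sentence <- sent
  tokens
}

# --- bundled closed-class word list for the heuristic tagger ----------------

.closed_class <- local({
  cls <- list(
    DT  = c("the", "a", "an", "this", "that", "these", "those", "each",
            "every", "some", "any", "no", "all", "both"),
    PRP = c("i", "we", "you", "he", "she", "it", "they", "them", "us", "him",
            "her", "me", "itself", "themselves"),
    IN  = c("in", "of", "on", "at", "by", "with", "from", "for", "to", "into",
            "onto", "over", "under", "between", "through", "within", "across",
            "against", "during", "as", "per", "via", "than", "after",
            "before", "without"),
    CC  = c("and", "or", "but", "nor"),
    MD  = c("will", "would", "can", "could", "may", "might", "should",
            "must", "shall"),
    VBD = c("was", "were", "did", "had", "used", "ran", "developed",
            "applied", "performed", "measured", "compared", "obtained",
            "showed", "found", "described", "implemented", "tested",
            "counted", "computed", "generated", "recorded", "repeated",
            "aligned", "analysed", "analyzed", "evaluated", "saw", "looked",
            "loaded", "fetched", "happened", "appeared", "reported",
            "presented", "built", "wrote", "made", "gave", "took"),
    VBP = c("use", "run", "develop", "apply", "perform", "measure",
            "compare", "obtain", "show", "find", "describe", "implement",
            "test", "count", "compute", "generate", "record", "do", "have",
            "are", "am", "provide", "provides", "uses", "runs", "contains",
            "contain", "require", "requires"),
    VBZ = c("is", "has", "does", "computes", "appears", "shows",
            "provides", "performs", "gives", "seems", "remains"),
    VB  = c("be", "been"),
    RB  = c("not", "also", "very", "only", "then", "however", "therefore",
            "widely", "extensively", "carefully", "twice", "here", "there",
            "again", "often", "still", "well", "today", "yesterday", "now",
            "later", "once", "briefly", "together"),
    JJ  = c("new", "novel", "quick", "fast", "available", "common", "large",
            "small", "free", "open", "other", "such", "several", "many",
            "most", "more", "main", "local", "global", "first", "second",
            "same", "different", "further", "public", "previous"),
    WDT = c("which", "what"),
    WP  = c("who", "whom")
  )
  tags <- rep(names(cls), lengths(cls))
  stats::setNames(tags, unlist(cls))
})

.noun_suffix_jj <- "(ous|ful|ive|ible|able|ic|ical)$"

#' Deterministic heuristic part-of-speech tagger
#'
#' The bundled fallback tagger: closed-class words from an internal list get
#' their class; punctuation tokens are tagged with their own surface;
#' numbers and version strings are `CD`; URLs are `URL`; tokens that are
#' ALL-CAPS, contain an internal capital, or mix letters and digits are
#' `NNP`; other capitalized tokens are `NNP`; remaining lowercase tokens are
#' tagged by suffix rules (`-ly` RB, `-ing` VBG, `-ed` VBN, adjectival
#' suffixes JJ) and default to `NN`/`NNS`.
#'
#' Satisfies the tagger plug-in contract: character vector of surfaces in,
#' equal-length character vector of Penn-style tags out.
#'
#' @param surfaces Character vector of token surfaces.
#' @return Character vector of tags.
#' @export
heuristic_tagger <- function(surfaces) {
  n <- length(surfaces)
  tags <- character(n)
  lower <- tolower(surfaces)
  for (i in seq_len(n)) {
    s <- surfaces[i]
    if (!grepl("[A-Za-z0-9]", s)) { tags[i] <- s; next }
    if (grepl("^(https?|ftp)://|^www\\.", s)) { tags[i] <- "URL"; next }
    if (grepl("^v?[0-9]+(\\.[0-9]+)*$", s)) { tags[i] <- "CD"; next }
    cc <- unname(.closed_class[lower[i]])
    if (!is.na(cc)) { tags[i] <- cc; next }
    has_upper_late <- grepl("^.+[A-Z]", s)
    all_caps <- grepl("^[A-Z0-9]+$", s) && grepl("[A-Z].*[A-Z]", s)
    mixed_alnum <- grepl("[A-Za-z]", s) && grepl("[0-9]", s)
    if (all_caps || has_upper_late || mixed_alnum || grepl("^[A-Z]", s)) {
      tags[i] <- "NNP"
      next
    }
    if (grepl("ly$", s)) { tags[i] <- "RB"; next }
    if (grepl("ing$", s)) { tags[i] <- "VBG"; next }
    if (grepl("ed$", s)) { tags[i] <- "VBN"; next }
    if (grepl(.noun_suffix_jj, s)) { tags[i] <- "JJ"; next }
    tags[i] <- if (grepl("s$", s) && nchar(s) > 3L) "NNS" else "NN"
  }
  tags
}

#' Part-of-speech tag tokens
#'
#' @param tokens Tokens (sentence-split or not).
#' @param tagger A function taking a character vector of surfaces and
#'   returning an equal-length character vector of tags. Defaults to the
#'   bundled [heuristic_tagger()].
#' @return `tokens` with `pos` and `is_noun` filled. `is_noun` is TRUE
#'   exactly for tags NN, NNS, NNP, NNPS.
#' @export
pos_tag <- function(tokens, tagger = heuristic_tagger) {
  if (nrow(tokens) == 0L) return(tokens)
  tags <- tagger(tokens$surface)
  if (length(tags) != nrow(tokens)) {
    stop("tagger must return one tag per token")
  }
  tokens$pos <- as.character(tags)
  tokens$is_noun <- tokens$pos %in% .noun_tags
  tokens
}

#' Full preprocessing pipeline for one document
#'
#' Tokenize, sentence-split and tag in one call.
#'
#' @inheritParams pos_tag
#' @param doc A `bionerds_document`.
#' @return Token data.frame with all columns filled.
#' @export
preprocess_document <- function(doc, tagger = heuristic_tagger) {
  pos_tag(split_sentences(tokenize(doc), doc), tagger = tagger)
}
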