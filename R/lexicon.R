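# The seven word lists the recogniser depends on, and the case-sensitive
# longest-match dictionary tagger.

.lexicon_sources <- c("resource_dict", "bioconductor", "english", "acronym",
                      "pos_keyword", "neg_head", "weak_indicator")

read_wordlist <- function(path, source) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(variant = character(0), canonical = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  variant <- vapply(parts, `[[`, "", 1L)
  canonical <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else p[[1L]], "")
  dup <- duplicated(variant)
  if (any(dup)) {
    warning(sprintf("%d duplicate entries in %s list dropped (%s)",
                    sum(dup), source,
                    paste(utils::head(unique(variant[dup]), 3), collapse = ", ")))
  }
  data.frame(variant = variant[!dup], canonical = canonical[!dup],
             source = source, stringsAsFactors = FALSE)
}

#' Load the recogniser's lexicon
#'
#' Seven one-entry-per-line lists: the resource dictionary (mandatory;
#' lines may be `variant<TAB>canonical`), Bioconductor package names, common
#' English words, known acronyms, positive keywords (`database`, `tool`,
#' `program`, ...), negative "blacklist" heads (`format`, `algorithm`, ...)
#' and weak indicators (`use`, `ran`, `platform`, ...). Resource and
#' Bioconductor lookups are case-sensitive; English-word lookups are
#' case-insensitive.
#'
#' @param resource_dict Path to the resource dictionary (mandatory).
#' @param bioconductor,english,acronyms,keywords,neg_heads,weak Optional
#'   paths; a missing list defaults to empty.
#' @return A `bionerds_lexicon`.
#' @export
load_lexicon <- function(resource_dict, bioconductor = NULL, english = NULL,
                         acronyms = NULL, keywords = NULL, neg_heads = NULL,
                         weak = NULL) {
  if (is.null(resource_dict) || !file.exists(resource_dict)) {
    stop("resource dictionary is mandatory and was not found: ",
         if (is.null(resource_dict)) "<missing>" else resource_dict)
  }
  load_opt <- function(path, source) {
    if (is.null(path)) {
      return(data.frame(variant = character(0), canonical = character(0),
                        source = character(0), stringsAsFactors = FALSE))
    }
    if (!file.exists(path)) {
      warning("lexicon file not found, using empty ", source, " list: ", path)
      return(data.frame(variant = character(0), canonical = character(0),
                        source = character(0), stringsAsFactors = FALSE))
    }
    read_wordlist(path, source)
  }
  entries <- rbind(
    read_wordlist(resource_dict, "resource_dict"),
    load_opt(bioconductor, "bioconductor"),
    load_opt(english, "english"),
    load_opt(acronyms, "acronym"),
    load_opt(keywords, "pos_keyword"),
    load_opt(neg_heads, "neg_head"),
    load_opt(weak, "weak_indicator")
  )
  new_lexicon(entries)
}

new_lexicon <- function(entries) {
  stopifnot(all(entries$source %in% .lexicon_sources))
  by <- split(entries, entries$source)
  get_set <- function(src) {
    e <- by[[src]]
    if (is.null(e)) character(0) else e$variant
  }
  dict <- rbind(by[["resource_dict"]], by[["bioconductor"]])
  # per-variant source sets and canonical names for the dictionary tagger
  dict_env <- new.env(parent = emptyenv(), size = max(16L, nrow(dict) %||% 16L))
  max_tok <- 1L
  if (!is.null(dict) && nrow(dict)) {
    for (i in seq_len(nrow(dict))) {
      v <- dict$variant[i]
      cur <- dict_env[[v]]
      if (is.null(cur)) {
        ntok <- nrow(tokenize(v))
        max_tok <- max(max_tok, ntok)
        dict_env[[v]] <- list(canonical = dict$canonical[i],
                              sources = dict$source[i], n_tokens = ntok)
      } else {
        cur$sources <- union(cur$sources, dict$source[i])
        dict_env[[v]] <- cur
      }
    }
  }
  structure(
    list(entries = entries,
         dict_env = dict_env,
         dict_max_tokens = max_tok,
         english = unique(tolower(get_set("english"))),
         acronym = unique(get_set("acronym")),
         pos_keyword = unique(tolower(get_set("pos_keyword"))),
         neg_head = unique(tolower(get_set("neg_head"))),
         weak_indicator = unique(tolower(get_set("weak_indicator")))),
    class = "bionerds_lexicon"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bionerds_lexicon <- function(x, ...) {
  tab <- table(factor(x$entries$source, levels = .lexicon_sources))
  cat("<lexicon>", paste(names(tab), as.integer(tab), sep = ":",
                         collapse = " "), "\n")
  invisible(x)
}

#' The bundled fixture lexicon
#'
#' Small drop-in lists shipped with the package (about 50 resource names,
#' 200 English words, 30 acronyms, plus keyword/blacklist/weak seeds).
#' Full-scale lists in the same formats can be swapped in via
#' [load_lexicon()].
#'
#' @return A `bionerds_lexicon`.
#' @export
default_lexicon <- function() {
  d <- system.file("extdata", "lexicons", package = "bionerds")
  load_lexicon(resource_dict = file.path(d, "resource_dict.tsv"),
               bioconductor = file.path(d, "bioconductor.txt"),
               english = file.path(d, "english.txt"),
               acronyms = file.path(d, "acronyms.txt"),
               keywords = file.path(d, "keywords.txt"),
               neg_heads = file.path(d, "neg_heads.txt"),
               weak = file.path(d, "weak.txt"))
}

# --- membership helpers -----------------------------------------------------

in_english <- function(lexicon, term) tolower(term) %in% lexicon$english
in_acronyms <- function(lexicon, term) term %in% lexicon$acronym

# keyword/blacklist membership with naive depluralization ("tools" -> "tool")
is_pos_keyword <- function(lexicon, term) {
  t <- tolower(term)
  t %in% lexicon$pos_keyword | sub("s$", "", t) %in% lexicon$pos_keyword
}
is_neg_head <- function(lexicon, term) {
  t <- tolower(term)
  t %in% lexicon$neg_head | sub("s$", "", t) %in% lexicon$neg_head
}
is_weak_indicator <- function(lexicon, term) {
  tolower(term) %in% lexicon$weak_indicator
}

#' Dictionary tagging: case-sensitive leftmost-longest match
#'
#' Scans the token stream left to right; at each position the longest
#' dictionary variant that matches (comparing the whitespace-collapsed
#' document slice, case-sensitively) wins, and scanning resumes after it, so
#' matches never overlap and always start and end on token boundaries.
#'
#' @param doc The source document.
#' @param tokens Tokenized document.
#' @param lexicon A `bionerds_lexicon`.
#' @param sources Dictionary sources to match against (default: the resource
#'   dictionary and Bioconductor list).
#' @return data.frame: start, end, surface, canonical, sources (list column
#'   of source tags), first_tok, last_tok.
#' @export
dict_tag <- function(doc, tokens, lexicon,
                     sources = c("resource_dict", "bioconductor")) {
  n <- nrow(tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    hit <- NULL
    jmax <- min(n, i + lexicon$dict_max_tokens - 1L)
    for (j in seq(jmax, i)) {
      if (!is.na(tokens$sentence[i]) && !is.na(tokens$sentence[j]) &&
          tokens$sentence[j] != tokens$sentence[i]) next
      key <- squish(doc_slice(doc, tokens$start[i], tokens$end[j]))
      e <- lexicon$dict_env[[key]]
      if (!is.null(e) && length(intersect(e$sources, sources))) {
        hit <- list(i = i, j = j, key = key, e = e)
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- data.frame(
        start = tokens$start[hit$i], end = tokens$end[hit$j],
        surface = doc_slice(doc, tokens$start[hit$i], tokens$end[hit$j]),
        canonical = hit$e$canonical, first_tok = hit$i, last_tok = hit$j,
        stringsAsFactors = FALSE)
      out[[length(out)]]$sources <- list(intersect(hit$e$sources, sources))
      i <- hit$j + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      surface = character(0), canonical = character(0),
                      first_tok = integer(0), last_tok = integer(0),
                      sources = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
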