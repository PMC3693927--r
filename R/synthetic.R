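# Deterministic synthetic corpus generator: articles with resource names
# planted in clue-bearing contexts (title pattern, Hearst lists, version
# numbers, citations, URLs, weak verbs) plus English-word / acronym /
# identifier distractors, with gold annotations and metadata.

.default_names <- function() {
  data.frame(
    name = c("BLAST", "MUMmer", "Vmatch", "Gene Ontology", "ClustalW",
             "FooTool", "SpliceMax", "GenoScan", "MapRight", "NetWeaver"),
    in_dict = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

.default_distractors <- function() {
  data.frame(
    kind = c("english", "english", "acronym", "acronym", "identifier"),
    item = c("analysis", "comparison", "PCR", "DNA", "GO"),
    stringsAsFactors = FALSE)
}

#' Specification for a synthetic fixture corpus
#'
#' The seed fully determines the output. Every planted name appears in at
#' least one strong-clue context (title, Hearst list, version + citation, or
#' version + URL); `weak_n` weak-verb sentences per document add
#' cross-mention evidence.
#'
#' @param seed Integer RNG seed.
#' @param n_documents Number of documents.
#' @param names data.frame(name, in_dict): resources to plant. `in_dict`
#'   marks names present in the bundled resource dictionary (used to pick
#'   Hearst partners).
#' @param distractors data.frame(kind, item) of English-word, acronym and
#'   identifier-prefix distractors to weave in.
#' @param years,journals Values stamped into the metadata (cycled).
#' @param weak_n Weak-context sentences per document.
#' @return list of class `bionerds_fixture_spec`.
#' @export
fixture_spec <- function(seed = 101L, n_documents = 20L,
                         names = .default_names(),
                         distractors = .default_distractors(),
                         years = 2001:2011,
                         journals = c("journal_a", "journal_b"),
                         weak_n = 2L) {
  if (nrow(names) == 0L) stop("at least one planted name is required")
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 names = names, distractors = distractors,
                 years = as.integer(years), journals = journals,
                 weak_n = as.integer(weak_n)),
            class = "bionerds_fixture_spec")
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.recipes <- c("title", "hearst", "version_ref", "url")

# all token-boundary occurrences of `name` in a document -> standoff rows
find_plant_spans <- function(doc, name) {
  tokens <- tokenize(doc)
  occ <- gregexpr(name, doc$text, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) return(NULL)
  rows <- list()
  for (p in as.integer(occ)) {
    s0 <- p - 1L
    e0 <- s0 + nchar(name, type = "chars")
    if ((s0 %in% tokens$start) && (e0 %in% tokens$end)) {
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc$doc_id, start = s0, end = e0, surface = name,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Generate a synthetic corpus with gold annotations
#'
#' Each document is assembled from sentence templates around one primary
#' planted name (recipes cycle through title pattern, Hearst list, version +
#' citation, version + URL), with weak-verb sentences and distractor
#' sentences mixed in. Gold annotations mark every token-boundary occurrence
#' of each planted name in each document.
#'
#' @param spec A [fixture_spec()].
#' @return list(documents = named list of documents, gold = standoff
#'   data.frame, metadata = data.frame(doc_id, journal, year), spec).
#' @export
generate_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "bionerds_fixture_spec"))
  with_local_seed(spec$seed, {
    kws <- c("program", "database", "tool", "package")
    topics <- c("sequence analysis", "read mapping", "gene annotation",
                "data processing")
    vers <- c("2.0", "1.2", "3.0", "2.1")
    dict_names <- spec$names$name[spec$names$in_dict]
    distractor_sentences <- c(
      "The analysis was performed carefully.",
      "The comparison was repeated twice.",
      "The PCR was measured twice.",
      "The DNA samples were measured twice.",
      "The sample identifier GO:001234 was counted.")
    weak_templates <- c("We used %s again for this step.",
                        "We ran %s on the samples.",
                        "We used %s to process the data.")
    docs <- vector("list", spec$n_documents)
    gold <- list()
    meta <- list()
    for (i in seq_len(spec$n_documents)) {
      doc_id <- sprintf("doc%03d", i)
      primary <- spec$names$name[((i - 1L) %% nrow(spec$names)) + 1L]
      recipe <- .recipes[((i - 1L) %% length(.recipes)) + 1L]
      kw <- sample(kws, 1L)
      topic <- sample(topics, 1L)
      ver <- sample(vers, 1L)
      refn <- sample(1:30, 1L)
      planted <- primary
      if (recipe == "title") {
        title <- sprintf("%s: a %s for %s", primary, kw, topic)
        body1 <- sprintf("We used %s %s in the main workflow.", primary, ver)
      } else if (recipe == "hearst") {
        partner <- sample(setdiff(dict_names, primary), 1L)
        planted <- c(planted, partner)
        title <- sprintf("A study of %s", topic)
        body1 <- sprintf("Tools such as %s or %s were applied to the data.",
                         primary, partner)
      } else if (recipe == "version_ref") {
        title <- sprintf("A study of %s", topic)
        body1 <- sprintf("We ran %s %s [%d] to compute the results.",
                         primary, ver, refn)
      } else {
        title <- sprintf("A study of %s", topic)
        body1 <- sprintf("We used %s %s ( http://example.org/%s ) during processing.",
                         primary, ver, tolower(gsub("[^A-Za-z0-9]", "", primary)))
      }
      weak_sents <- character(0)
      if (spec$weak_n > 0L) {
        weak_sents <- sprintf(
          weak_templates[((seq_len(spec$weak_n) - 1L) %%
                            length(weak_templates)) + 1L], primary)
      }
      distr <- sample(distractor_sentences, 2L)
      body <- paste(c(body1, weak_sents, distr), collapse = " ")
      doc <- document(doc_id, title = title, body = body,
                      year = spec$years[((i - 1L) %% length(spec$years)) + 1L],
                      journal = spec$journals[((i - 1L) %%
                                                 length(spec$journals)) + 1L])
      docs[[i]] <- doc
      for (nm in planted) {
        g <- find_plant_spans(doc, nm)
        if (!is.null(g)) gold[[length(gold) + 1L]] <- g
      }
      meta[[i]] <- data.frame(doc_id = doc_id, journal = doc$journal,
                              year = doc$year, stringsAsFactors = FALSE)
    }
    names(docs) <- vapply(docs, `[[`, "", "doc_id")
    gold <- do.call(rbind, c(gold, list(make.row.names = FALSE)))
    gold <- gold[order(gold$doc_id, gold$start), , drop = FALSE]
    rownames(gold) <- NULL
    list(documents = docs, gold = gold,
         metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         spec = spec)
  })
}

#' Write a generated corpus to disk
#'
#' Plain-text documents (`<doc_id>.txt`, first line = title), `gold.tsv`
#' standoff annotations and `metadata.csv`.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus$documents) {
    writeLines(c(doc$title, doc$body),
               file.path(dir, paste0(doc$doc_id, ".txt")))
  }
  write_standoff(corpus$gold, file.path(dir, "gold.tsv"))
  utils::write.csv(corpus$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
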