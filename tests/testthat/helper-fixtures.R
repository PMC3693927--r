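# Shared helpers: a tiny in-code lexicon and document builders so tests do
# not depend on the bundled fixture lists unless they say so.

test_lexicon <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_list <- function(lines, name) {
    path <- file.path(dir, name)
    writeLines(lines, path)
    path
  }
  load_lexicon(
    resource_dict = write_list(
      c("BLAST", "MUMmer", "Vmatch", "Gene Ontology\tGene Ontology",
        "ClustalW", "GenBank", "R"), "dict.tsv"),
    bioconductor = write_list(c("affy", "limma", "graph"), "bioc.txt"),
    english = write_list(
      c("analysis", "the", "a", "results", "data", "graph", "tool",
        "database", "sequence", "gene", "program", "study", "fox",
        "quick", "format", "terms", "widgets", "read"), "english.txt"),
    acronyms = write_list(c("PCR", "DNA", "GO", "ROC"), "acr.txt"),
    keywords = write_list(
      c("database", "ontology", "web service", "tool", "program",
        "software", "package", "server"), "kw.txt"),
    neg_heads = write_list(
      c("format", "file", "algorithm", "method", "language", "identifier",
        "operating system"), "neg.txt"),
    weak = write_list(
      c("record", "alignment", "develop", "ran", "use", "used", "uses",
        "using", "interface", "platform", "run", "runs"), "weak.txt"))
}

# document + preprocessed tokens in one go
prep_doc <- function(title, body, doc_id = "d1") {
  doc <- document(doc_id, title, body)
  list(doc = doc, tokens = preprocess_document(doc))
}

# full local pipeline up to scored candidates
scored_candidates <- function(title, body, lexicon,
                              config = clue_config()) {
  p <- prep_doc(title, body)
  cands <- extract_candidates(p$doc, p$tokens, lexicon)
  cands <- fire_local_clues(cands, p$tokens, p$doc, lexicon, config)
  tallies <- tally_weak_clues(cands, p$tokens, lexicon)
  list(doc = p$doc, tokens = p$tokens,
       candidates = apply_weak_scores(cands, tallies, config))
}

# independent brute-force oracle: re-sum a clue set against the default
# score table, counting distinct positive types for the compound factor
oracle_score <- function(clues, config = clue_config()) {
  table1 <- c(Dictionary = 5.5, Title = 4, Enum = 3, Hearst = 4,
              GoodHead = 2, Version = 3, Reference = 1, HyperLink = 1.5,
              MixedCase = 1, UpperCase = 0.5, Bioconductor = -1.75,
              DictionaryWord = -4, KnownAcronym = -15, NegativeHead = -15,
              LowerCase = -1, PartialWord = -15)
  clues <- unique(clues)
  positives <- c("Dictionary", "Title", "Enum", "Hearst", "GoodHead",
                 "Version", "Reference", "HyperLink", "MixedCase",
                 "UpperCase")
  scores <- stats::setNames(
    vapply(names(table1), function(cl) config[[cl]], 0), names(table1))
  sum(scores[clues]) + sum(clues %in% positives) * config$CompoundFactor
}
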