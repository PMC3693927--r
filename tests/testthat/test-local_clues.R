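# helper: clue set of the candidate with a given surface
clues_of <- function(sc, surface) {
  row <- which(sc$candidates$surface == surface)
  expect_length(row, 1L)
  sc$candidates$clues[[row]]
}

test_that("title clue needs position 0, a separator, and a keyword in the remainder", {
  lex <- test_lexicon()
  sc <- scored_candidates("FooTool: a database of widgets", "Body text.", lex)
  expect_true("Title" %in% clues_of(sc, "FooTool"))

  sc2 <- scored_candidates("A survey of tools", "Body.", lex)
  expect_false(any(vapply(sc2$candidates$clues, function(cl)
    "Title" %in% cl, TRUE)))

  # no keyword after the separator -> no title clue
  sc3 <- scored_candidates("FooTool: fast widget counting", "Body.", lex)
  expect_false("Title" %in% clues_of(sc3, "FooTool"))
})

test_that("Hearst and Enum fire on list members and may stack", {
  lex <- test_lexicon()
  sc <- scored_candidates("T", "tools such as MUMmer or Vmatch were applied.",
                          lex)
  for (s in c("MUMmer", "Vmatch")) {
    expect_true(all(c("Hearst", "Enum") %in% clues_of(sc, s)), info = s)
  }
  # list without any dictionary member -> no Enum
  sc2 <- scored_candidates("T", "we saw Apples, Pears and Oranges today.", lex)
  expect_false(any(vapply(sc2$candidates$clues, function(cl)
    "Enum" %in% cl, TRUE)))
  # one dictionary member qualifies the whole list
  sc3 <- scored_candidates("T", "we compared Xalpha, BLAST and Zbeta here.", lex)
  for (s in c("Xalpha", "BLAST", "Zbeta")) {
    expect_true("Enum" %in% clues_of(sc3, s), info = s)
  }
})

test_that("good and negative heads fire from following keyword/blacklist tokens", {
  lex <- test_lexicon()
  sc <- scored_candidates("T", "The PolyFreq program was used.", lex)
  expect_true("GoodHead" %in% clues_of(sc, "PolyFreq"))

  sc2 <- scored_candidates("T", "the FASTA format was described.", lex)
  expect_true("NegativeHead" %in% clues_of(sc2, "FASTA"))

  sc3 <- scored_candidates("T", "BLAST results were shown.", lex)
  cl <- clues_of(sc3, "BLAST")
  expect_false(any(c("GoodHead", "NegativeHead") %in% cl))
})

test_that("version, reference and hyperlink context clues fire within their windows", {
  lex <- test_lexicon()
  sc <- scored_candidates("T", "We used MUMmer 3.0 today.", lex)
  expect_true("Version" %in% clues_of(sc, "MUMmer"))

  sc2 <- scored_candidates("T", "We used BLAST [3] today.", lex)
  expect_true("Reference" %in% clues_of(sc2, "BLAST"))

  sc3 <- scored_candidates("T", "FooTool ( http://foo.org ) was used.", lex)
  expect_true("HyperLink" %in% clues_of(sc3, "FooTool"))

  # far-away link does not fire
  sc4 <- scored_candidates("T", "FooTool was later fetched from from http://foo.org today.", lex)
  expect_false("HyperLink" %in% clues_of(sc4, "FooTool"))
})

test_that("orthographic and list-based negative clues fire as specified", {
  lex <- test_lexicon()
  sc <- scored_candidates("T", "We used BLAST today.", lex)
  expect_true("UpperCase" %in% clues_of(sc, "BLAST"))

  # the GO of GO:001234 is a partial word
  sc2 <- scored_candidates("T", "We looked at GO:001234 briefly.", lex)
  go_rows <- grep("GO", sc2$candidates$surface)
  expect_true(any(vapply(sc2$candidates$clues[go_rows], function(cl)
    "PartialWord" %in% cl, TRUE)))

  # English word: DictionaryWord + LowerCase -> local -5
  sc3 <- scored_candidates("T", "some analysis happened there.", lex)
  row <- which(sc3$candidates$surface == "analysis")
  expect_setequal(sc3$candidates$clues[[row]],
                  c("DictionaryWord", "LowerCase"))
  expect_equal(sc3$candidates$local_score[row], -5)

  # acronym list
  sc4 <- scored_candidates("T", "some PCR happened there.", lex)
  expect_true("KnownAcronym" %in% clues_of(sc4, "PCR"))

  # at most one case clue per candidate (property over generated cases)
  set.seed(3)
  words <- c("BLAST", "FooTool", "analysis", "Vmatch", "MUMmer", "data",
             "GenBank", "R")
  for (rep in 1:10) {
    body <- paste("We saw", paste(sample(words, 4), collapse = " and "),
                  "today.")
    sc5 <- scored_candidates("T", body, lex)
    for (cl in sc5$candidates$clues) {
      expect_lte(sum(c("UpperCase", "MixedCase", "LowerCase") %in% cl), 1L)
    }
  }
})

test_that("Bioconductor dictionary entries take the extra negative score", {
  lex <- test_lexicon()
  sc <- scored_candidates("T", "we loaded affy for this.", lex)
  row <- which(sc$candidates$surface == "affy")
  expect_true(all(c("Dictionary", "Bioconductor", "LowerCase") %in%
                    sc$candidates$clues[[row]]))
  # 5.50 - 1.75 - 1.00 + 1 x 0.50 = 3.25, below the +5.00 threshold
  expect_equal(sc$candidates$local_score[row], 3.25)
  expect_lt(sc$candidates$final_score[row], clue_config()$threshold)
})

test_that("score_mention equals the independent clue-sum oracle on random subsets", {
  cfg <- clue_config()
  all_clues <- c("Dictionary", "Title", "Enum", "Hearst", "GoodHead",
                 "Version", "Reference", "HyperLink", "MixedCase",
                 "UpperCase", "Bioconductor", "DictionaryWord",
                 "KnownAcronym", "NegativeHead", "LowerCase", "PartialWord")
  set.seed(42)
  for (rep in 1:200) {
    clues <- sample(all_clues, sample(0:8, 1))
    expect_equal(score_mention(clues, cfg), oracle_score(clues, cfg))
  }
  # frozen spot values computed with the oracle
  expect_equal(score_mention("Dictionary", cfg), 6.0)
  expect_equal(score_mention(character(0), cfg), 0.0)
  expect_equal(score_mention(c("Dictionary", "Bioconductor", "LowerCase"),
                             cfg), 3.25)
})

test_that("scores are monotone in added clues", {
  cfg <- clue_config()
  positives <- c("Title", "Enum", "Hearst", "GoodHead", "Version",
                 "Reference", "HyperLink", "MixedCase", "UpperCase")
  negatives <- c("Bioconductor", "DictionaryWord", "KnownAcronym",
                 "NegativeHead", "LowerCase", "PartialWord")
  set.seed(9)
  for (rep in 1:50) {
    base <- sample(c(positives, negatives), sample(0:5, 1))
    s0 <- score_mention(base, cfg)
    extra_pos <- setdiff(positives, base)
    extra_neg <- setdiff(negatives, base)
    if (length(extra_pos)) {
      expect_gte(score_mention(c(base, sample(extra_pos, 1)), cfg), s0)
    }
    if (length(extra_neg)) {
      expect_lte(score_mention(c(base, sample(extra_neg, 1)), cfg), s0)
    }
  }
})

test_that("an acronym-only candidate cannot reach the threshold with modest weak evidence", {
  cfg <- clue_config()
  base <- score_mention("KnownAcronym", cfg)
  for (k in 0:19) expect_lte(base + k * cfg$Weak, cfg$threshold)
})
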