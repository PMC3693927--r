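test_that("name normalization collapses whitespace and dashes, preserves case", {
  expect_equal(normalize_name("Gene  Ontology"), "Gene Ontology")
  expect_equal(normalize_name("Clustal-W"), "Clustal W")
  expect_equal(normalize_name("BLAST"), "BLAST")
  expect_equal(normalize_name("  Foo – Bar  "), "Foo Bar")
})

test_that("weak clues tally per name across the whole document", {
  lex <- test_lexicon()
  sc <- scored_candidates(
    "A title", "We used FooTool. We used FooTool. We used FooTool.", lex)
  tallies <- tally_weak_clues(sc$candidates, sc$tokens, lex)
  expect_equal(tallies$weak_count[tallies$normalized_name == "FooTool"], 3L)

  # ambiguous head counts as a weak firing
  sc2 <- scored_candidates("A title", "the FooTool platform crashed.", lex)
  t2 <- tally_weak_clues(sc2$candidates, sc2$tokens, lex)
  expect_equal(t2$weak_count[grepl("FooTool", t2$normalized_name)], 1L)

  # no weak terms -> all tallies zero
  sc3 <- scored_candidates("A title", "the BLAST output appeared.", lex)
  t3 <- tally_weak_clues(sc3$candidates, sc3$tokens, lex)
  expect_true(all(t3$weak_count == 0L))
})

test_that("weak scores add per mention: local + weak_count * 0.50", {
  cfg <- clue_config()
  cands <- data.frame(surface = c("FooTool", "FooTool", "Other"),
                      local_score = c(4.25, 1.0, 2.0),
                      stringsAsFactors = FALSE)
  tallies <- data.frame(normalized_name = c("FooTool", "Other"),
                        weak_count = c(3L, 0L), stringsAsFactors = FALSE)
  out <- apply_weak_scores(cands, tallies, cfg)
  expect_equal(out$final_score, c(4.25 + 1.5, 1.0 + 1.5, 2.0))
  expect_gt(out$final_score[1], cfg$threshold)
})

test_that("threshold is strict and propagation tags every verbatim occurrence", {
  lex <- test_lexicon()
  doc <- document("d1", "FooTool: a database of widgets",
                  "FooTool computes widgets. Later FooTool appeared again.")
  res <- annotate_document(doc, lex)
  foo <- res$resources[res$resources$normalized_name == "FooTool", ]
  # title mention accepted; 2 more verbatim occurrences propagated
  expect_equal(foo$mention_count, 3L)
  expect_equal(sum(!res$mentions$propagated[res$mentions$surface == "FooTool"]), 1L)
  expect_equal(sum(res$mentions$propagated), 2L)
  # propagated mentions carry the accepting mention's score
  expect_true(all(res$mentions$score == max(res$mentions$score)))

  # a candidate at exactly the threshold is rejected ("needed to exceed")
  cfg <- clue_config()
  cands <- data.frame(start = 0L, end = 3L, surface = "Foo",
                      final_score = cfg$threshold, stringsAsFactors = FALSE)
  toks <- pos_tag(tokenize("Foo"))
  d2 <- document("d2", "Foo", "")
  out <- threshold_and_propagate(cands, toks, d2, cfg)
  expect_equal(nrow(out$mentions), 0L)
  expect_equal(nrow(out$resources), 0L)
})

test_that("propagation is case-sensitive and respects token boundaries", {
  lex <- test_lexicon()
  doc <- document("d1", "FooTool: a database of widgets",
                  "footool is different and FooToolKit is not FooTool.")
  res <- annotate_document(doc, lex)
  surfs <- res$mentions$surface
  starts <- res$mentions$start
  # lowercase variant and embedded occurrence are not tagged
  expect_false(any(doc_slice(doc, starts, starts + 7) == "footool"))
  for (i in seq_along(surfs)) {
    expect_equal(doc_slice(doc, res$mentions$start[i], res$mentions$end[i]),
                 surfs[i])
  }
  # the embedded "FooTool" inside "FooToolKit" must not be a mention
  kit_start <- regexpr("FooToolKit", doc$text, fixed = TRUE)[[1]] - 1L
  expect_false(any(res$mentions$start == kit_start & res$mentions$end == kit_start + 7L))
})

test_that("raising the threshold never increases the resource list (monotone filter)", {
  lex <- test_lexicon()
  doc <- generate_corpus(fixture_spec(seed = 4, n_documents = 3))$documents[[1]]
  sizes <- vapply(c(0, 3, 5, 8, 12, 100), function(th) {
    nrow(annotate_document(doc, lex, clue_config(threshold = th))$resources)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("propagation output is a superset of accepted candidates", {
  lex <- test_lexicon()
  corp <- generate_corpus(fixture_spec(seed = 8, n_documents = 6))
  cfg <- clue_config()
  for (doc in corp$documents) {
    tokens <- preprocess_document(doc)
    cands <- fire_local_clues(extract_candidates(doc, tokens, lex),
                              tokens, doc, lex, cfg)
    cands <- apply_weak_scores(cands, tally_weak_clues(cands, tokens, lex),
                               cfg)
    res <- threshold_and_propagate(cands, tokens, doc, cfg)
    acc <- res$mentions[!res$mentions$propagated, ]
    keys <- paste(res$mentions$start, res$mentions$end)
    expect_true(all(paste(acc$start, acc$end) %in% keys))
    # every resource has one mention whose pre-propagation score passed
    for (r in seq_len(nrow(res$resources))) {
      expect_gt(res$resources$max_score[r], cfg$threshold)
    }
  }
})

test_that("document-level JSON lists round-trip", {
  dl <- data.frame(doc_id = c("d1", "d1", "d2"),
                   name = c("BLAST", "FooTool", "BLAST"),
                   mention_count = c(2L, 1L, 4L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_doc_lists(dl, path)
  back <- read_doc_lists(path)
  back <- back[order(back$doc_id, back$name), ]
  rownames(back) <- NULL
  expect_equal(back, dl[order(dl$doc_id, dl$name), ], ignore_attr = TRUE)
})
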