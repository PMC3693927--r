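---
title: "Recognising database and software names by clue scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising database and software names by clue scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionerds)
```

## The problem

Bioinformatics runs on a sprawling, fast-changing inventory of databases and
software — the "resourceome". Knowing which resources a paper actually used
matters for cataloguing tools, tracking adoption trends, and reconstructing
computational methods, but resource names are short, ambiguous, and coined
faster than any curated dictionary can follow (`analysis`, `Network`, `tRNA`
and many Bioconductor package names are all legitimate resource names *and*
ordinary technical vocabulary). `bionerds` implements a rule-based,
score-driven named-entity recogniser for such names in full-text articles,
together with the evaluation framework and corpus-survey statistics used to
study resource usage over time.

## The recognition model

Each document is tokenized, sentence-split and part-of-speech tagged, then
candidate mentions are proposed from two sources:

1. a **case-sensitive dictionary** of known resource names (leftmost-longest
   match on token boundaries), and
2. **noun-only token runs** — maximal sequences of noun tokens, since resource
   names are typically contiguous noun sequences. A run ending in a positive
   keyword (`program`, `database`, ...) sheds that descriptor head and
   remembers it as head evidence, unless the full run is itself a dictionary
   name (`Gene Ontology`).

Every candidate accumulates **clue events**, each worth a fixed score:

| clue | score | fires when |
|---|---|---|
| Dictionary | +5.50 | span matches the resource dictionary |
| Title | +4.00 | candidate opens the title, followed by `:`/dash, keyword in the remainder |
| Hearst | +4.00 | member of "*tools such as X or Y*", "*... including X*", "*X and other tools*" |
| Enum | +3.00 | member of a noun-phrase list with ≥ 1 dictionary member |
| GoodHead | +2.00 | followed by a positive keyword head |
| Version | +3.00 | next non-punctuation token is version-shaped (`2.0`, `v1.2.3`) |
| HyperLink | +1.50 | URL token within 3 tokens |
| Reference | +1.00 | bracketed citation within 2 tokens |
| MixedCase / UpperCase | +1.00 / +0.50 | orthography of the candidate |
| Bioconductor | −1.75 | name from the Bioconductor list (often homonymic with concepts) |
| DictionaryWord | −4.00 | every token is a common English word |
| LowerCase | −1.00 | all-lowercase candidate |
| KnownAcronym / NegativeHead / PartialWord | −15.00 | known bio-acronym; blacklisted head (`format`, `algorithm`); sub-token match (the `GO` of `GO:001234`) |

The local score is the sum of fired clue scores plus the number of *distinct
positive clue types* × the compound factor (+0.50). Weak contextual evidence
(verbs like *use*, *ran*; ambiguous heads like *interface*, *platform*) is too
unreliable per mention, so it is pooled: the number of weak firings across all
of a name's candidate mentions in the document, times the weak score (+0.50),
is added to *every* mention of that name. A candidate is accepted when its
final score **strictly exceeds** the threshold (+5.00 by default — a mention
scoring exactly 5.00 is rejected). Accepted surfaces are then **propagated**:
every verbatim, case-sensitive occurrence on token boundaries elsewhere in
the document is tagged too, which is what rescues the many bare repeat
mentions in tool-focused papers. The per-document output is a mention table
and a resource list with mention counts.

All scores, the compound factor, the weak score and the threshold live in
[clue_config()] and can be overridden from a flat `key = value` file; the
defaults reproduce the score table above exactly.

```{r}
cfg <- clue_config()
c(threshold = cfg$threshold, Dictionary = cfg$Dictionary, Weak = cfg$Weak)
```

## A worked example

```{r}
doc <- document("demo", "FooTool: a database of widgets",
                "We used FooTool 2.0 [3] here. Tools such as MUMmer or Vmatch were applied.")
res <- annotate_document(doc)
res$candidates[res$candidates$final_score > 5,
               c("surface", "origin", "local_score", "weak_count", "final_score")]
res$resources[, c("normalized_name", "mention_count", "max_score")]
```

`FooTool` is unknown to the dictionary but passes on the title pattern plus
mixed case (4.00 + 1.00 + 2 × 0.50 = 6.00) and again on version + citation
evidence; `MUMmer` (dictionary + Hearst + Enum) and `Vmatch` (Hearst + Enum
alone) pass from the list context.

## Design choices where the design was open

* **POS tagging is a plug-in contract.** Any function mapping token surfaces
  to Penn-style tags can be injected; the bundled deterministic heuristic
  (closed-class lists, orthographic rules, suffix rules) keeps the package
  self-contained and reproducible with no model downloads. It is cruder than
  a trained tagger; its errors mostly create extra noun-run candidates, which
  the negative clues then suppress.
* **Head detection is shallow.** Keyword/blacklist heads are detected from
  the token immediately following the candidate (or the stripped final token
  of its run) rather than from a dependency parse. The two head patterns the
  scoring model rewards ("The *PolyFreq* program", "*FASTA* format") are
  covered; long-range head attachments are not.
* **Enum and Hearst stack** on one mention, and DictionaryWord and
  KnownAcronym stack likewise: the score table lists them as independent
  patterns.
* **Case clue on multi-token candidates** uses the majority token class;
  ties yield no case clue.
* **Overlapping candidate spans** both survive scoring; at threshold time
  the highest-scoring accepted span wins, ties going to the longer span.
* **Propagation is exact**: "lexically equivalent" means a case-sensitive
  verbatim surface on token boundaries, and propagated mentions carry the
  accepting mention's score rather than being re-scored.
* **URLs are atomic tokens** (an exception to the one-punctuation-character
  rule) so the hyperlink clue can test a token prefix.
* **Weak windows include the candidate's own tokens**, so an ambiguous head
  absorbed into the noun run ("the FooTool platform") still counts once.
* **Strict `>` at the threshold**, since a candidate must *exceed* +5.00.

## Evaluation framework

[evaluate_predictions()] scores predictions against gold standoff
annotations at two levels × two modes. Mention-level strict requires
identical offsets; lenient accepts any character overlap with greedy
one-to-one pairing (largest overlap first — one prediction can never match
two gold spans). Document-level compares per-document name sets after
normalization (whitespace/dash folding); strict is case-sensitive, lenient
case-insensitive. Zero denominators yield 0 by convention. The bundled
[reference_scores()] table carries the published benchmark rows of the
original recogniser; for the training/development/Genome-Biology lenient
rows, recomputing F = 2PR/(P+R) from the printed P and R reproduces the
printed F to two decimals, which the test suite asserts.

## Survey statistics

From document-level lists plus a metadata table, [relative_usage()] computes
per-year usage (documents mentioning a resource / total documents that
year, or summed mention counts), [sigma_delta()] the sum of absolute
year-over-year changes (missing years count as zero), and
[random_walk_bounds()] a Gaussian random-walk envelope fitted to pooled
baseline-normalized changes. The default bound at step *k* is
*kμ ± 2σ√k* — the variance of a Gaussian random walk accumulates linearly —
with a flat *±2σ* variant behind a flag, since either reading of
"two standard deviations from the mean" is defensible for trend screening.
[long_tail_stats()] and [journal_overlap()] summarise the skew of mention
counts and cross-journal sharing.

## The synthetic fixture corpus

[generate_corpus()] builds a fully deterministic corpus (seeded; default 20
documents, 10 planted names of which 5 are dictionary entries, years
2001–2011 across two synthetic journals). Each document plants its primary
name in one strong-clue recipe — title pattern, Hearst list with a
dictionary partner, version + citation, or version + URL — plus two
weak-verb sentences and two distractor sentences (English words, acronyms,
`GO:001234`-style identifiers). Every token-boundary occurrence of a planted
name is gold.

What the generator emulates is the *clue machinery*: every planted name
carries at least two strong clues, and distractors exercise each negative
list. What it does not emulate: genuinely ambiguous resource names used as
common nouns, novel names with no contextual clues, coordination
("Clustal W and X"), OCR/layout noise, or the long-tail surface diversity
of real articles. Perfect recovery on the fixture therefore demonstrates
that the scoring, weak-evidence and propagation mechanics work as
specified — not that real-corpus F-measures would reach these levels; the
published benchmarks above show what this class of recogniser achieves on
real text.

## Problem sizes and numerics

The test suite and acceptance script run the full pipeline over the default
20-document fixture corpus (seconds on one CPU); property suites use a few
hundred randomized clue subsets and small randomized span sets checked
against brute-force oracles. Scores are plain doubles; no tolerances beyond
exact arithmetic are needed anywhere in scoring. Degenerate inputs are
defined: empty documents error at read time, empty candidate sets and empty
gold/prediction sets yield zero counts, zero-denominator metrics yield 0,
and random-walk fitting requires at least two change observations.

## Limitations

The recogniser is only as current as its dictionary and keyword lists; the
bundled lists are small fixtures, and full-scale lists are expected as
drop-in files. Name-variant aggregation is limited to case, whitespace and
dash folding — acronym expansion linking is out of scope. Document-level
propagation never crosses documents. The heuristic tagger is deliberately
simple; swap in a trained tagger through the plug-in interface when model
downloads are acceptable.
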