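Package: bionerds
Title: Rule-Based Recognition of Database and Software Names in Bioinformatics Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A score-driven, rule-based named-entity recogniser for
    bioinformatics database and software names in full-text articles.
    Candidate mentions from a case-sensitive dictionary and noun-only token
    runs are scored with local clues (title patterns, Hearst-style lists,
    keyword heads, version numbers, citations, URLs, orthography), adjusted
    by document-wide weak evidence, thresholded and propagated to every
    verbatim occurrence to yield document-level resource lists. Includes a
    strict/lenient evaluation framework at mention and document level, corpus
    survey statistics (yearly relative usage, sum-of-absolute-change
    variation, Gaussian random-walk bounds, long-tail and cross-journal
    overlap summaries), and a deterministic synthetic corpus generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
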