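#' Published benchmark scores of the original recogniser
#'
#' The precision/recall/F rows reported for the original system on its
#' 60-article gold-standard corpora (training, development, evaluation and a
#' Genome Biology hold-out; mention and document level, strict and lenient
#' matching). Bundled as a plain-text table so the F-measure arithmetic can
#' be regression-checked: for the training, development and genome_biology
#' lenient rows, recomputing F = 2PR/(P+R) from the printed P and R
#' reproduces the printed F to two decimals.
#'
#' @return data.frame(corpus, level, mode, precision, recall, f_score).
#' @export
reference_scores <- function() {
  utils::read.delim(system.file("extdata", "reference_scores.tsv",
                                package = "bionerds"),
                    stringsAsFactors = FALSE)
}
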