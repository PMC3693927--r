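# Clue scores, the compound factor, the weak score and the acceptance
# threshold — the tunable heart of the recogniser.

.positive_clues <- c("Dictionary", "Title", "Enum", "Hearst", "GoodHead",
                     "Version", "Reference", "HyperLink", "MixedCase",
                     "UpperCase")
.negative_clues <- c("Bioconductor", "DictionaryWord", "KnownAcronym",
                     "NegativeHead", "LowerCase", "PartialWord")
.clue_types <- c(.positive_clues, .negative_clues)

#' Clue score configuration
#'
#' Default scores: Dictionary +5.50, Title +4.00, Enum +3.00, Hearst +4.00,
#' GoodHead +2.00, Version +3.00, Reference +1.00, HyperLink +1.50,
#' MixedCase +1.00, UpperCase +0.50, Bioconductor -1.75, DictionaryWord
#' -4.00, KnownAcronym -15.00, NegativeHead -15.00, LowerCase -1.00,
#' PartialWord -15.00, CompoundFactor +0.50, Weak +0.50, threshold +5.00.
#' A candidate is accepted only when its final score strictly exceeds the
#' threshold.
#'
#' @param ... Named overrides, e.g. `clue_config(threshold = 6)`.
#' @return A named list of class `bionerds_clue_config`.
#' @export
clue_config <- function(...) {
  cfg <- list(
    Dictionary = 5.50, Title = 4.00, Enum = 3.00, Hearst = 4.00,
    GoodHead = 2.00, Version = 3.00, Reference = 1.00, HyperLink = 1.50,
    MixedCase = 1.00, UpperCase = 0.50,
    Bioconductor = -1.75, DictionaryWord = -4.00, KnownAcronym = -15.00,
    NegativeHead = -15.00, LowerCase = -1.00, PartialWord = -15.00,
    CompoundFactor = 0.50, Weak = 0.50, threshold = 5.00
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown clue config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- lapply(overrides, as.numeric)
  structure(cfg, class = "bionerds_clue_config")
}

#' Read a clue configuration file
#'
#' Flat `key = value` lines (``#`` comments allowed); keys missing from the
#' file keep their defaults, so an empty file reproduces the default
#' configuration exactly.
#'
#' @param path Config file path.
#' @return A `bionerds_clue_config`.
#' @export
read_clue_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(clue_config())
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- as.numeric(vapply(kv, `[[`, "", 2L))
  if (anyNA(vals)) stop("non-numeric value in clue config: ", path)
  do.call(clue_config, as.list(stats::setNames(vals, keys)))
}
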