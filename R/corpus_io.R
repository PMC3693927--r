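#' Construct a document
#'
#' A document is the unit over which the recogniser builds its resource list.
#' All character offsets used by the package are 0-based, half-open, and
#' counted in the canonical string `paste0(title, "\n", body)`.
#'
#' @param doc_id Non-empty identifier, unique within a corpus.
#' @param title Title text (first "sentence" of the document).
#' @param body Body text.
#' @param year Publication year (integer) or `NA`.
#' @param journal Journal name or `NA`.
#' @return An object of class `bionerds_document` with fields `doc_id`,
#'   `title`, `body`, `text` (the canonical string), `char_count`, `year`,
#'   `journal`.
#' @export
document <- function(doc_id, title, body, year = NA_integer_,
                     journal = NA_character_) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id)) {
    stop("doc_id must be a non-empty string")
  }
  title <- as.character(title)
  body <- as.character(body)
  text <- paste0(title, "\n", body)
  structure(
    list(doc_id = doc_id, title = title, body = body, text = text,
         char_count = nchar(text, type = "chars"),
         year = as.integer(year), journal = as.character(journal)),
    class = "bionerds_document"
  )
}

#' @export
print.bionerds_document <- function(x, ...) {
  cat(sprintf("<document %s> %d chars, title: %s\n", x$doc_id, x$char_count,
              substr(x$title, 1, 60)))
  invisible(x)
}

#' Extract a slice of the canonical document text
#'
#' @param doc A `bionerds_document`.
#' @param start,end 0-based half-open character offsets.
#' @return The substring `[start, end)`.
#' @export
doc_slice <- function(doc, start, end) {
  substr(rep(doc$text, length(start)), start + 1L, end)
}

#' Read a document from disk
#'
#' Plain text uses the dialect "first line is the title, the remainder is the
#' body". PMC-style JATS XML is reduced to plain text: markup is stripped and
#' element boundaries are replaced by single spaces so offsets are stable; the
#' abstract (when present) is prepended to the body.
#'
#' @param path File path.
#' @param format `"plaintext"` or `"pmc_xml"`.
#' @param doc_id Document identifier; defaults to the file name without
#'   extension.
#' @return A [document()].
#' @export
read_document <- function(path, format = c("plaintext", "pmc_xml"),
                          doc_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read document file: ", path)
  if (is.null(doc_id)) doc_id <- tools::file_path_sans_ext(basename(path))
  if (format == "plaintext") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
      stop("empty document: ", path)
    }
    document(doc_id, title = lines[[1L]],
             body = paste(lines[-1L], collapse = "\n"))
  } else {
    x <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    title <- xml_plain(xml2::xml_find_first(x, ".//article-title"))
    abstract <- xml_plain(xml2::xml_find_first(x, ".//abstract"))
    body <- xml_plain(xml2::xml_find_first(x, ".//body"))
    if (!nzchar(title) && !nzchar(body)) stop("empty document: ", path)
    full_body <- paste(c(abstract, body)[nzchar(c(abstract, body))],
                       collapse = " ")
    document(doc_id, title = title, body = full_body)
  }
}

# Flatten an XML node to text with element boundaries as single spaces.
xml_plain <- function(node) {
  if (inherits(node, "xml_missing") || length(node) == 0L) return("")
  pieces <- xml2::xml_text(xml2::xml_find_all(node, ".//text()"))
  squish(paste(pieces, collapse = " "))
}

squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Read a directory of plain-text documents
#'
#' @param dir Directory containing `*.txt` files (one document each).
#' @return Named list of [document()]s keyed by `doc_id`.
#' @export
read_corpus_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(paths) == 0L) stop("no .txt documents found in ", dir)
  docs <- lapply(paths, read_document)
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  if (anyDuplicated(names(docs))) stop("duplicate doc_id in corpus directory")
  docs
}

#' Read standoff annotations
#'
#' Standoff TSV columns: `doc_id`, `start`, `end`, `surface`. Offsets are
#' 0-based, half-open, into the canonical document string.
#'
#' @param path TSV path with header.
#' @return data.frame with columns doc_id (character), start, end (integer),
#'   surface (character), in file order.
#' @export
read_standoff <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = c(doc_id = "character",
                                         start = "integer", end = "integer",
                                         surface = "character"))
  required <- c("doc_id", "start", "end", "surface")
  if (!all(required %in% names(df))) {
    stop("standoff file must have columns: ", paste(required, collapse = ", "))
  }
  df <- df[required]
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad)) {
    stop("invalid standoff rows (need 0 <= start < end): row ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Write standoff annotations
#'
#' Inverse of [read_standoff()]: `read_standoff(write_standoff(x, p))` is the
#' identity. Extra columns (e.g. `score`, `propagated`) are preserved.
#'
#' @param annotations data.frame with at least doc_id, start, end, surface.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(annotations, path) {
  required <- c("doc_id", "start", "end", "surface")
  stopifnot(all(required %in% names(annotations)))
  ord <- c(required, setdiff(names(annotations), required))
  utils::write.table(annotations[ord], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate annotations against a corpus
#'
#' Checks that each annotation's document exists, offsets lie inside the
#' document, and the surface equals the document slice.
#'
#' @param annotations Standoff data.frame.
#' @param corpus Named list of documents (from [read_corpus_dir()] or built in
#'   code).
#' @return `annotations`, invisibly, or an error naming offending rows.
#' @export
validate_annotations <- function(annotations, corpus) {
  bad <- integer(0)
  for (i in seq_len(nrow(annotations))) {
    doc <- corpus[[annotations$doc_id[i]]]
    if (is.null(doc) ||
        annotations$end[i] > doc$char_count ||
        doc_slice(doc, annotations$start[i], annotations$end[i]) !=
          annotations$surface[i]) {
      bad <- c(bad, i)
    }
  }
  if (length(bad)) {
    stop("annotations failing offset/surface validation: row ",
         paste(bad, collapse = ", "))
  }
  invisible(annotations)
}

#' Read a document metadata table
#'
#' @param path CSV with columns `doc_id`, `journal`, `year`.
#' @return data.frame with those columns (year integer).
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(doc_id = "character"))
  stopifnot(all(c("doc_id", "journal", "year") %in% names(df)))
  df$year <- as.integer(df$year)
  df
}
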