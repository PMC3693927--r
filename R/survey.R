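# Corpus-level resource-usage analytics: yearly relative usage, variation
# (sum of absolute year-over-year changes), Gaussian random-walk envelopes,
# long-tail and cross-journal overlap summaries.

# survey-level grouping: normalize + case-fold
survey_key <- function(x) tolower(normalize_name(x))

#' Yearly usage of one resource
#'
#' Document level: the number of documents mentioning the resource in a year
#' divided by the total number of papers that year. Mention level: the sum
#' of mention counts instead of document flags. Years with zero total
#' documents are absent from the result; documents without year metadata are
#' excluded with a warning.
#'
#' @param doc_lists data.frame(doc_id, name, mention_count) from
#'   [annotate_corpus()] or [read_doc_lists()].
#' @param metadata data.frame(doc_id, journal, year).
#' @param resource Resource name (matched after normalization and
#'   case-folding).
#' @param level `"document"` or `"mention"`.
#' @param journal Optional journal filter.
#' @return data.frame(year, count, total_docs, relative).
#' @export
relative_usage <- function(doc_lists, metadata, resource,
                           level = c("document", "mention"),
                           journal = NULL) {
  level <- match.arg(level)
  if (!is.null(journal)) metadata <- metadata[metadata$journal == journal, ,
                                              drop = FALSE]
  no_year <- is.na(metadata$year)
  if (any(no_year)) {
    warning(sum(no_year), " documents without year metadata excluded")
    metadata <- metadata[!no_year, , drop = FALSE]
  }
  years <- sort(unique(metadata$year))
  totals <- as.integer(table(factor(metadata$year, levels = years)))
  hits <- doc_lists[survey_key(doc_lists$name) == survey_key(resource) &
                    doc_lists$doc_id %in% metadata$doc_id, , drop = FALSE]
  year_of <- stats::setNames(metadata$year, metadata$doc_id)
  hit_years <- year_of[hits$doc_id]
  count <- vapply(years, function(y) {
    rows <- which(hit_years == y)
    if (level == "document") length(unique(hits$doc_id[rows]))
    else sum(hits$mention_count[rows])
  }, 0L)
  data.frame(year = years, count = count, total_docs = totals,
             relative = ifelse(totals > 0, count / totals, NA_real_))
}

#' Variation: sum of absolute year-over-year changes
#'
#' For a series x over consecutive years, `sum(|x[y+1] - x[y]|)` over the
#' configured range. Years missing from the series count as 0.
#'
#' @param series Named numeric vector (names = years) or data.frame with
#'   `year` and a value column (`relative` or `count`, first found wins).
#' @param year_range Integer vector of years (at least 2) over which to
#'   evaluate, e.g. `2000:2010`.
#' @return list(sigma_delta, year_range).
#' @export
sigma_delta <- function(series, year_range) {
  year_range <- sort(as.integer(year_range))
  if (length(year_range) < 2L) stop("year_range must span at least 2 years")
  if (is.data.frame(series)) {
    valcol <- intersect(c("relative", "count", "value"), names(series))[1L]
    if (is.na(valcol)) stop("series data.frame needs a value column")
    series <- stats::setNames(series[[valcol]], series$year)
  }
  x <- stats::setNames(rep(0, length(year_range)), year_range)
  present <- intersect(names(series), names(x))
  x[present] <- series[present]
  list(sigma_delta = sum(abs(diff(unname(x)))), year_range = year_range)
}

#' Gaussian random-walk envelope for usage trajectories
#'
#' Fits the step mean and standard deviation from pooled year-over-year
#' changes of baseline-normalized usage, then reports upper/lower bounds at
#' each step k. Default scaling is cumulative (`k*mu +/- 2*sd*sqrt(k)`, the
#' variance of a Gaussian random walk after k steps); a flat `+/- 2*sd`
#' variant is available via `cumulative = FALSE`.
#'
#' @param changes Numeric vector of pooled per-resource year-over-year
#'   changes (at least 2 values).
#' @param horizon Number of steps k to tabulate.
#' @param cumulative Use sqrt(k) scaling (default TRUE).
#' @return list(mean_step, sd_step, bounds = data.frame(step, center, lower,
#'   upper)).
#' @export
random_walk_bounds <- function(changes, horizon, cumulative = TRUE) {
  changes <- as.numeric(changes)
  if (length(changes) < 2L) stop("need at least 2 change observations")
  mu <- mean(changes)
  sigma <- stats::sd(changes)
  k <- seq_len(horizon)
  half <- if (cumulative) 2 * sigma * sqrt(k) else rep(2 * sigma, horizon)
  bounds <- data.frame(step = k, center = k * mu, lower = k * mu - half,
                       upper = k * mu + half)
  list(mean_step = mu, sd_step = sigma, bounds = bounds)
}

#' Flag trajectory points outside a random-walk envelope
#'
#' @param trajectory Numeric vector of cumulative normalized changes, one
#'   value per step (step 1 first).
#' @param bounds Result of [random_walk_bounds()].
#' @return Logical vector: TRUE where the trajectory escapes the envelope.
#' @export
outside_bounds <- function(trajectory, bounds) {
  b <- bounds$bounds
  k <- seq_along(trajectory)
  if (length(k) > nrow(b)) stop("trajectory longer than tabulated horizon")
  trajectory > b$upper[k] | trajectory < b$lower[k]
}

#' Long-tail summary of mention counts
#'
#' @param counts Named or unnamed numeric vector of per-resource mention
#'   counts (non-empty).
#' @param below_n Threshold for the "mentioned fewer than N times" fraction
#'   (default 6).
#' @param top_k Number of top resources for the dominance share (default
#'   100, capped at the number of resources).
#' @return list(fraction_once, fraction_below, top_k_share, n_resources).
#' @export
long_tail_stats <- function(counts, below_n = 6, top_k = 100) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("empty count table")
  k <- min(top_k, length(counts))
  srt <- sort(counts, decreasing = TRUE)
  list(fraction_once = mean(counts == 1),
       fraction_below = mean(counts < below_n),
       top_k_share = sum(srt[seq_len(k)]) / sum(counts),
       n_resources = length(counts))
}

#' Cross-journal name overlap report
#'
#' @param names_a,names_b Resource-name sets of the two journals (survey
#'   grouping: normalized and case-folded before comparison).
#' @param counts Named numeric vector of total mention counts per resource
#'   name over both journals (names on the same key).
#' @return list(jaccard, intersection_size, union_size, share_a, share_b,
#'   share_total) — the intersection's share of each journal's mentions and
#'   of all mentions.
#' @export
journal_overlap <- function(names_a, names_b, counts) {
  a <- unique(survey_key(names_a))
  b <- unique(survey_key(names_b))
  names(counts) <- survey_key(names(counts))
  both <- intersect(a, b)
  all_names <- union(a, b)
  cnt <- function(nms) sum(counts[intersect(nms, names(counts))], na.rm = TRUE)
  total <- cnt(all_names)
  list(jaccard = if (length(all_names)) length(both) / length(all_names) else 0,
       intersection_size = length(both),
       union_size = length(all_names),
       share_a = if (cnt(a) > 0) cnt(both) / cnt(a) else 0,
       share_b = if (cnt(b) > 0) cnt(both) / cnt(b) else 0,
       share_total = if (total > 0) cnt(both) / total else 0)
}
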