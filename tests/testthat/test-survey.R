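md <- function(n, year = 2005L, journal = "journal_a") {
  data.frame(doc_id = sprintf("d%02d", seq_len(n)), journal = journal,
             year = year, stringsAsFactors = FALSE)
}

test_that("relative usage divides mentioning documents by yearly totals", {
  meta <- md(10)
  dl <- data.frame(doc_id = c("d01", "d02", "d03"), name = "R",
                   mention_count = c(1L, 2L, 5L), stringsAsFactors = FALSE)
  u <- relative_usage(dl, meta, "R", level = "document")
  expect_equal(u$relative, 0.30)
  expect_equal(u$count, 3L)
  # mention level sums counts instead of flags
  um <- relative_usage(dl, meta, "R", level = "mention")
  expect_equal(um$count, 8L)
  # resource never mentioned -> zero counts, values stay within [0, 1]
  u0 <- relative_usage(dl, meta, "NotThere", level = "document")
  expect_true(all(u0$count == 0L))
  expect_true(all(u$relative >= 0 & u$relative <= 1))
  # documents without year metadata are excluded with a warning
  meta2 <- meta; meta2$year[1] <- NA
  expect_warning(relative_usage(dl, meta2, "R"), "without year")
})

test_that("sigma-delta sums absolute year-over-year changes", {
  yrs <- 2000:2002
  expect_equal(sigma_delta(stats::setNames(c(2, 2, 2), yrs), yrs)$sigma_delta, 0)
  expect_equal(sigma_delta(stats::setNames(c(1, 3, 2), yrs), yrs)$sigma_delta, 3)
  # strictly increasing telescopes to last - first
  inc <- stats::setNames(c(1, 4, 9, 16), 2000:2003)
  expect_equal(sigma_delta(inc, 2000:2003)$sigma_delta, 15)
  # reversal invariance and missing years as zero
  set.seed(31)
  for (rep in 1:20) {
    v <- stats::setNames(runif(5), 2000:2004)
    fwd <- sigma_delta(v, 2000:2004)$sigma_delta
    rev_v <- stats::setNames(rev(unname(v)), 2000:2004)
    expect_equal(fwd, sigma_delta(rev_v, 2000:2004)$sigma_delta)
  }
  gap <- stats::setNames(c(1, 2), c(2000, 2002))
  expect_equal(sigma_delta(gap, 2000:2002)$sigma_delta, 1 + 2)  # missing 2001 counts as 0
  expect_error(sigma_delta(gap, 2000), "at least 2")
})

test_that("random-walk bounds follow the closed forms", {
  # sigma = 0 collapses to the mean line
  b0 <- random_walk_bounds(c(0.3, 0.3, 0.3), horizon = 5)
  expect_equal(b0$bounds$upper, b0$bounds$lower)
  expect_equal(b0$bounds$upper, 0.3 * 1:5)
  # mu = 0, sigma = 1, k = 4 -> bounds at +/- 4 under sqrt scaling
  x <- c(-1, 1, -1, 1, -1, 1, -1, 1) * sqrt(8 / 7)  # mean 0, sd 1... check below
  x <- x / stats::sd(x)
  b1 <- random_walk_bounds(x, horizon = 4)
  expect_equal(b1$mean_step, 0)
  expect_equal(b1$sd_step, 1)
  expect_equal(b1$bounds$upper[4], 4.0)
  expect_equal(b1$bounds$lower[4], -4.0)
  # flat variant stays at +/- 2 sd
  bf <- random_walk_bounds(x, horizon = 4, cumulative = FALSE)
  expect_equal(bf$bounds$upper, rep(2, 4))
  # doubling sigma doubles the half-width at every step
  b2 <- random_walk_bounds(2 * x, horizon = 6)
  b1b <- random_walk_bounds(x, horizon = 6)
  expect_equal(b2$bounds$upper - b2$bounds$center,
               2 * (b1b$bounds$upper - b1b$bounds$center))
  expect_error(random_walk_bounds(1, horizon = 3), "at least 2")
})

test_that("trajectories are flagged outside the envelope and not inside", {
  x <- stats::rnorm(50)
  x <- (x - mean(x)) / stats::sd(x)  # mu = 0, sd = 1 exactly
  b <- random_walk_bounds(x, horizon = 4)
  escaping <- c(1, 2, 3, 9)   # 9 > 2 * sqrt(4)
  inside <- c(0.5, -1, 1, 3)  # 3 < 4
  expect_true(any(outside_bounds(escaping, b)))
  expect_false(any(outside_bounds(inside, b)))
})

test_that("long-tail statistics: fractions and top-K share", {
  s <- long_tail_stats(c(10, 1, 1, 1))
  expect_equal(s$fraction_once, 0.75)
  expect_equal(long_tail_stats(5)$top_k_share, 1.0)
  expect_equal(long_tail_stats(c(5, 4, 3, 2, 1), top_k = 2)$top_k_share, 0.6)
  # fraction below N is monotone non-decreasing in N
  counts <- c(1, 1, 2, 3, 5, 8, 20)
  fr <- vapply(1:10, function(n) long_tail_stats(counts, below_n = n)$fraction_below, 0)
  expect_true(all(diff(fr) >= 0))
  expect_error(long_tail_stats(numeric(0)), "empty")
})

test_that("journal overlap reports jaccard and mention shares", {
  counts <- c(x = 10, y = 1, z = 1, w = 1)
  ov <- journal_overlap(c("x", "y", "z"), c("x", "w"), counts)
  expect_equal(ov$jaccard, 0.25)
  expect_equal(ov$share_total, 10 / 13)
  expect_equal(ov$share_b, 10 / 11)
  expect_equal(ov$share_a, 10 / 12)
  # degenerate cases
  expect_equal(journal_overlap("a", "b", c(a = 1, b = 1))$share_total, 0)
  expect_equal(journal_overlap(c("a", "b"), c("a", "b"),
                               c(a = 2, b = 3))$jaccard, 1.0)
})
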