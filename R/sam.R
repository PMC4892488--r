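# Significance Analysis of Microarrays (two-class unpaired) used as a
# differential pre-filter before network construction. The d statistic is a
# t-like contrast moderated by a fudge factor s0 that stabilises genes with
# tiny scatter; genes are selected when their observed d deviates from the
# permutation-averaged expected order statistic by more than delta.

group_moments <- function(expr, ids) {
  x <- expr[, ids, drop = FALSE]
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  list(n = n, mean = m, ss = ss)
}

sam_d_numden <- function(expr, ref_ids, test_ids) {
  a <- group_moments(expr, ref_ids)
  b <- group_moments(expr, test_ids)
  pooled_var <- (a$ss + b$ss) / (a$n + b$n - 2)
  s <- sqrt((1 / a$n + 1 / b$n) * pooled_var)
  list(num = b$mean - a$mean, s = s)
}

#' SAM fudge factor s0
#'
#' Chooses s0 as the percentile of the per-gene scatter distribution that
#' minimises the coefficient of variation of the median absolute deviation
#' of d across windows of genes grouped by scatter — the standard SAM
#' recipe for making |d| roughly independent of s.
#'
#' @param num Per-gene numerators (test mean - reference mean).
#' @param s Per-gene pooled standard errors.
#' @param n_windows Number of scatter-quantile windows (default 10).
#' @return A single nonnegative s0 value.
#' @export
choose_s0 <- function(num, s, n_windows = 10L) {
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05),
                                 names = FALSE))
  win <- cut(rank(s, ties.method = "first"),
             breaks = n_windows, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- num / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2L) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cv)]
}

#' Per-gene SAM d statistic
#'
#' d_i = (mean_test - mean_ref) / (s_i + s0), with s_i the pooled standard
#' error of the mean difference. Swapping the two condition labels negates
#' every d.
#'
#' @param expr Expression matrix (genes x samples).
#' @param groups `sample_groups` with at least two samples per condition.
#' @param s0 Nonnegative fudge factor; `NULL` selects it with [choose_s0()].
#' @return Named numeric vector of d values with the chosen s0 as an
#'   attribute.
#' @export
sam_statistic <- function(expr, groups, s0 = NULL) {
  assert_expression_matrix(expr)
  check_groups_cover(expr, groups, min_per_group = 2L)
  ref_ids <- group_samples(groups, expr, "reference")
  test_ids <- group_samples(groups, expr, "test")
  nd <- sam_d_numden(expr, ref_ids, test_ids)
  if (is.null(s0)) s0 <- choose_s0(nd$num, nd$s)
  if (s0 < 0) stop_coexdiff("s0 must be nonnegative")
  d <- nd$num / (nd$s + s0)
  attr(d, "s0") <- s0
  d
}

drop_high_missingness <- function(expr, groups, max_missing = 0.2) {
  bad <- rep(FALSE, nrow(expr))
  for (w in c("reference", "test")) {
    ids <- group_samples(groups, expr, w)
    bad <- bad | rowMeans(is.na(expr[, ids, drop = FALSE])) > max_missing
  }
  if (any(bad)) {
    log_warn("dropping ", sum(bad), " genes missing in > ",
             max_missing * 100, "% of samples of a group")
    expr <- expr[!bad, , drop = FALSE]
  }
  expr
}

#' SAM gene selection by delta banding
#'
#' Condition labels are permuted `n_perm` times; the expected d order
#' statistics are the across-permutation means of the sorted permuted d.
#' A gene is selected when its sorted observed d deviates from the matching
#' expected order statistic by more than `delta`. Selection is monotone:
#' raising delta can only shrink the selected set.
#'
#' @param expr Expression matrix (genes x samples).
#' @param groups `sample_groups`.
#' @param delta Nonnegative banding threshold on |d - expected d|.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @param s0 Optional fixed fudge factor (default: automatic).
#' @return A `sam_result` list: `d`, `expected` (per gene, aligned),
#'   `selected` (logical per gene), `s0`, `delta`, `n_perm`.
#' @export
sam_select <- function(expr, groups, delta = 0.296, n_perm = 100L,
                       seed = 1L, s0 = NULL) {
  if (delta < 0) stop_coexdiff("delta must be nonnegative")
  if (n_perm < 1) stop_coexdiff("n_perm must be at least 1")
  assert_expression_matrix(expr)
  expr <- drop_high_missingness(expr, groups)
  check_groups_cover(expr, groups, min_per_group = 2L)
  d <- sam_statistic(expr, groups, s0 = s0)
  s0 <- attr(d, "s0")

  ref_lab <- attr(groups, "reference")
  samples <- intersect(colnames(expr), names(groups))
  cond <- unname(groups[samples])
  n_ref <- sum(cond == ref_lab)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  perm_sorted <- matrix(0, nrow(expr), n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample(length(samples))
    ref_ids <- samples[idx[seq_len(n_ref)]]
    test_ids <- samples[idx[-seq_len(n_ref)]]
    nd <- sam_d_numden(expr, ref_ids, test_ids)
    perm_sorted[, p] <- sort(nd$num / (nd$s + s0))
  }
  expected_sorted <- rowMeans(perm_sorted)

  ord <- order(d)
  expected <- numeric(length(d))
  expected[ord] <- expected_sorted
  names(expected) <- names(d)
  selected <- abs(d - expected) > delta

  structure(
    list(d = d, expected = expected, selected = selected,
         s0 = s0, delta = delta, n_perm = n_perm, seed = seed),
    class = "sam_result"
  )
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM two-class result: ", sum(x$selected), "/", length(x$d),
      " genes selected (delta = ", x$delta, ", s0 = ",
      signif(x$s0, 4), ", ", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}
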