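# Signed weighted co-expression network: Pearson correlation, soft
# thresholding to a signed adjacency, scale-free topology criterion for the
# power, and the topological overlap matrix (TOM) and its dissimilarity.

#' Pearson correlation matrix across samples
#'
#' @param expr Expression matrix (genes x samples), at least 3 samples,
#'   every gene with positive variance.
#' @return Symmetric gene x gene correlation matrix with unit diagonal
#'   (symmetrised by averaging with its transpose).
#' @export
correlation_matrix <- function(expr) {
  assert_expression_matrix(expr)
  if (ncol(expr) < 3L)
    stop_coexdiff("need at least 3 samples for correlations")
  v <- apply(expr, 1L, stats::var)
  if (any(v <= 0 | !is.finite(v)))
    stop_coexdiff("zero-variance genes: ",
                  paste(utils::head(rownames(expr)[v <= 0 | !is.finite(v)], 5),
                        collapse = ", "))
  cc <- stats::cor(t(expr))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Signed soft-threshold adjacency
#'
#' a_ij = ((1 + cor_ij) / 2) ^ beta. Negative correlations map near zero
#' instead of being conflated with positive co-expression; beta sharpens the
#' contrast between strong and weak correlation.
#'
#' @param correlation Symmetric correlation matrix with entries in [-1, 1].
#' @param beta Positive integer soft-thresholding power.
#' @return Adjacency matrix in [0, 1] with unit diagonal.
#' @export
signed_adjacency <- function(correlation, beta) {
  if (length(beta) != 1L || beta < 1 || beta != round(beta))
    stop_coexdiff("beta must be a positive integer")
  if (max(abs(correlation)) > 1 + 1e-8)
    stop_coexdiff("correlation entries must lie in [-1, 1]")
  a <- ((1 + correlation) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a network's connectivity distribution
#'
#' Connectivity k_i is the row sum of the adjacency excluding the diagonal.
#' Genes are binned into `n_bins` equal-width bins of k; log10 frequency is
#' regressed on log10 mean bin connectivity over occupied bins.
#'
#' @param adjacency Adjacency matrix.
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return List with `r_squared`, `slope`, `k` (per-gene connectivity) and
#'   the binned points used for the fit.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10L) {
  assert_square_symmetric(adjacency, "adjacency")
  k <- rowSums(adjacency) - diag(adjacency)
  if (diff(range(k)) < .Machine$double.eps^0.5)
    stop_coexdiff("degenerate connectivity distribution: all k identical")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  freq <- tabulate(bin, nbins = n_bins)
  mean_k <- vapply(seq_len(n_bins),
                   function(b) if (freq[b] > 0) mean(k[bin == b]) else NA_real_,
                   numeric(1))
  ok <- freq > 0 & mean_k > 0
  if (sum(ok) < 2L)
    stop_coexdiff("fewer than 2 occupied connectivity bins")
  x <- log10(mean_k[ok])
  y <- log10(freq[ok])
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  list(
    r_squared = r2,
    slope = unname(stats::coef(fit)[2]),
    k = k,
    bins = data.frame(mean_k = mean_k[ok], frequency = freq[ok])
  )
}

#' Soft-threshold power selection by the scale-free topology criterion
#'
#' Scans candidate powers and returns the smallest one whose network has a
#' log-log connectivity fit with R^2 above `r2_cut` and negative slope. If
#' none qualifies the power maximising R^2 is returned with a warning and
#' the scan flagged.
#'
#' @param correlation Correlation matrix.
#' @param candidate_betas Increasing positive integers (default 1:20).
#' @param r2_cut R^2 requirement (default 0.8).
#' @param n_bins Bins for [scale_free_fit()].
#' @return List: `beta`, `scan` (data.frame beta/r_squared/slope/mean_k),
#'   `reached_cut` flag.
#' @export
pick_soft_threshold <- function(correlation, candidate_betas = 1:20,
                                r2_cut = 0.8, n_bins = 10L) {
  if (!length(candidate_betas))
    stop_coexdiff("candidate_betas must be nonempty")
  if (is.unsorted(candidate_betas, strictly = TRUE))
    stop_coexdiff("candidate_betas must be strictly increasing")
  scan <- data.frame(beta = candidate_betas, r_squared = NA_real_,
                     slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidate_betas)) {
    a <- signed_adjacency(correlation, candidate_betas[i])
    f <- scale_free_fit(a, n_bins = n_bins)
    scan$r_squared[i] <- f$r_squared
    scan$slope[i] <- f$slope
    scan$mean_k[i] <- mean(f$k)
  }
  qualifies <- scan$r_squared > r2_cut & scan$slope < 0
  if (any(qualifies)) {
    beta <- candidate_betas[which(qualifies)[1]]
    reached <- TRUE
  } else {
    beta <- candidate_betas[which.max(scan$r_squared)]
    reached <- FALSE
    log_warn("no candidate beta reached R^2 > ", r2_cut,
             "; falling back to argmax-R^2 beta = ", beta)
  }
  list(beta = beta, scan = scan, reached_cut = reached)
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j, with
#' L_ij the count of shared weighted neighbours sum_u a_iu a_uj (u != i, j)
#' and k the connectivity. TOM_ii = 1. For adjacencies in [0, 1] all TOM
#' entries lie in [0, 1].
#'
#' @param adjacency Symmetric adjacency with unit diagonal, entries [0, 1].
#' @return TOM matrix of the same order.
#' @export
topological_overlap <- function(adjacency) {
  assert_square_symmetric(adjacency, "adjacency")
  if (min(adjacency) < -1e-12 || max(adjacency) > 1 + 1e-12)
    stop_coexdiff("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a            # zero diagonal of a excludes u = i and u = j
  k <- rowSums(a)
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' TOM dissimilarity
#'
#' @param tom TOM matrix.
#' @return 1 - TOM elementwise (zero diagonal).
#' @export
tom_dissimilarity <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Build the full co-expression network for one condition
#'
#' Convenience constructor chaining correlation, signed adjacency, and TOM.
#'
#' @param expr Expression matrix for the condition's samples.
#' @param beta Soft-threshold power; `NULL` selects it with
#'   [pick_soft_threshold()].
#' @param candidate_betas,r2_cut Passed to the power scan when beta is NULL.
#' @return A `coexpression_network` list: `gene_ids`, `correlation`,
#'   `adjacency`, `tom`, `beta`, and `scan` when the power was scanned.
#' @export
build_coexpression_network <- function(expr, beta = NULL,
                                       candidate_betas = 1:20, r2_cut = 0.8) {
  cc <- correlation_matrix(expr)
  scan <- NULL
  if (is.null(beta)) {
    picked <- pick_soft_threshold(cc, candidate_betas, r2_cut)
    beta <- picked$beta
    scan <- picked$scan
  }
  a <- signed_adjacency(cc, beta)
  structure(
    list(gene_ids = rownames(expr), correlation = cc, adjacency = a,
         tom = topological_overlap(a), beta = as.integer(beta), scan = scan),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Signed co-expression network: ", length(x$gene_ids), " genes, beta = ",
      x$beta, "\n", sep = "")
  invisible(x)
}
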