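# Module preservation: does a module defined on the reference network keep
# its density and connectivity pattern in the test network? Observed
# statistics are compared with a permutation null of random same-size gene
# sets; per-statistic Z scores are median-combined within the density and
# connectivity aspects and averaged into Zsummary.

# Submatrix worker shared by the exported interface and the permutation
# loop; x_std is the module rows of the per-gene standardized expression.
density_stats_sub <- function(a, cc, x_std) {
  off <- upper.tri(a)
  ev <- eigen(crossprod(x_std), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  c(meanAdj = mean(a[off]),
    meanCor = mean(cc[off]),
    propVarExplained = ev[1] / sum(ev))
}

#' Density preservation statistics of a gene set in one network
#'
#' @param module_genes Character vector of gene ids (at least 3).
#' @param network `coexpression_network` containing those genes.
#' @param expr Expression matrix for the same condition (used for the
#'   eigengene variance explained).
#' @return Named numeric vector: `meanAdj`, `meanCor`, `propVarExplained`.
#' @export
density_statistics <- function(module_genes, network, expr) {
  if (length(module_genes) < 3L)
    stop_coexdiff("need at least 3 genes for density statistics")
  if (!all(module_genes %in% network$gene_ids))
    stop_coexdiff("module genes missing from the network")
  density_stats_sub(network$adjacency[module_genes, module_genes],
                    network$correlation[module_genes, module_genes],
                    standardize_genes(expr[module_genes, , drop = FALSE]))
}

#' Connectivity preservation statistics between two networks
#'
#' Correlations, over a module's genes, of (i) intramodular connectivity
#' vectors, (ii) vectorized upper-triangle adjacencies, (iii) vectorized
#' upper-triangle correlations, between the reference and test networks.
#' A statistic with a constant input vector is reported as 0 and flagged.
#'
#' @param module_genes Character vector of gene ids (at least 3).
#' @param reference,test `coexpression_network` objects sharing the genes.
#' @return Named numeric vector `cor_kIM`, `cor_adj`, `cor_cor` with a
#'   `degenerate` attribute naming flagged statistics.
#' @name connectivity_statistics
NULL

connectivity_stats_sub <- function(a_r, a_t, c_r, c_t) {
  k_r <- rowSums(a_r) - diag(a_r)
  k_t <- rowSums(a_t) - diag(a_t)
  off <- upper.tri(a_r)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  out <- c(cor_kIM = safe_cor(k_r, k_t),
           cor_adj = safe_cor(a_r[off], a_t[off]),
           cor_cor = safe_cor(c_r[off], c_t[off]))
  degenerate <- names(out)[is.na(out)]
  out[is.na(out)] <- 0
  attr(out, "degenerate") <- degenerate
  out
}

#' @rdname connectivity_statistics
#' @export
connectivity_statistics <- function(module_genes, reference, test) {
  if (length(module_genes) < 3L)
    stop_coexdiff("need at least 3 genes for connectivity statistics")
  connectivity_stats_sub(reference$adjacency[module_genes, module_genes],
                         test$adjacency[module_genes, module_genes],
                         reference$correlation[module_genes, module_genes],
                         test$correlation[module_genes, module_genes])
}

#' Random same-size gene sets for the permutation null
#'
#' @param module_size Size of each drawn set.
#' @param network_genes Gene universe to draw from.
#' @param n_perm Number of draws (at least 20).
#' @param seed Integer seed.
#' @return List of `n_perm` character vectors.
#' @export
permutation_null <- function(module_size, network_genes, n_perm = 200L,
                             seed = 1L) {
  if (module_size > length(network_genes))
    stop_coexdiff("module_size exceeds the gene universe")
  if (n_perm < 20L) stop_coexdiff("n_perm must be at least 20")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  lapply(seq_len(n_perm), function(i) sample(network_genes, module_size))
}

#' Permutation Z score per statistic
#'
#' Z = (observed - mean(null)) / sd(null). A null with zero spread yields a
#' signed infinite sentinel and a flag rather than a silent drop.
#'
#' @param observed Named numeric vector of observed statistics.
#' @param null_values Matrix (permutations x statistics) of null samples,
#'   columns matching `observed`.
#' @return Named numeric Z vector with a `degenerate` attribute.
#' @export
z_scores <- function(observed, null_values) {
  if (is.null(dim(null_values)))
    null_values <- matrix(null_values, ncol = length(observed),
                          dimnames = list(NULL, names(observed)))
  if (nrow(null_values) < 20L)
    stop_coexdiff("need at least 20 permutation values per statistic")
  mu <- colMeans(null_values)
  sdev <- apply(null_values, 2L, stats::sd)
  z <- (observed - mu[names(observed)]) / sdev[names(observed)]
  degenerate <- names(observed)[sdev[names(observed)] == 0]
  dev <- sign(observed[degenerate] - mu[degenerate])
  z[degenerate] <- ifelse(dev == 0, 0, dev * Inf)
  attr(z, "degenerate") <- degenerate
  z
}

#' Combine per-statistic Z scores into Zsummary
#'
#' The density and connectivity aspects are each summarised by the median
#' of their statistics' Z scores; Zsummary is the arithmetic mean of the
#' two medians.
#'
#' @param z_density_values,z_connectivity_values Numeric vectors of Z
#'   scores (nonempty).
#' @return Named numeric vector `z_density`, `z_connectivity`, `z_summary`.
#' @export
z_summary <- function(z_density_values, z_connectivity_values) {
  if (!length(z_density_values) || !length(z_connectivity_values))
    stop_coexdiff("both Z lists must be nonempty")
  zd <- stats::median(z_density_values)
  zc <- stats::median(z_connectivity_values)
  c(z_density = zd, z_connectivity = zc, z_summary = (zd + zc) / 2)
}

#' Preservation category from Zsummary
#'
#' Zsummary at most 2: no preservation; between 2 and 10: weak-to-moderate
#' evidence; above 10: strong evidence. Boundary values fall into the lower
#' category.
#'
#' @param z_summary Finite Zsummary value(s).
#' @return Character vector of categories.
#' @export
classify_preservation <- function(z_summary) {
  ifelse(z_summary <= 2, "none",
         ifelse(z_summary <= 10, "weak-to-moderate", "strong"))
}

#' Permutation preservation report for all modules of a partition
#'
#' For every nonzero module (plus the unassigned "grey" pool and an
#' artificial "gold" module of randomly sampled network genes used as a
#' calibration baseline), computes observed density statistics in the test
#' network, observed ref-vs-test connectivity statistics, a permutation
#' null from random same-size gene sets of the test universe, per-statistic
#' Z scores, and Zsummary.
#'
#' @param reference,test `coexpression_network` objects on the same genes.
#' @param partition `module_partition` defined on the reference network.
#' @param expr_test Expression matrix of the test condition (samples used
#'   for the test network).
#' @param n_perm Number of permutations (default 200).
#' @param seed Integer seed.
#' @param gold_size Size of the artificial gold module (default
#'   `min(1000, n/5)`), 0 to disable.
#' @return A `preservation_report` data.frame: module, color, size,
#'   z_density, z_connectivity, z_summary, category, plus observed
#'   statistics.
#' @export
module_preservation <- function(reference, test, partition, expr_test,
                                n_perm = 200L, seed = 1L, gold_size = NULL) {
  if (!identical(reference$gene_ids, test$gene_ids))
    stop_coexdiff("reference and test networks must share gene ids")
  genes <- reference$gene_ids
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  labs <- sort(unique(partition$labels[partition$labels > 0]))
  mods <- lapply(labs, function(k) module_genes(partition, k))
  names(mods) <- partition$colors[as.character(labs)]
  grey <- names(partition$labels)[partition$labels == 0]
  if (length(grey) >= 3L) mods$grey <- grey
  if (is.null(gold_size))
    gold_size <- min(1000L, max(3L, floor(length(genes) / 5)))
  if (gold_size >= 3L) mods$gold <- sample(genes, gold_size)

  stat_names <- c("meanAdj", "meanCor", "propVarExplained",
                  "cor_kIM", "cor_adj", "cor_cor")
  expr_std <- standardize_genes(expr_test[genes, , drop = FALSE])
  # Null model (module-label permutation in the test network): density of a
  # random same-size gene set in the test network, and connectivity
  # agreement between the module's reference pattern and a random test-side
  # gene set — the gene-wise correspondence, not the networks, is what gets
  # randomized.
  stats_for <- function(midx, tidx) {
    c(density_stats_sub(test$adjacency[tidx, tidx],
                        test$correlation[tidx, tidx],
                        expr_std[tidx, , drop = FALSE]),
      connectivity_stats_sub(reference$adjacency[midx, midx],
                             test$adjacency[tidx, tidx],
                             reference$correlation[midx, midx],
                             test$correlation[tidx, tidx]))
  }
  rows <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    mg <- mods[[i]]
    midx <- match(mg, genes)
    obs <- stats_for(midx, midx)
    obs_d <- obs[1:3]; obs_c <- obs[4:6]
    null <- matrix(NA_real_, n_perm, length(stat_names),
                   dimnames = list(NULL, stat_names))
    for (p in seq_len(n_perm))
      null[p, ] <- stats_for(midx, sample.int(length(genes), length(mg)))
    z <- z_scores(c(obs_d, obs_c), null)
    zs <- z_summary(z[1:3], z[4:6])
    rows[[i]] <- data.frame(
      module = names(mods)[i], size = length(mg),
      z_density = zs["z_density"], z_connectivity = zs["z_connectivity"],
      z_summary = zs["z_summary"],
      category = classify_preservation(zs["z_summary"]),
      meanAdj = obs_d["meanAdj"], meanCor = obs_d["meanCor"],
      propVarExplained = obs_d["propVarExplained"],
      cor_kIM = obs_c["cor_kIM"], cor_adj = obs_c["cor_adj"],
      cor_cor = obs_c["cor_cor"],
      degenerate = length(attr(z, "degenerate")) > 0,
      row.names = NULL
    )
  }
  report <- do.call(rbind, rows)
  report <- report[order(-report$z_summary), ]
  rownames(report) <- NULL
  class(report) <- c("preservation_report", "data.frame")
  report
}

#' Select weakly preserved (disease candidate) modules
#'
#' Modules with Zsummary below `cutoff`, excluding the unassigned grey pool
#' and the artificial gold module, sorted by ascending Zsummary.
#'
#' @param report A `preservation_report`.
#' @param cutoff Zsummary selection cutoff (default 5).
#' @return Character vector of module names.
#' @export
select_weak_modules <- function(report, cutoff = 5) {
  keep <- !(report$module %in% c("grey", "gold")) & report$z_summary < cutoff
  sel <- report[keep, ]
  sel$module[order(sel$z_summary)]
}
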