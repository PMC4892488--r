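# Module detection: average-linkage clustering of the TOM dissimilarity,
# hybrid dynamic tree cut, module colors, eigengenes and kME.

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Thin wrapper over [stats::hclust()] with `method = "average"` taking a
#' square dissimilarity matrix; rejects missing values up front.
#'
#' @param dissimilarity Square symmetric matrix, zero diagonal.
#' @return An `hclust` object.
#' @export
average_linkage <- function(dissimilarity) {
  assert_square_symmetric(dissimilarity, "dissimilarity")
  if (anyNA(dissimilarity))
    stop_coexdiff("dissimilarity contains missing values")
  if (any(abs(diag(dissimilarity)) > 1e-10))
    stop_coexdiff("dissimilarity must have a zero diagonal")
  stats::hclust(stats::as.dist(dissimilarity), method = "average")
}

# deep_split in {0,1,2,3} -> fraction of a branch's height range allowed
# as core scatter; the minimum gap is (1 - fraction) * 3/4 of that range.
# The range is branch-relative (attachment height minus the branch's lowest
# internal join) so that loose and tight modules are judged on their own
# scale rather than against the globally tightest branch.
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:3)
    stop_coexdiff("deep_split must be one of 0, 1, 2, 3")
  c(0.64, 0.73, 0.82, 0.91)[deep_split + 1L]
}

# Per-node subtree summaries of an hclust tree: size, leaves, and the
# lowest merge heights (enough to compute a core scatter over the first
# `core_size` joined elements).
subtree_summaries <- function(hc, core_size) {
  m <- hc$merge
  h <- hc$height
  n_nodes <- nrow(m)
  size <- integer(n_nodes)
  leaves <- vector("list", n_nodes)
  low_h <- vector("list", n_nodes)     # up to core_size - 1 smallest heights
  keep <- max(core_size - 1L, 1L)
  child <- function(x, what) {
    if (x < 0) {
      switch(what, size = 1L, leaves = -x, low = numeric(0))
    } else {
      switch(what, size = size[x], leaves = leaves[[x]], low = low_h[[x]])
    }
  }
  for (i in seq_len(n_nodes)) {
    size[i] <- child(m[i, 1], "size") + child(m[i, 2], "size")
    leaves[[i]] <- c(child(m[i, 1], "leaves"), child(m[i, 2], "leaves"))
    hh <- sort(c(child(m[i, 1], "low"), child(m[i, 2], "low"), h[i]))
    low_h[[i]] <- hh[seq_len(min(keep, length(hh)))]
  }
  list(size = size, leaves = leaves, low_h = low_h)
}

# Mean join height of a branch's core (the first core_size leaves merged).
node_core_scatter <- function(node, info, core_size) {
  if (node < 0) return(0)
  hh <- info$low_h[[node]]
  mean(hh[seq_len(min(length(hh), max(core_size - 1L, 1L)))])
}

node_size <- function(node, info) if (node < 0) 1L else info$size[node]
node_leaves <- function(node, info) if (node < 0) -node else info$leaves[[node]]
node_height <- function(node, h) if (node < 0) 0 else h[node]

#' Hybrid dynamic tree cut
#'
#' Identifies modules as dendrogram branches below `cut_height` that are
#' distinct from their surroundings: branch core scatter at most a
#' `deep_split`-controlled fraction of the cut-height range, and a join gap
#' to the enclosing branch of at least the complementary minimum gap.
#' Branches are explored top-down; small offshoots met on the way become
#' strays, and a branch whose two halves are not each distinct is kept
#' whole. Clusters smaller than `min_size` are dissolved. With `pam_stage`,
#' each stray gene is assigned to the nearest cluster by average
#' dissimilarity when it lies within that cluster's radius (the largest
#' member-averaged dissimilarity); remaining genes get label 0.
#'
#' @param dendrogram `hclust` tree from [average_linkage()].
#' @param dissimilarity The matrix the tree was built from.
#' @param deep_split Split sensitivity, 0 (coarse) to 3 (fine).
#' @param cut_height Maximum join height considered part of any module.
#' @param min_size Minimum module size.
#' @param pam_stage Reassign stray genes to near-enough clusters?
#' @return A `module_partition`: integer labels per gene (0 = unassigned),
#'   color names, and the parameters used.
#' @export
hybrid_dynamic_cut <- function(dendrogram, dissimilarity, deep_split = 1L,
                               cut_height = 0.99, min_size = 27L,
                               pam_stage = TRUE) {
  if (cut_height <= 0 || cut_height > max(1, max(dendrogram$height)))
    stop_coexdiff("cut_height must lie in (0, max tree height]")
  assert_square_symmetric(dissimilarity, "dissimilarity")
  n <- length(dendrogram$order)
  if (n != nrow(dissimilarity))
    stop_coexdiff("dendrogram and dissimilarity disagree on gene count")
  gene_ids <- dendrogram$labels %||% rownames(dissimilarity) %||%
    as.character(seq_len(n))

  h <- dendrogram$height
  m <- dendrogram$merge
  mcs_frac <- deep_split_params(deep_split)
  info <- subtree_summaries(dendrogram, core_size = as.integer(min_size))

  distinct <- function(node, attach_h) {
    if (node_size(node, info) < min_size) return(FALSE)
    lo <- if (node > 0) info$low_h[[node]][1] else 0
    rng <- attach_h - lo
    if (rng <= 0) return(FALSE)
    node_core_scatter(node, info, min_size) <= lo + mcs_frac * rng &&
      (attach_h - node_height(node, h)) >= (1 - mcs_frac) * 0.75 * rng
  }

  # Recursive branch exploration; returns list(clusters = list of leaf
  # vectors, strays = leaf vector).
  explore <- function(node, attach_h) {
    sz <- node_size(node, info)
    if (sz < min_size)
      return(list(clusters = list(), strays = node_leaves(node, info)))
    if (node > 0) {
      l <- m[node, 1]; r <- m[node, 2]
      sl <- node_size(l, info); sr <- node_size(r, info)
      if (sl >= min_size && sr >= min_size) {
        res_l <- explore(l, h[node])
        res_r <- explore(r, h[node])
        combined <- list(clusters = c(res_l$clusters, res_r$clusters),
                         strays = c(res_l$strays, res_r$strays))
        if (length(combined$clusters)) return(combined)
      } else if (sl >= min_size || sr >= min_size) {
        # The small side is an offshoot, not a real boundary: the big side
        # keeps the enclosing attachment height for its gap. When the big
        # side carries a single cluster and this whole branch is itself
        # distinct, prefer the whole branch (absorb the offshoots).
        big <- if (sl >= sr) l else r
        small <- if (sl >= sr) r else l
        res <- explore(big, attach_h)
        if (length(res$clusters) == 1L && distinct(node, attach_h))
          return(list(clusters = list(node_leaves(node, info)),
                      strays = integer(0)))
        if (length(res$clusters))
          return(list(clusters = res$clusters,
                      strays = c(res$strays, node_leaves(small, info))))
      }
    }
    if (distinct(node, attach_h))
      list(clusters = list(node_leaves(node, info)), strays = integer(0))
    else
      list(clusters = list(), strays = node_leaves(node, info))
  }

  # Static branches: maximal merges at or below the cut height.
  parent <- integer(nrow(m))
  for (i in seq_len(nrow(m))) for (j in 1:2)
    if (m[i, j] > 0) parent[m[i, j]] <- i
  below <- which(h <= cut_height)
  tops <- below[vapply(below, function(i)
    parent[i] == 0L || h[parent[i]] > cut_height, logical(1))]

  clusters <- list()
  strays <- integer(0)
  for (t in tops) {
    attach_h <- if (parent[t] > 0L) h[parent[t]] else cut_height
    res <- explore(t, attach_h)
    clusters <- c(clusters, res$clusters)
    strays <- c(strays, res$strays)
  }
  in_any <- c(unlist(clusters), strays)
  strays <- c(strays, setdiff(seq_len(n), in_any))  # leaves above the cut

  # Trim outlying members: a gene whose average dissimilarity to the rest
  # of its cluster lies above the Tukey upper fence of the cluster's
  # member-dissimilarity distribution is returned to the strays. Clusters
  # falling below min_size afterwards are dissolved.
  kept <- list()
  for (cl in clusters) {
    di <- colSums(dissimilarity[cl, cl, drop = FALSE]) / (length(cl) - 1L)
    q <- stats::quantile(di, c(0.25, 0.75), names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    out <- di > fence
    strays <- c(strays, cl[out])
    cl <- cl[!out]
    if (length(cl) >= min_size) kept[[length(kept) + 1L]] <- cl
    else strays <- c(strays, cl)
  }
  clusters <- kept

  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k

  if (pam_stage && length(clusters) && length(strays)) {
    radius <- vapply(clusters, function(cl) {
      if (length(cl) < 2L) return(0)
      max(colSums(dissimilarity[cl, cl, drop = FALSE]) / (length(cl) - 1L))
    }, numeric(1))
    for (g in strays) {
      avg <- vapply(clusters, function(cl)
        mean(dissimilarity[g, cl]), numeric(1))
      k <- which.min(avg)
      if (avg[k] <= radius[k]) labels[g] <- k
    }
  }

  # Relabel by decreasing size (ties by first occurrence).
  nz <- labels[labels > 0]
  if (length(nz)) {
    sizes <- table(nz)
    new_order <- as.integer(names(sort(sizes, decreasing = TRUE)))
    remap <- integer(max(new_order))
    remap[new_order] <- seq_along(new_order)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  names(labels) <- gene_ids

  assign_colors(structure(
    list(labels = labels, colors = NULL,
         params = list(deep_split = deep_split, cut_height = cut_height,
                       min_size = min_size, pam_stage = pam_stage)),
    class = "module_partition"
  ))
}

# WGCNA-convention module color sequence (largest module first).
module_color_sequence <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

#' Assign color names to modules by decreasing size
#'
#' Module labels, ordered by decreasing size, receive names from the fixed
#' conventional color list; label 0 is always "grey". Beyond the list,
#' modules are named `module_<k>`.
#'
#' @param partition A `module_partition`.
#' @return The partition with its `colors` map filled in.
#' @export
assign_colors <- function(partition) {
  labels <- partition$labels
  nz <- sort(unique(labels[labels > 0]))
  pal <- module_color_sequence()
  sizes <- vapply(nz, function(k) sum(labels == k), integer(1))
  ord <- nz[order(-sizes, nz)]
  cols <- character(length(ord))
  cols[seq_along(ord)] <- ifelse(seq_along(ord) <= length(pal),
                                 pal[seq_along(ord)],
                                 paste0("module_", seq_along(ord)))
  colors <- stats::setNames(c("grey", cols), c("0", as.character(ord)))
  partition$colors <- colors
  partition
}

#' @export
print.module_partition <- function(x, ...) {
  nz <- x$labels[x$labels > 0]
  cat("Module partition: ", length(unique(nz)), " modules over ",
      length(x$labels), " genes (", sum(x$labels == 0), " unassigned)\n",
      sep = "")
  invisible(x)
}

#' Sizes of the nonzero modules of a partition
#' @param partition A `module_partition`.
#' @return Named integer vector, module label -> size.
#' @export
module_sizes <- function(partition) {
  nz <- partition$labels[partition$labels > 0]
  if (!length(nz)) return(stats::setNames(integer(0), character(0)))
  tab <- table(nz)
  stats::setNames(as.integer(tab), names(tab))
}

#' Genes belonging to one module
#' @param partition A `module_partition`.
#' @param label Module label (integer) or color name.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(partition, label) {
  if (is.character(label) && is.na(suppressWarnings(as.integer(label)))) {
    hit <- names(partition$colors)[partition$colors == label]
    if (!length(hit)) stop_coexdiff("unknown module color: ", label)
    label <- as.integer(hit[1])
  }
  names(partition$labels)[partition$labels == as.integer(label)]
}

standardize_genes <- function(expr) {
  n <- ncol(expr)
  mu <- rowMeans(expr)
  sd_pop <- sqrt(rowSums((expr - mu)^2) / n)   # population denominator
  if (any(sd_pop == 0))
    stop_coexdiff("zero-variance genes cannot be standardized")
  (expr - mu) / sd_pop
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of its
#' per-gene standardized expression (genes x samples): the unit-norm sample
#' direction capturing the most variance. Signs are aligned so each
#' eigengene correlates nonnegatively with the module's mean standardized
#' expression.
#'
#' @param expr Expression matrix covering the partition's genes.
#' @param partition A `module_partition` (label 0 is skipped).
#' @return An `eigengene_set`: `eigengenes` (samples x modules matrix with
#'   column names `ME<label>`), `var_explained` per module, `labels` used.
#' @export
module_eigengenes <- function(expr, partition) {
  assert_expression_matrix(expr)
  labs <- sort(unique(partition$labels[partition$labels > 0]))
  if (!length(labs)) stop_coexdiff("partition has no modules")
  me <- matrix(NA_real_, ncol(expr), length(labs),
               dimnames = list(colnames(expr), paste0("ME", labs)))
  ve <- stats::setNames(numeric(length(labs)), paste0("ME", labs))
  for (i in seq_along(labs)) {
    genes <- module_genes(partition, labs[i])
    x <- standardize_genes(expr[genes, , drop = FALSE])
    sv <- svd(x)
    v1 <- sv$v[, 1]
    if (sum(v1 * colMeans(x)) < 0) v1 <- -v1
    me[, i] <- v1
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, var_explained = ve, labels = labs),
            class = "eigengene_set")
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module
#' eigengene.
#'
#' @param expr Expression matrix.
#' @param eigengenes An `eigengene_set` computed on the same samples.
#' @return Gene x module matrix of correlations in [-1, 1].
#' @export
kme <- function(expr, eigengenes) {
  assert_expression_matrix(expr)
  me <- eigengenes$eigengenes
  if (!identical(rownames(me), colnames(expr)))
    stop_coexdiff("eigengenes were computed on different samples")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0))
    stop_coexdiff("zero-variance genes: ",
                  paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  stats::cor(t(expr), me)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity (1 - correlation) is below `dissim_threshold`, recomputing
#' eigengenes after each merge. A threshold of 0 disables merging.
#'
#' @param expr Expression matrix.
#' @param partition A `module_partition`.
#' @param dissim_threshold Eigengene dissimilarity below which to merge.
#' @return The (possibly) merged `module_partition`, relabeled by size.
#' @export
merge_similar_modules <- function(expr, partition, dissim_threshold = 0) {
  if (dissim_threshold < 0)
    stop_coexdiff("dissim_threshold must be nonnegative")
  if (dissim_threshold == 0) return(partition)
  labels <- partition$labels
  repeat {
    labs <- sort(unique(labels[labels > 0]))
    if (length(labs) < 2L) break
    tmp <- partition; tmp$labels <- labels
    me <- module_eigengenes(expr, tmp)$eigengenes
    dis <- 1 - stats::cor(me)
    diag(dis) <- Inf
    if (min(dis) >= dissim_threshold) break
    idx <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    keep <- labs[min(idx)]; drop <- labs[max(idx)]
    labels[labels == drop] <- keep
  }
  # compact labels by size and refresh colors
  out <- partition
  out$labels <- labels
  nz <- labels[labels > 0]
  if (length(nz)) {
    sizes <- table(nz)
    new_order <- as.integer(names(sort(sizes, decreasing = TRUE)))
    remap <- integer(max(new_order)); remap[new_order] <- seq_along(new_order)
    out$labels[labels > 0] <- remap[nz]
  }
  assign_colors(out)
}
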