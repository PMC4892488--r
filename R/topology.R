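# Per-module graph export and differential betweenness centrality: the
# module graphs are thresholded TOM (or adjacency) submatrices turned into
# undirected unweighted graphs; genes are ranked by the change in
# betweenness between the reference- and test-condition graphs.

#' Threshold achieving a target edge density
#'
#' Smallest matrix value that, used as an inclusive edge threshold, keeps
#' the graph's edge density at or below `max_density`.
#'
#' @param mat Symmetric matrix restricted to the module.
#' @param max_density Maximum fraction of possible edges (default 0.15).
#' @return A single threshold value.
#' @export
density_threshold <- function(mat, max_density = 0.15) {
  vals <- sort(mat[upper.tri(mat)], decreasing = TRUE)
  n_keep <- floor(max_density * length(vals))
  if (n_keep < 1L) return(max(vals) + .Machine$double.eps)
  vals[n_keep]
}

#' Build an unweighted module graph from a network matrix
#'
#' Edge (i, j) exists iff the chosen source matrix value is at least
#' `threshold`; isolated nodes are retained so betweenness tables cover the
#' whole module.
#'
#' @param network `coexpression_network`.
#' @param module_genes Character vector of gene ids in the network.
#' @param source Which matrix to threshold: `"tom"` (default) or
#'   `"adjacency"`.
#' @param threshold Absolute edge threshold in (0, 1); `NULL` picks the
#'   per-module [density_threshold()].
#' @param max_density Target edge density when threshold is automatic.
#' @return An [igraph::graph] with a `threshold` graph attribute.
#' @export
build_module_graph <- function(network, module_genes,
                               source = c("tom", "adjacency"),
                               threshold = NULL, max_density = 0.15) {
  source <- match.arg(source)
  if (!all(module_genes %in% network$gene_ids))
    stop_coexdiff("module genes missing from the network")
  mat <- network[[source]][module_genes, module_genes]
  if (is.null(threshold)) {
    threshold <- density_threshold(mat, max_density)
  } else if (threshold <= 0 || threshold >= 1) {
    stop_coexdiff("threshold must lie strictly between 0 and 1")
  }
  adj <- (mat >= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g <- igraph::set_graph_attr(g, "source", source)
  g
}

#' Betweenness centrality of module genes
#'
#' Unnormalized betweenness on the unweighted undirected graph: for each
#' unordered pair (s, t), node v earns the fraction of shortest s-t paths
#' passing through it; disconnected pairs contribute nothing.
#'
#' @param graph An igraph graph from [build_module_graph()].
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, weights = NA)
}

#' Differential betweenness table across conditions
#'
#' Takes the union of the two gene sets (genes absent from one graph score
#' 0 there and are flagged), ranks genes in each condition by decreasing
#' betweenness (ties by gene id), and sorts by decreasing |delta_bc|.
#'
#' @param ref_bc,test_bc Named numeric betweenness vectors.
#' @return A `centrality_table` data.frame: gene, bc_reference, bc_test,
#'   rank_reference, rank_test, delta_bc, delta_rank, absent_reference,
#'   absent_test.
#' @export
differential_bc <- function(ref_bc, test_bc) {
  genes <- sort(union(names(ref_bc), names(test_bc)))
  if (!length(genes)) stop_coexdiff("no genes in either betweenness vector")
  br <- stats::setNames(rep(0, length(genes)), genes)
  bt <- br
  br[names(ref_bc)] <- ref_bc
  bt[names(test_bc)] <- test_bc
  rank_desc <- function(x) {
    ord <- order(-x, names(x))
    r <- integer(length(x)); r[ord] <- seq_along(x)
    stats::setNames(r, names(x))
  }
  rr <- rank_desc(br); rt <- rank_desc(bt)
  out <- data.frame(
    gene = genes,
    bc_reference = unname(br), bc_test = unname(bt),
    rank_reference = unname(rr), rank_test = unname(rt),
    delta_bc = unname(bt - br),
    delta_rank = unname(rr - rt),
    absent_reference = !(genes %in% names(ref_bc)),
    absent_test = !(genes %in% names(test_bc))
  )
  out <- out[order(-abs(out$delta_bc), out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Differential betweenness analysis of one module
#'
#' Builds the module graph in both conditions, computes betweenness in
#' each, and returns the differential table with the thresholds used as
#' attributes.
#'
#' @param reference,test `coexpression_network` objects.
#' @param module_genes Character vector of module gene ids.
#' @param ... Passed to [build_module_graph()].
#' @return A `centrality_table` with `graph_reference`, `graph_test`
#'   attributes.
#' @export
module_centrality <- function(reference, test, module_genes, ...) {
  g_ref <- build_module_graph(reference, module_genes, ...)
  g_test <- build_module_graph(test, module_genes, ...)
  tab <- differential_bc(betweenness_centrality(g_ref),
                         betweenness_centrality(g_test))
  attr(tab, "graph_reference") <- g_ref
  attr(tab, "graph_test") <- g_test
  tab
}

#' Export a module graph
#'
#' GraphML (via igraph) or a plain two-column tab-separated edge list
#' compatible with interactive viewers.
#'
#' @param graph An igraph graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return The path, invisibly.
#' @export
write_module_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
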