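# End-to-end orchestration: presence/SAM filtering, per-condition signed
# networks, module detection on the reference network, permutation
# preservation, weak-module selection, differential betweenness, optional
# over-representation, with all tables written as TSV plus a run-metadata
# sidecar.

#' Pipeline configuration with the study's documented defaults
#'
#' @param min_fraction Presence-filter fraction (default 0.5).
#' @param sam_delta SAM selection delta (default 0.296).
#' @param sam_n_perm SAM label permutations (default 100).
#' @param candidate_betas Soft-threshold scan powers (default 1:20).
#' @param r2_cut Scale-free fit requirement (default 0.8).
#' @param shared_beta Reuse the reference network's power for the test
#'   network (default TRUE)?
#' @param deep_split,cut_height,min_size,pam_stage Hybrid tree-cut
#'   parameters (defaults 1, 0.99, 27, TRUE).
#' @param merge_threshold Eigengene-dissimilarity merge threshold (default
#'   0: merging off).
#' @param preservation_n_perm Preservation permutations (default 200).
#' @param preservation_cutoff Zsummary selection cutoff (default 5).
#' @param graph_source,graph_max_density Module-graph construction policy.
#' @param min_overlap,q_cut Enrichment reporting filters (defaults 2, 0.05).
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_fraction = 0.5, sam_delta = 0.296,
                            sam_n_perm = 100L, candidate_betas = 1:20,
                            r2_cut = 0.8, shared_beta = TRUE,
                            deep_split = 1L, cut_height = 0.99,
                            min_size = 27L, pam_stage = TRUE,
                            merge_threshold = 0,
                            preservation_n_perm = 200L,
                            preservation_cutoff = 5,
                            graph_source = "tom", graph_max_density = 0.15,
                            min_overlap = 2L, q_cut = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full differential co-expression workflow
#'
#' @param expr Expression matrix over all samples (genes x samples).
#' @param groups `sample_groups` mapping every sample to one of the two
#'   conditions.
#' @param config A [pipeline_config()].
#' @param outdir Output directory; `NULL` skips all file output.
#' @param flags Optional presence-flag matrix (skips the presence filter
#'   when absent).
#' @param gene_sets Optional `gene_set_collection` (or GMT path) for
#'   over-representation of the selected modules.
#' @return Invisible list with every intermediate result: `sam`,
#'   `expr_filtered`, `network_ref`, `network_test`, `dendrogram`,
#'   `partition`, `eigengenes`, `kme`, `preservation`, `selected_modules`,
#'   `centrality` (per selected module), `enrichment` (per selected
#'   module), `config`.
#' @export
run_pipeline <- function(expr, groups, config = pipeline_config(),
                         outdir = NULL, flags = NULL, gene_sets = NULL) {
  assert_expression_matrix(expr)
  check_groups_cover(expr, groups)
  cfg <- config
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  save_tsv <- function(df, name) {
    if (!is.null(outdir)) write_tsv(df, file.path(outdir, name))
  }

  if (!is.null(flags))
    expr <- presence_filter(expr, flags, groups, cfg$min_fraction)

  sam <- sam_select(expr, groups, delta = cfg$sam_delta,
                    n_perm = cfg$sam_n_perm, seed = cfg$seed)
  expr_f <- expr[names(sam$selected)[sam$selected], , drop = FALSE]
  if (nrow(expr_f) < 10L)
    stop_coexdiff("filtering stage left fewer than 10 genes")
  save_tsv(data.frame(gene_id = rownames(expr_f), expr_f,
                      check.names = FALSE), "filtered_expression.tsv")

  ref_expr <- expr_f[, group_samples(groups, expr_f, "reference"),
                     drop = FALSE]
  test_expr <- expr_f[, group_samples(groups, expr_f, "test"), drop = FALSE]
  net_ref <- build_coexpression_network(ref_expr,
                                        candidate_betas = cfg$candidate_betas,
                                        r2_cut = cfg$r2_cut)
  beta_test <- if (cfg$shared_beta) net_ref$beta else NULL
  net_test <- build_coexpression_network(test_expr, beta = beta_test,
                                         candidate_betas = cfg$candidate_betas,
                                         r2_cut = cfg$r2_cut)
  if (!is.null(net_ref$scan)) save_tsv(net_ref$scan, "soft_threshold_scan.tsv")

  dend <- average_linkage(tom_dissimilarity(net_ref$tom))
  part <- hybrid_dynamic_cut(dend, tom_dissimilarity(net_ref$tom),
                             deep_split = cfg$deep_split,
                             cut_height = cfg$cut_height,
                             min_size = cfg$min_size,
                             pam_stage = cfg$pam_stage)
  if (cfg$merge_threshold > 0)
    part <- merge_similar_modules(ref_expr, part, cfg$merge_threshold)
  eig <- module_eigengenes(ref_expr, part)
  km <- kme(ref_expr, eig)
  own_kme <- vapply(seq_along(part$labels), function(i) {
    lab <- part$labels[i]
    if (lab == 0L) NA_real_ else km[i, paste0("ME", lab)]
  }, numeric(1))
  save_tsv(data.frame(gene_id = names(part$labels),
                      module = unname(part$labels),
                      color = unname(part$colors[as.character(part$labels)]),
                      kme_own = own_kme), "module_partition.tsv")

  pres <- module_preservation(net_ref, net_test, part, test_expr,
                              n_perm = cfg$preservation_n_perm,
                              seed = cfg$seed)
  save_tsv(pres, "preservation.tsv")
  selected <- select_weak_modules(pres, cfg$preservation_cutoff)
  if (!is.null(outdir))
    writeLines(selected, file.path(outdir, "selected_modules.txt"))

  centrality <- list()
  for (mod in selected) {
    genes <- module_genes(part, mod)
    tab <- module_centrality(net_ref, net_test, genes,
                             source = cfg$graph_source,
                             max_density = cfg$graph_max_density)
    centrality[[mod]] <- tab
    rounded <- tab
    rounded$bc_reference <- round(rounded$bc_reference, 2)
    rounded$bc_test <- round(rounded$bc_test, 2)
    rounded$delta_bc <- round(rounded$delta_bc, 2)
    save_tsv(rounded, paste0("centrality_", mod, ".tsv"))
    if (!is.null(outdir)) {
      gdir <- file.path(outdir, "graphs")
      dir.create(gdir, showWarnings = FALSE)
      write_module_graph(attr(tab, "graph_reference"),
                         file.path(gdir, paste0(mod, "_reference.graphml")))
      write_module_graph(attr(tab, "graph_test"),
                         file.path(gdir, paste0(mod, "_test.graphml")))
      write_module_graph(attr(tab, "graph_reference"),
                         file.path(gdir, paste0(mod, "_reference_edges.tsv")),
                         format = "edgelist")
      write_module_graph(attr(tab, "graph_test"),
                         file.path(gdir, paste0(mod, "_test_edges.tsv")),
                         format = "edgelist")
    }
  }

  enrichment <- list()
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    for (mod in selected) {
      res <- hypergeometric_enrichment(module_genes(part, mod),
                                       rownames(expr_f), gene_sets,
                                       min_overlap = cfg$min_overlap,
                                       q_cut = cfg$q_cut)
      enrichment[[mod]] <- res
      save_tsv(res, paste0("enrichment_", mod, ".tsv"))
    }
  } else {
    message("NOTE: no gene sets supplied; enrichment stage skipped")
  }

  if (!is.null(outdir)) {
    meta <- data.frame(
      key = c("seed", "n_genes_input", "n_genes_analysis", "beta",
              "sam_delta", "deep_split", "cut_height", "min_size",
              "pam_stage", "merge_threshold", "preservation_n_perm",
              "preservation_cutoff", "graph_source", "graph_max_density",
              "n_modules", "selected_modules"),
      value = c(cfg$seed, nrow(expr), nrow(expr_f), net_ref$beta,
                cfg$sam_delta, cfg$deep_split, cfg$cut_height, cfg$min_size,
                cfg$pam_stage, cfg$merge_threshold, cfg$preservation_n_perm,
                cfg$preservation_cutoff, cfg$graph_source,
                cfg$graph_max_density, length(module_sizes(part)),
                paste(selected, collapse = ";")))
    write_tsv(meta, file.path(outdir, "run_metadata.tsv"))
  }

  invisible(list(sam = sam, expr_filtered = expr_f, network_ref = net_ref,
                 network_test = net_test, dendrogram = dend,
                 partition = part, eigengenes = eig, kme = km,
                 preservation = pres, selected_modules = selected,
                 centrality = centrality, enrichment = enrichment,
                 config = cfg))
}
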