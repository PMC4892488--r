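# Over-representation analysis of module gene sets against pathway
# collections: one-sided hypergeometric p-values with Benjamini-Hochberg
# correction within each module's test batch.

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#' Duplicate set names are rejected; duplicate genes within a set are
#' dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_coexdiff("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop_coexdiff("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(seq_along(fields), function(i) {
    g <- fields[[i]][-(1:2)]
    if (anyDuplicated(g)) {
      log_warn("set ", nm[i], ": dropped ", sum(duplicated(g)),
               " duplicate gene entries")
      g <- unique(g)
    }
    g
  })
  names(sets) <- nm
  structure(sets, descriptions = stats::setNames(
    vapply(fields, `[[`, character(1), 2L), nm),
    class = "gene_set_collection")
}

#' Hypergeometric over-representation of a module in gene sets
#'
#' Each set is intersected with the background; the one-sided upper-tail
#' hypergeometric p-value is the probability of an overlap at least as
#' large as observed when drawing `|module|` genes from the background.
#' p-values are BH-corrected across all tested sets, then results filtered
#' to overlap >= `min_overlap` and q < `q_cut`, sorted by p.
#'
#' @param module_genes Character vector (must lie within `background`).
#' @param background Character vector: the gene universe.
#' @param sets A `gene_set_collection` (or plain named list).
#' @param min_overlap Minimum overlap to report (default 2).
#' @param q_cut BH q-value cutoff (default 0.05).
#' @return Data.frame: set, description, overlap, set_size, p_value,
#'   q_value, genes (semicolon-joined). The unfiltered table is attached as
#'   attribute `full`.
#' @export
hypergeometric_enrichment <- function(module_genes, background, sets,
                                      min_overlap = 2L, q_cut = 0.05) {
  if (!length(background)) stop_coexdiff("empty background universe")
  background <- unique(background)
  if (!all(module_genes %in% background))
    stop_coexdiff("module genes must be a subset of the background")
  module_genes <- unique(module_genes)
  descr <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  trimmed <- lapply(sets, intersect, background)
  tested <- names(trimmed)[lengths(trimmed) > 0]
  n_bg <- length(background)
  n_mod <- length(module_genes)
  rows <- lapply(tested, function(s) {
    members <- trimmed[[s]]
    hit <- intersect(module_genes, members)
    k <- length(hit)
    p <- stats::phyper(k - 1L, length(members), n_bg - length(members),
                       n_mod, lower.tail = FALSE)
    data.frame(set = s, description = unname(descr[s]),
               overlap = k, set_size = length(members), p_value = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  full <- do.call(rbind, rows)
  if (is.null(full))
    return(data.frame(set = character(0), description = character(0),
                      overlap = integer(0), set_size = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      genes = character(0)))
  full$q_value <- stats::p.adjust(full$p_value, method = "BH")
  full <- full[order(full$p_value, full$set),
               c("set", "description", "overlap", "set_size",
                 "p_value", "q_value", "genes")]
  rownames(full) <- NULL
  out <- full[full$overlap >= min_overlap & full$q_value < q_cut, ]
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}
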