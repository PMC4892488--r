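# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_coexdiff <- function(..., class = "coexdiff_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_expression_matrix <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_coexdiff(arg, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_coexdiff(arg, " must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop_coexdiff(arg, " has duplicated gene identifiers")
  if (anyDuplicated(colnames(expr)))
    stop_coexdiff(arg, " has duplicated sample identifiers")
  invisible(expr)
}

assert_square_symmetric <- function(m, arg = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_coexdiff(arg, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop_coexdiff(arg, " must be symmetric")
  invisible(m)
}

# Two-condition sample map. Stored as a named character vector
# sample_id -> condition, with attributes naming the reference and test
# labels so downstream stages never guess the direction of contrasts.
sample_groups <- function(sample_ids, conditions, reference, test) {
  if (length(sample_ids) != length(conditions))
    stop_coexdiff("sample_ids and conditions differ in length")
  if (anyDuplicated(sample_ids))
    stop_coexdiff("duplicated sample identifiers in group map")
  labs <- unique(conditions)
  if (missing(reference)) reference <- labs[1]
  if (missing(test)) test <- setdiff(labs, reference)[1]
  if (!all(labs %in% c(reference, test)))
    stop_coexdiff("group map contains conditions beyond the two declared: ",
                  paste(setdiff(labs, c(reference, test)), collapse = ", "))
  g <- stats::setNames(as.character(conditions), sample_ids)
  attr(g, "reference") <- reference
  attr(g, "test") <- test
  class(g) <- "sample_groups"
  g
}

group_samples <- function(groups, expr = NULL, which = c("reference", "test")) {
  which <- match.arg(which)
  ids <- names(groups)[groups == attr(groups, which)]
  if (!is.null(ids) && !is.null(expr)) ids <- intersect(colnames(expr), ids)
  ids
}

check_groups_cover <- function(expr, groups, min_per_group = 3L) {
  missing_samples <- setdiff(colnames(expr), names(groups))
  if (length(missing_samples))
    stop_coexdiff("samples without a condition label: ",
                  paste(utils::head(missing_samples, 5), collapse = ", "))
  for (w in c("reference", "test")) {
    n <- length(group_samples(groups, expr, w))
    if (n < min_per_group)
      stop_coexdiff("condition '", attr(groups, w), "' has ", n,
                    " samples in the matrix; need at least ", min_per_group)
  }
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

log_warn <- function(...) {
  message("WARN: ", ...)
}
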