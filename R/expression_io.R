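#' Read a genes-by-samples expression table
#'
#' Parses a tab-separated expression matrix: first row sample identifiers,
#' first column gene identifiers, remaining cells numeric (log-scale)
#' expression values. Duplicate gene or sample identifiers and ragged rows
#' are rejected with an error naming the offender.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (genes x samples) with gene rownames and sample
#'   colnames.
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop_coexdiff("no data rows in ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) == 0L)
    stop_coexdiff("malformed header: no sample columns in ", path)
  if (anyDuplicated(sample_ids))
    stop_coexdiff("duplicated sample identifier: ",
                  sample_ids[duplicated(sample_ids)][1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  bad <- which(widths != length(header))
  if (length(bad))
    stop_coexdiff("ragged row at line ", bad[1] + 1L, ": expected ",
                  length(header), " fields, found ", widths[bad[1]])
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop_coexdiff("duplicated gene identifier: ",
                  gene_ids[duplicated(gene_ids)][1])
  vals <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(body, `[`, -1L)))),
    nrow = length(gene_ids), byrow = TRUE,
    dimnames = list(gene_ids, sample_ids)
  )
  vals
}

#' Read a sample-to-condition map
#'
#' Two-column TSV (`sample_id<TAB>condition`, header optional via
#' `header`), with exactly two condition labels.
#'
#' @param path Path to a TSV file.
#' @param reference Condition label to treat as the reference network
#'   (default: first label encountered).
#' @param header Does the file carry a header row?
#' @return A `sample_groups` object (named character vector sample -> label
#'   with `reference`/`test` attributes).
#' @export
read_sample_groups <- function(path, reference = NULL, header = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop_coexdiff("group file must have two columns: sample_id, condition")
  if (is.null(reference)) reference <- df[[2]][1]
  sample_groups(df[[1]], df[[2]], reference = reference)
}

#' Read a presence/absence flag matrix
#'
#' Same layout as the expression table. Cells may be 0/1 or Affymetrix
#' P/M/A detection calls; "P" (present) maps to `TRUE`, "M"/"A" to `FALSE`.
#'
#' @param path Path to a TSV file.
#' @return Logical matrix aligned like an expression matrix.
#' @export
read_presence_flags <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character")
  m <- as.matrix(raw)
  out <- toupper(m) == "P" | m == "1" | toupper(m) == "TRUE"
  storage.mode(out) <- "logical"
  out
}

#' Presence filter: keep genes detected in enough samples of some group
#'
#' A gene survives if, in at least one condition, the fraction of samples
#' with a present call is at least `min_fraction`. Gene order is preserved.
#'
#' @param expr Expression matrix (genes x samples).
#' @param flags Logical presence matrix of identical shape and dimnames.
#' @param groups `sample_groups` covering the samples.
#' @param min_fraction Required fraction of present calls, in (0, 1]; 0 is
#'   allowed and keeps everything.
#' @return The row-subset expression matrix.
#' @export
presence_filter <- function(expr, flags, groups, min_fraction = 0.5) {
  assert_expression_matrix(expr)
  if (!identical(dim(flags), dim(expr)) ||
      !identical(rownames(flags), rownames(expr)) ||
      !identical(colnames(flags), colnames(expr)))
    stop_coexdiff("flags are not aligned to the expression matrix")
  if (min_fraction < 0 || min_fraction > 1)
    stop_coexdiff("min_fraction must be in [0, 1]")
  keep <- rep(FALSE, nrow(expr))
  for (w in c("reference", "test")) {
    ids <- group_samples(groups, expr, w)
    if (!length(ids)) next
    frac <- rowMeans(flags[, ids, drop = FALSE])
    keep <- keep | (frac >= min_fraction)
  }
  expr[keep, , drop = FALSE]
}
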