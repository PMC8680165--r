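#' Reference basis for kernel features
#'
#' Freezes the training cohort's per-gene mean expression, the essential-gene
#' panel, and the training fold-change matrix. Query samples are later
#' centered against these frozen means — never against the query cohort —
#' so prediction for a single unseen sample is well-defined and independent
#' of batch composition.
#'
#' @param train_expr `expr_matrix` of training samples on a log scale
#'   (`log_normalized`).
#' @param essential_genes Character vector of gene ids used for the
#'   correlation kernel (the essential-gene panel).
#' @return A `reference_basis`: list with `gene_means` (named vector over all
#'   training genes), `essential_genes` (the realized intersection),
#'   `fc_ref` (essential genes x reference samples fold-change matrix) and
#'   `reference_samples`.
#' @export
fit_reference_basis <- function(train_expr, essential_genes) {
  stopifnot(inherits(train_expr, "expr_matrix"))
  if (ncol(train_expr) < 2L) {
    abort("Need at least 2 training samples to fit a reference basis.")
  }
  present <- intersect(essential_genes, rownames(train_expr))
  if (length(present) < 2L) {
    abort("Fewer than 2 essential genes present in the training matrix.")
  }
  if (length(present) < 0.5 * length(essential_genes)) {
    warn(sprintf("Only %d/%d essential genes present in the training matrix.",
                 length(present), length(essential_genes)))
  }
  dropped <- setdiff(essential_genes, present)
  if (length(dropped) > 0L && length(present) >= 0.5 * length(essential_genes)) {
    warn(sprintf("%d essential gene(s) absent from the training matrix were dropped.",
                 length(dropped)))
  }
  vals <- unclass(train_expr)
  gene_means <- rowMeans(vals)
  fc_ref <- vals[present, , drop = FALSE] - gene_means[present]
  if (any(apply(fc_ref, 2L, sd) == 0)) {
    abort("A reference sample has constant fold-change over the essential genes; correlation undefined.")
  }
  structure(list(gene_means = gene_means,
                 essential_genes = present,
                 fc_ref = fc_ref,
                 reference_samples = colnames(train_expr)),
            class = "reference_basis")
}

#' @export
print.reference_basis <- function(x, ...) {
  cat(sprintf("<reference_basis> %d reference samples, %d essential genes (of %d genes)\n",
              length(x$reference_samples), length(x$essential_genes),
              length(x$gene_means)))
  invisible(x)
}

#' Kernel features for query samples
#'
#' Projects query expression profiles into the kernel feature space x_u: each
#' query's fold-change against the frozen reference means is correlated
#' (Pearson) with every reference sample's fold-change vector over the shared
#' essential genes. Row u of the result is the feature vector x_u.
#'
#' @param query_expr `expr_matrix` of query samples on the same log scale as
#'   the training data (apply `log2(TPM + 1)` to single-cell TPM first, e.g.
#'   via [log_tpm()]).
#' @param basis A `reference_basis` from [fit_reference_basis()].
#' @return Numeric matrix, query samples x reference samples, entries in
#'   \[-1, 1\].
#' @export
compute_kernel <- function(query_expr, basis) {
  stopifnot(inherits(query_expr, "expr_matrix"),
            inherits(basis, "reference_basis"))
  shared <- intersect(basis$essential_genes, rownames(query_expr))
  if (length(shared) < 2L) {
    abort("Query shares fewer than 2 essential genes with the reference basis.")
  }
  if (length(shared) < 0.5 * length(basis$essential_genes)) {
    warn(sprintf("Query covers only %d/%d essential genes of the basis.",
                 length(shared), length(basis$essential_genes)))
  }
  fc_query <- unclass(query_expr)[shared, , drop = FALSE] -
    basis$gene_means[shared]
  const <- apply(fc_query, 2L, sd) == 0
  if (any(const)) {
    abort(sprintf("Constant fold-change vector (correlation undefined) for sample(s): %s",
                  paste(head(colnames(fc_query)[const], 5L), collapse = ", ")))
  }
  k <- cor(fc_query, basis$fc_ref[shared, , drop = FALSE])
  dimnames(k) <- list(colnames(query_expr), basis$reference_samples)
  k
}

#' Log-transform a TPM expression matrix
#'
#' Convenience bridge from linear TPM to the log scale consumed by
#' [compute_kernel()]: `log2(TPM + 1)`.
#'
#' @param expr `expr_matrix` with scale `"tpm"`.
#' @return `expr_matrix` with scale `"log_normalized"`.
#' @export
log_tpm <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_scale(expr) != "tpm") abort("`expr` must be on the TPM scale.")
  expression_matrix(log2(unclass(expr) + 1), scale = "log_normalized")
}

#' Read an essential-gene list
#'
#' @param path Plain-text file, one gene id per line.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
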