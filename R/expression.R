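#' Expression matrix carrier
#'
#' An `expr_matrix` is a numeric genes x samples matrix with a `scale` tag
#' recording the unit convention of its values: `"tpm"` (linear transcripts
#' per million, non-negative), `"log_normalized"` (log-scale normalized
#' expression, e.g. RMA or log2(TPM+1)), or `"log2_fold_change"` (log2 ratios
#' against a reference mean). Gene identifiers are row names, sample
#' identifiers column names; both must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   row and column names set.
#' @param scale One of `"tpm"`, `"log_normalized"`, `"log2_fold_change"`.
#' @return A validated `expr_matrix` object.
#' @export
expression_matrix <- function(values,
                              scale = c("tpm", "log_normalized",
                                        "log2_fold_change")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate gene ids in expression matrix.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample ids in expression matrix.")
  }
  if (scale == "tpm" && any(values < 0, na.rm = TRUE)) {
    abort("TPM-scale expression values must be non-negative.")
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "scale")))
  print(head(unclass(x)[, seq_len(min(ncol(x), 5L)), drop = FALSE], 5L))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out, scale = attr(x, "scale"),
              class = c("expr_matrix", "matrix", "array"))
  } else {
    out
  }
}

#' Scale tag of an expression matrix
#' @param x An `expr_matrix`.
#' @return The scale tag string.
#' @export
expr_scale <- function(x) attr(x, "scale")

#' Read an expression matrix from a delimited file
#'
#' Expects genes in rows and a header row of sample ids; the first column
#' holds gene ids. Duplicate gene rows are collapsed by their per-sample mean
#' with a warning, mirroring common practice for public matrices.
#'
#' @param path Path to a TSV/CSV file (delimiter auto-detected from the
#'   extension; `.csv` means comma, anything else tab).
#' @param scale Scale tag to attach; values are validated against it.
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   scale = c("tpm", "log_normalized",
                                             "log2_fold_change")) {
  scale <- match.arg(scale)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(tb) == 0L || ncol(tb) < 2L) {
    abort(sprintf("Malformed expression table '%s': need a gene-id column plus >=1 sample column and >=1 row.",
                  path))
  }
  gene_ids <- as.character(tb[[1L]])
  mat <- as.matrix(tb[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tb[-1L], is.numeric, logical(1L)))[1L]
    abort(sprintf("Malformed expression table '%s': column '%s' is not numeric.",
                  path, colnames(tb)[-1L][bad]))
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warn(sprintf("Collapsing %d duplicated gene id(s) by mean: %s",
                 length(dups), paste(head(dups, 5L), collapse = ", ")))
    mat <- rowsum(mat, group = gene_ids, reorder = FALSE)
    counts <- as.vector(table(factor(gene_ids, levels = rownames(mat))))
    mat <- mat / counts
    gene_ids <- rownames(mat)
  }
  rownames(mat) <- gene_ids
  expression_matrix(mat, scale = scale)
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column
#' (`gene_id`), one column per sample.
#'
#' @param x An `expr_matrix`.
#' @param path Output path; `.csv` writes comma-separated, else tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  tb <- tibble::as_tibble(unclass(x), rownames = "gene_id")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tb, path, delim = delim)
  invisible(path)
}

#' Quality-control filter for cells
#'
#' Removes cells with fewer than `min_reads` total reads or with a
#' mitochondrial read fraction at or above `max_mito`. Cells with exactly
#' `min_reads` reads are kept (removal is strict `<`); the mitochondrial
#' threshold is inclusive at `max_mito`.
#'
#' @param expr An `expr_matrix` (genes x cells, TPM scale).
#' @param read_counts Named numeric vector of total reads per cell.
#' @param mito_fraction Named numeric vector of mitochondrial fractions.
#' @param min_reads Minimum read count to keep a cell (default 10000).
#' @param max_mito Mitochondrial fraction at which a cell is removed
#'   (default 0.25).
#' @param max_genes Optional: remove cells expressing more than this many
#'   genes (TPM > 0). No default; `Inf` disables the check.
#' @return Filtered `expr_matrix` with attribute `removed_cells` listing the
#'   removed cell ids.
#' @export
qc_filter_cells <- function(expr, read_counts, mito_fraction,
                            min_reads = 10000, max_mito = 0.25,
                            max_genes = Inf) {
  stopifnot(inherits(expr, "expr_matrix"))
  cells <- colnames(expr)
  missing <- setdiff(cells, intersect(names(read_counts), names(mito_fraction)))
  if (length(missing) > 0L) {
    abort(sprintf("QC metrics missing for cell(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  rc <- read_counts[cells]
  mf <- mito_fraction[cells]
  n_expressed <- colSums(unclass(expr) > 0)
  drop <- rc < min_reads | mf >= max_mito | n_expressed > max_genes
  out <- expr[, !drop, drop = FALSE]
  attr(out, "removed_cells") <- cells[drop]
  out
}

#' Quality-control filter for genes
#'
#' Keeps genes with nonzero expression (TPM > 0) in at least
#' `min_cell_fraction` of cells; a gene at exactly the threshold is kept.
#'
#' @param expr An `expr_matrix` (genes x cells).
#' @param min_cell_fraction Minimum fraction of cells in which a gene must be
#'   expressed (default 0.05).
#' @return Filtered `expr_matrix`.
#' @export
qc_filter_genes <- function(expr, min_cell_fraction = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr) < 1L) abort("Expression matrix has no cells.")
  frac <- rowMeans(unclass(expr) > 0)
  expr[frac >= min_cell_fraction, , drop = FALSE]
}

#' Cell-to-cluster assignment table
#'
#' Builds the tibble linking each cell to its patient and cluster. Cluster
#' labels are opaque strings supplied by an external clustering workflow.
#'
#' @param cell_ids,patient_ids,cluster_ids Character vectors, one entry per
#'   cell.
#' @return A tibble with columns `cell_id`, `patient_id`, `cluster_id`.
#' @export
cell_cluster_table <- function(cell_ids, patient_ids, cluster_ids) {
  tb <- tibble::tibble(cell_id = as.character(cell_ids),
                       patient_id = as.character(patient_ids),
                       cluster_id = as.character(cluster_ids))
  if (anyDuplicated(tb$cell_id)) abort("Duplicate cell ids in cluster table.")
  if (any(!nzchar(tb$cluster_id)) || any(is.na(tb$cluster_id))) {
    abort("Cluster labels must be non-empty strings.")
  }
  tb
}

#' Read a cell-cluster table from CSV
#'
#' @param path CSV with columns `cell_id`, `patient_id`, `cluster_id`.
#' @return A validated cluster tibble.
#' @export
read_cell_clusters <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "patient_id", "cluster_id")
  if (!all(need %in% names(tb))) {
    abort(sprintf("Cluster table '%s' must have columns: %s",
                  path, paste(need, collapse = ", ")))
  }
  cell_cluster_table(tb$cell_id, tb$patient_id, tb$cluster_id)
}

#' Clonal composition of a patient sample
#'
#' Summarizes a patient's cells into clusters: the fraction of cells in each
#' cluster and the cluster's mean expression profile (arithmetic mean of TPM
#' across its cells).
#'
#' @param expr An `expr_matrix` of cells (TPM scale).
#' @param clusters A cell-cluster tibble (see [cell_cluster_table()]).
#' @param patient_id Patient whose cells to summarize.
#' @return A `clonal_composition` object: list with `patient_id`, `gene_ids`,
#'   and `clusters` — a tibble with columns `cluster_id`, `n_cells`,
#'   `fraction`, and a list-column `mean_profile` of named numeric vectors.
#' @export
build_clonal_composition <- function(expr, clusters, patient_id) {
  stopifnot(inherits(expr, "expr_matrix"))
  pc <- clusters[clusters$patient_id == patient_id, , drop = FALSE]
  if (nrow(pc) == 0L) abort(sprintf("Patient '%s' has zero cells.", patient_id))
  missing <- setdiff(pc$cell_id, colnames(expr))
  if (length(missing) > 0L) {
    abort(sprintf("Cells of patient '%s' absent from expression matrix: %s",
                  patient_id, paste(head(missing, 5L), collapse = ", ")))
  }
  split_cells <- split(pc$cell_id, pc$cluster_id)
  cl <- tibble::tibble(
    cluster_id = names(split_cells),
    n_cells = unname(lengths(split_cells)),
    fraction = unname(lengths(split_cells)) / nrow(pc),
    mean_profile = purrr::map(split_cells, function(ids) {
      rowMeans(unclass(expr)[, ids, drop = FALSE])
    })
  )
  structure(list(patient_id = patient_id, gene_ids = rownames(expr),
                 clusters = cl),
            class = "clonal_composition")
}

#' @export
print.clonal_composition <- function(x, ...) {
  cat(sprintf("<clonal_composition> patient '%s': %d cluster(s), %d genes\n",
              x$patient_id, nrow(x$clusters), length(x$gene_ids)))
  print(x$clusters[, c("cluster_id", "n_cells", "fraction")])
  invisible(x)
}

#' Validate a clonal composition
#' @param x A `clonal_composition`.
#' @return `x`, invisibly; aborts if fractions do not sum to 1 or a profile
#'   is inconsistent with the gene axis.
#' @export
validate_clonal_composition <- function(x) {
  stopifnot(inherits(x, "clonal_composition"))
  if (abs(sum(x$clusters$fraction) - 1) > 1e-9) {
    abort("Cluster fractions must sum to 1.")
  }
  if (any(x$clusters$fraction <= 0)) abort("Cluster fractions must be > 0.")
  ok <- vapply(x$clusters$mean_profile,
               function(p) identical(names(p), x$gene_ids), logical(1L))
  if (!all(ok)) abort("Cluster mean profiles disagree on the gene axis.")
  invisible(x)
}

#' Pseudo-bulk profile of a set of cells
#'
#' Per-gene arithmetic mean of TPM across cells — the patient-level proxy for
#' a bulk expression profile.
#'
#' @param expr An `expr_matrix` (TPM scale).
#' @param cell_ids Cells to average; default all columns.
#' @return Named numeric vector over genes.
#' @export
pseudo_bulk <- function(expr, cell_ids = colnames(expr)) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(cell_ids) < 1L) abort("pseudo_bulk needs at least one cell.")
  missing <- setdiff(cell_ids, colnames(expr))
  if (length(missing) > 0L) {
    abort(sprintf("Unknown cell id(s): %s", paste(head(missing, 5L), collapse = ", ")))
  }
  rowMeans(unclass(expr)[, cell_ids, drop = FALSE])
}
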