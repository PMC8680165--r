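#' Read gene sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways()` with validation: every set must
#' be non-empty and member ids unique within a set.
#'
#' @param path GMT file (set name, description, tab-separated member ids).
#' @return Named list of character vectors (one per set).
#' @export
read_gene_sets <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("Reading GMT files requires the fgsea package.")
  }
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) abort(sprintf("No gene sets found in '%s'.", path))
  sets <- purrr::map(sets, unique)
  if (any(lengths(sets) == 0L)) abort("GMT file contains an empty gene set.")
  sets
}

#' Pathway activity scores
#'
#' Activity of a pathway in a sample is the sum of the sample's log2
#' fold-change values over the pathway's member genes present in the
#' matrix. Per-set coverage (fraction of members present) is recorded.
#'
#' @param fc `expr_matrix` on the `log2_fold_change` scale (genes x
#'   samples), e.g. expression centered on the reference means of a
#'   [fit_reference_basis()].
#' @param sets Named list of gene-id vectors (see [read_gene_sets()]).
#' @return A `pathway_activity` object: list with `activity` (sets x
#'   samples matrix, `NA` rows for sets with no member present, with a
#'   warning) and `coverage` tibble (`set_name`, `n_members`, `n_present`,
#'   `coverage`).
#' @export
pathway_activity <- function(fc, sets) {
  stopifnot(inherits(fc, "expr_matrix"))
  if (expr_scale(fc) != "log2_fold_change") {
    abort("`fc` must be on the log2_fold_change scale.")
  }
  vals <- unclass(fc)
  act <- matrix(NA_real_, length(sets), ncol(vals),
                dimnames = list(names(sets), colnames(vals)))
  present <- purrr::map(sets, intersect, rownames(vals))
  for (k in seq_along(sets)) {
    if (length(present[[k]]) > 0L) {
      act[k, ] <- colSums(vals[present[[k]], , drop = FALSE])
    }
  }
  empty <- names(sets)[lengths(present) == 0L]
  if (length(empty) > 0L) {
    warn(sprintf("No member genes present for set(s): %s",
                 paste(head(empty, 5L), collapse = ", ")))
  }
  if (all(lengths(present) == 0L)) {
    abort("No gene set has any member present in the fold-change matrix.")
  }
  structure(list(
    activity = act,
    coverage = tibble::tibble(set_name = names(sets),
                              n_members = unname(lengths(sets)),
                              n_present = unname(lengths(present)),
                              coverage = unname(lengths(present) / lengths(sets)))
  ), class = "pathway_activity")
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat(sprintf("<pathway_activity> %d sets x %d samples (mean coverage %.0f%%)\n",
              nrow(x$activity), ncol(x$activity),
              100 * mean(x$coverage$coverage)))
  invisible(x)
}

#' Drug-pathway association by correlation
#'
#' Pearson correlation between pathway activity scores and predicted drug
#' response (cell-death fraction) across shared samples. Positive r means
#' high pathway activity accompanies increased drug sensitivity.
#'
#' @param activity A `pathway_activity` object.
#' @param predicted_death Matrix drugs x samples of predicted cell-death
#'   fractions.
#' @param adjust Apply Benjamini-Hochberg adjustment to the correlation
#'   test p-values (default `FALSE`; the raw correlations are the primary
#'   output).
#' @return Tibble with columns `drug_id`, `set_name`, `r`, `p_value`,
#'   `n_samples` (plus `p_adjusted` when `adjust = TRUE`); `r` is `NA` for
#'   constant vectors or sets without coverage.
#' @export
drug_pathway_association <- function(activity, predicted_death,
                                     adjust = FALSE) {
  stopifnot(inherits(activity, "pathway_activity"))
  shared <- intersect(colnames(activity$activity), colnames(predicted_death))
  if (length(shared) < 3L) abort("Need at least 3 shared samples.")
  act <- activity$activity[, shared, drop = FALSE]
  dth <- predicted_death[, shared, drop = FALSE]
  out <- tidyr::expand_grid(drug_id = rownames(dth),
                            set_name = rownames(act))
  res <- purrr::pmap_dfr(out, function(drug_id, set_name) {
    a <- act[set_name, ]
    h <- dth[drug_id, ]
    if (anyNA(a) || sd(a) == 0 || sd(h) == 0) {
      return(tibble::tibble(r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(a, h, method = "pearson")
    tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- dplyr::bind_cols(out, res)
  out$n_samples <- length(shared)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
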