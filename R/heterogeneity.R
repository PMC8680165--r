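#' Intra-tumor transcriptomic heterogeneity (ITTH) score
#'
#' Shannon entropy (natural log) of a cell-type or cluster composition:
#' `ITTH = -sum P_i log P_i`. Components below `min_fraction` are excluded
#' first (to suppress classification noise from rare calls) and the
#' survivors renormalized to sum to 1; a composition collapsing to a single
#' surviving type scores 0.
#'
#' @param fractions Numeric vector of non-negative fractions summing to 1
#'   (names optional).
#' @param min_fraction Exclusion threshold (default 0.05); components at
#'   exactly the threshold are kept.
#' @return Entropy in nats.
#' @export
itth_score <- function(fractions, min_fraction = 0.05) {
  if (any(fractions < 0)) abort("Composition fractions must be non-negative.")
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("Composition fractions must sum to 1.")
  }
  p <- fractions[fractions >= min_fraction]
  if (length(p) == 0L) {
    abort("All components fall below the frequency threshold; degenerate composition.")
  }
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' ITTH score from single-cell cluster assignments
#'
#' Counts a patient's cells per cluster, converts counts to fractions, and
#' scores their entropy via [itth_score()] (same exclusion threshold).
#'
#' @param clusters Cell-cluster tibble (see [cell_cluster_table()]).
#' @param patient_id Patient to score.
#' @param min_fraction Exclusion threshold passed to [itth_score()].
#' @return Entropy in nats.
#' @export
sc_itth_score <- function(clusters, patient_id, min_fraction = 0.05) {
  pc <- clusters[clusters$patient_id == patient_id, , drop = FALSE]
  if (nrow(pc) == 0L) abort(sprintf("Patient '%s' has no cells.", patient_id))
  counts <- table(pc$cluster_id)
  itth_score(as.numeric(counts) / sum(counts), min_fraction = min_fraction)
}

#' Classify samples by ITTH quartiles
#'
#' Labels each sample `low` (score strictly below the first quartile),
#' `high` (strictly above the third quartile) or `medium` otherwise.
#' Quartiles use linear interpolation (`stats::quantile` type 7); scores
#' exactly at a quartile are `medium`.
#'
#' @param scores Named numeric vector of per-sample ITTH scores (>= 4
#'   samples).
#' @return Tibble with columns `sample_id`, `itth`, `itth_class` (factor
#'   low/medium/high).
#' @export
itth_tertiles <- function(scores) {
  if (length(scores) < 4L) abort("Need at least 4 samples to form quartiles.")
  q <- quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  cls <- ifelse(scores < q[1L], "low", ifelse(scores > q[2L], "high", "medium"))
  tibble::tibble(
    sample_id = if (is.null(names(scores))) as.character(seq_along(scores))
                else names(scores),
    itth = unname(scores),
    itth_class = factor(cls, levels = c("low", "medium", "high"))
  )
}

#' ITTH scores for a sample-by-cell-type fraction table
#'
#' Tidy front end for deconvolution outputs: one row per sample, one column
#' per cell type, fractions summing to 1 per row.
#'
#' @param fractions Data frame / tibble with a `sample_id` column and
#'   numeric cell-type fraction columns.
#' @param min_fraction Exclusion threshold (default 0.05).
#' @return Tibble with `sample_id`, `itth`, and `itth_class` when >= 4
#'   samples (otherwise no class column).
#' @export
itth_from_fractions <- function(fractions, min_fraction = 0.05) {
  if (!"sample_id" %in% names(fractions)) {
    abort("`fractions` must have a sample_id column.")
  }
  mat <- as.matrix(fractions[setdiff(names(fractions), "sample_id")])
  scores <- setNames(
    apply(mat, 1L, itth_score, min_fraction = min_fraction),
    fractions$sample_id)
  if (length(scores) >= 4L) {
    itth_tertiles(scores)
  } else {
    tibble::tibble(sample_id = names(scores), itth = unname(scores))
  }
}
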