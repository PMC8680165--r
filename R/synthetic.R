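#' Synthetic cell-line drug screening panel with known ground truth
#'
#' Emulates a cell-line training panel for the recommender: latent sample
#' factors `P` (n_lines x f_true) are drawn i.i.d. Gaussian; expression is
#' emitted as `P G + noise` through a shared random gene-loading matrix `G`,
#' so transcriptomic kernel similarity between lines reflects their latent
#' proximity (the premise the model exploits); true sensitivity scores are
#' `s_true = b_Q + Q t(P)` and observed scores add Gaussian response noise
#' and a missingness mask. Each drug's maximum tested dosage is placed at a
#' quantile of its true score distribution so both response classes are
#' populated.
#'
#' @param n_lines,n_drugs,n_genes Panel dimensions.
#' @param f_true Latent dimension of the generating model.
#' @param sigma_response SD of the Gaussian noise added to observed scores.
#' @param missing_rate Probability a drug-line pair is unobserved.
#' @param seed Seed; all output is a pure function of arguments + seed.
#' @param sigma_expr SD of the expression emission noise (default 0.1).
#' @param dose_quantile Quantile of each drug's true scores at which the
#'   maximum tested dosage is set (default 0.5).
#' @return List with `expr` (`expr_matrix`, log-normalized genes x lines),
#'   `panel` (`response_panel`), and `truth` (list: `P`, `G`, `Q`, `b_Q`,
#'   `s_true`, `sigma_response`, `seed`).
#' @export
generate_panel <- function(n_lines, n_drugs, n_genes, f_true,
                           sigma_response = 0.3, missing_rate = 0.1,
                           seed = 1L, sigma_expr = 0.1,
                           dose_quantile = 0.5) {
  if (f_true > min(n_lines, n_drugs)) {
    abort("f_true must be <= min(n_lines, n_drugs).")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1).")
  }
  set.seed(seed)
  line_ids <- sprintf("CL%03d", seq_len(n_lines))
  drug_ids <- sprintf("drug%02d", seq_len(n_drugs))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  P <- matrix(rnorm(n_lines * f_true), n_lines, f_true,
              dimnames = list(line_ids, NULL))
  G <- matrix(rnorm(f_true * n_genes), f_true, n_genes,
              dimnames = list(NULL, gene_ids))
  expr_vals <- t(P %*% G + matrix(rnorm(n_lines * n_genes, sd = sigma_expr),
                                  n_lines, n_genes))
  expr <- expression_matrix(expr_vals, scale = "log_normalized")
  Q <- matrix(rnorm(n_drugs * f_true), n_drugs, f_true,
              dimnames = list(drug_ids, NULL))
  b_Q <- setNames(rnorm(n_drugs), drug_ids)
  s_true <- sweep(Q %*% t(P), 1L, b_Q, "+")
  s_obs <- s_true + matrix(rnorm(n_drugs * n_lines, sd = sigma_response),
                           n_drugs, n_lines)
  observed <- matrix(runif(n_drugs * n_lines) >= missing_rate,
                     n_drugs, n_lines, dimnames = dimnames(s_true))
  max_dose_log2 <- apply(s_true, 1L, quantile, probs = dose_quantile,
                         type = 7, names = FALSE)
  names(max_dose_log2) <- drug_ids
  s_masked <- ifelse(observed, s_obs, NA_real_)
  dimnames(s_masked) <- dimnames(s_true)
  sens <- s_masked > max_dose_log2
  single <- vapply(seq_len(n_drugs), function(i) {
    v <- sens[i, observed[i, ]]
    length(unique(v)) < 2L
  }, logical(1L))
  if (any(single)) {
    warn(sprintf("Drug(s) with a single observed response class (consider regenerating with another seed): %s",
                 paste(drug_ids[single], collapse = ", ")))
  }
  list(expr = expr,
       panel = response_panel(s_masked, max_dose_log2, observed),
       truth = list(P = P, G = G, Q = Q, b_Q = b_Q, s_true = s_true,
                    sigma_response = sigma_response, seed = seed))
}

#' Synthetic heterogeneous patient from clonal base profiles
#'
#' Emits single-cell TPM profiles for one patient composed of `n_clusters`
#' clones: each cell is its cluster's base profile plus Gaussian noise
#' (clamped at zero to stay on the TPM scale), with optional dropout
#' zeroing. The generating composition is returned as ground truth.
#'
#' @param n_clusters Number of clones.
#' @param cells_per_cluster Cells per clone; scalar or length-`n_clusters`
#'   vector.
#' @param base_profiles Optional genes x clusters matrix of non-negative
#'   base TPM profiles; generated (exponential, mean 100 TPM) when `NULL`.
#' @param n_genes Number of genes when generating base profiles
#'   (default 200).
#' @param noise SD of the additive cell-level noise (default 0).
#' @param dropout_rate Probability an expression value is zeroed
#'   (default 0).
#' @param seed Seed.
#' @param patient_id Patient label (default "P1").
#' @return List with `expr` (`expr_matrix`, TPM, genes x cells), `clusters`
#'   (cell-cluster tibble), and `truth` (`clonal_composition` built from
#'   the base profiles and intended fractions).
#' @export
generate_heterogeneous_patient <- function(n_clusters, cells_per_cluster,
                                           base_profiles = NULL,
                                           n_genes = 200L, noise = 0,
                                           dropout_rate = 0, seed = 1L,
                                           patient_id = "P1") {
  if (n_clusters < 1L) abort("Need at least one cluster.")
  set.seed(seed)
  if (length(cells_per_cluster) == 1L) {
    cells_per_cluster <- rep(cells_per_cluster, n_clusters)
  }
  stopifnot(length(cells_per_cluster) == n_clusters)
  if (is.null(base_profiles)) {
    base_profiles <- matrix(stats::rexp(n_genes * n_clusters, rate = 0.01),
                            n_genes, n_clusters)
  }
  n_genes <- nrow(base_profiles)
  if (is.null(rownames(base_profiles))) {
    rownames(base_profiles) <- sprintf("g%04d", seq_len(n_genes))
  }
  cluster_ids <- sprintf("c%d", seq_len(n_clusters))
  colnames(base_profiles) <- cluster_ids
  n_cells <- sum(cells_per_cluster)
  cell_cluster <- rep(cluster_ids, times = cells_per_cluster)
  cell_ids <- sprintf("%s_cell%03d", patient_id, seq_len(n_cells))
  vals <- base_profiles[, cell_cluster, drop = FALSE]
  if (noise > 0) {
    vals <- pmax(vals + matrix(rnorm(n_genes * n_cells, sd = noise),
                               n_genes, n_cells), 0)
  }
  if (dropout_rate > 0) {
    vals[matrix(runif(n_genes * n_cells) < dropout_rate,
                n_genes, n_cells)] <- 0
  }
  colnames(vals) <- cell_ids
  expr <- expression_matrix(vals, scale = "tpm")
  clusters <- cell_cluster_table(cell_ids, rep(patient_id, n_cells),
                                 cell_cluster)
  true_fractions <- cells_per_cluster / n_cells
  truth <- structure(list(
    patient_id = patient_id,
    gene_ids = rownames(base_profiles),
    clusters = tibble::tibble(
      cluster_id = cluster_ids,
      n_cells = as.integer(cells_per_cluster),
      fraction = true_fractions,
      mean_profile = purrr::map(seq_len(n_clusters),
                                function(k) base_profiles[, k]))
  ), class = "clonal_composition")
  list(expr = expr, clusters = clusters, truth = truth)
}

#' Random clone mixture of dose-response curves
#'
#' Weights are symmetric Dirichlet(1); log2-IC50s uniform on \[-6, 6\]
#' (about 0.016-64 uM) and slopes uniform on \[0.5, 3\].
#'
#' @param k Number of clones.
#' @param seed Seed.
#' @return A `mixture_curve`.
#' @export
generate_mixture_curves <- function(k, seed = 1L) {
  if (k < 1L) abort("Need at least one component.")
  set.seed(seed)
  w <- stats::rgamma(k, shape = 1)
  w <- w / sum(w)
  ms <- runif(k, -6, 6)
  bs <- runif(k, 0.5, 3)
  mixture_curve(w, purrr::map2(ms, bs, dose_response_curve))
}
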