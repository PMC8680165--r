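# Shared fixtures and independent oracles. Oracles are deliberately naive
# (scalar loops, textbook formulas) and never call the code paths they check.

# Two-pass textbook Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Central finite differences of a scalar function.
numeric_gradient <- function(fn, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (fn(xp) - fn(xm)) / (2 * eps)
  }, numeric(1L))
}

# Bisection root-finder on a bracketing interval.
bisection_root <- function(g, lo, hi, tol = 1e-12, max_iter = 200L) {
  glo <- g(lo)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid; glo <- gm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Small deterministic expression fixture (genes x samples).
tiny_expr <- function(values, scale = "tpm",
                      genes = sprintf("g%d", seq_len(nrow(values))),
                      samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale = scale)
}

# A small panel + expression pair for quick training runs.
tiny_training_data <- function(n_lines = 25L, n_drugs = 4L, n_genes = 120L,
                               f_true = 2L, sigma = 0, missing = 0,
                               seed = 101L) {
  generate_panel(n_lines, n_drugs, n_genes, f_true,
                 sigma_response = sigma, missing_rate = missing, seed = seed)
}

quick_config <- function(...) {
  args <- utils::modifyList(list(f = 3L, max_epochs = 4000L,
                                 min_epochs = 4000L), list(...))
  do.call(train_config, args)
}

# A fully controlled model over three reference profiles. The reference
# kernel K is rank-deficient (fold-changes are centered across references),
# so instead of inverting it the helper fixes W_P to the first two kernel
# coordinates (f = 2) and solves, per drug, the 3x3 linear system
#   b_i + Q[i, ] . (K[r, 1], K[r, 2]) = s_target[i, r],  r = 1..3,
# so a query equal to reference r realizes s_target[i, r] exactly.
make_toy_model <- function(s_target, max_dose_log2 = NULL, seed = 5L) {
  stopifnot(ncol(s_target) == 3L)
  set.seed(seed)
  n_genes <- 30L
  vals <- matrix(rnorm(n_genes * 3L, mean = 5, sd = 2), n_genes, 3L,
                 dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                 c("ref1", "ref2", "ref3")))
  expr <- expression_matrix(vals, scale = "log_normalized")
  basis <- fit_reference_basis(expr, rownames(vals))
  K <- compute_kernel(expr, basis)
  drugs <- rownames(s_target)
  if (is.null(max_dose_log2)) {
    max_dose_log2 <- setNames(rep(0, length(drugs)), drugs)
  }
  W_P <- cbind(c(1, 0, 0), c(0, 1, 0))       # latent coords = (K[r,1], K[r,2])
  design <- cbind(1, K %*% W_P)              # rows: (1, K[r,1], K[r,2])
  theta <- t(apply(s_target, 1L, function(tr) solve(design, tr)))
  model <- structure(list(
    W_P = W_P,
    Q = unname(theta[, 2:3, drop = FALSE]),
    b_Q = setNames(theta[, 1L], drugs),
    drug_ids = drugs,
    basis = basis,
    max_dose_log2 = max_dose_log2,
    config = train_config(f = 2L),
    loss_trace = tibble::tibble(epoch = 1L, loss = 0),
    converged = TRUE
  ), class = "pharmacospace_model")
  rownames(model$Q) <- drugs
  list(model = model, ref_expr = expr, ref_profiles = vals)
}

# Clonal composition over the toy model's reference profiles.
toy_composition <- function(toy, fractions, refs = seq_along(fractions),
                            patient_id = "PT1") {
  structure(list(
    patient_id = patient_id,
    gene_ids = rownames(toy$ref_profiles),
    clusters = tibble::tibble(
      cluster_id = sprintf("c%d", seq_along(fractions)),
      n_cells = rep(1L, length(fractions)),
      fraction = fractions,
      mean_profile = lapply(refs, function(r) toy$ref_profiles[, r]))
  ), class = "clonal_composition")
}
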