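#' Training configuration for the pharmacogenomic space
#'
#' Collects the hyper-parameters of the calibrated matrix-factorization
#' model. Defaults follow the published protocol: a 10-dimensional latent
#' space trained by full-batch gradient descent at learning rate 0.01 for at
#' most 100,000 epochs, with early stopping once the relative loss change
#' over `patience` epochs falls below `tol`.
#'
#' @param f Latent dimension (default 10).
#' @param learning_rate Gradient-descent step size (default 0.01).
#' @param max_epochs Maximum number of full-batch epochs (default 100000).
#' @param l2_lambda L2 penalty on the drug matrix Q and projection W_P
#'   (biases are not penalized; default 0.01).
#' @param logistic_slope Slope l of the logistic calibration weight, in
#'   -log2-uM units (default 1).
#' @param sample_weights Optional named vector of per-sample weights d_u
#'   (default: 1 for every sample). Use [indication_weights()] to build
#'   indication-focused weights.
#' @param seed Seed for parameter initialization (default 1).
#' @param tol Relative loss-change tolerance for early stopping
#'   (default 1e-6).
#' @param patience Epoch window over which the relative change is measured
#'   (default 100).
#' @param min_epochs Burn-in before early stopping is considered (default
#'   5000); full-batch descent on the bilinear factorization crosses a flat
#'   saddle while the latent factors break symmetry, which a plain
#'   plateau rule would mistake for convergence.
#' @param optimizer `"gd"` (plain full-batch gradient descent, default) or
#'   `"adam"`.
#' @return A `train_config` list.
#' @export
train_config <- function(f = 10L, learning_rate = 0.01, max_epochs = 100000L,
                         l2_lambda = 0.01, logistic_slope = 1,
                         sample_weights = NULL, seed = 1L, tol = 1e-6,
                         patience = 100L, min_epochs = 5000L,
                         optimizer = c("gd", "adam")) {
  optimizer <- match.arg(optimizer)
  if (f < 1L) abort("Latent dimension `f` must be >= 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  if (logistic_slope <= 0) abort("`logistic_slope` must be > 0.")
  if (!is.null(sample_weights) && any(sample_weights <= 0)) {
    abort("Sample weights d_u must be > 0.")
  }
  structure(list(f = as.integer(f), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), l2_lambda = l2_lambda,
                 logistic_slope = logistic_slope,
                 sample_weights = sample_weights, seed = as.integer(seed),
                 tol = tol, patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 optimizer = optimizer),
            class = "train_config")
}

#' Logistic calibration weight for a drug-sample pair
#'
#' The calibration weight c = min(f(s_obs, o, l), f(s_pred, o, l)) with
#' f(s, o, l) = 1 / (1 + exp(-l (s - o))), a logistic centered at the
#' maximum-dosage threshold o. When both the observed and predicted scores
#' sit deep in the insensitive regime (s << o, an extrapolated IC50), the
#' weight approaches 0 and the pair's squared error is suppressed; pairs in
#' the sensitive regime keep weight near 1.
#'
#' @param s_obs Observed sensitivity score(s).
#' @param s_pred Predicted sensitivity score(s).
#' @param o Per-drug threshold, o = -log2(max dose uM); recycled.
#' @param l Logistic slope (> 0).
#' @return Weight(s) in (0, 1), the elementwise minimum of the two logistic
#'   evaluations.
#' @export
logistic_weight <- function(s_obs, s_pred, o, l = 1) {
  if (l <= 0) abort("Logistic slope `l` must be > 0.")
  pmin(stats::plogis(l * (s_obs - o)), stats::plogis(l * (s_pred - o)))
}

## Core numeric kernel shared by objective(), gradients and the training
## loop. X: samples x d kernel features; s, mask: drugs x samples; o, b:
## per-drug; d_u: per-sample. Weights `cw` (calibration) are supplied by the
## caller so they can be frozen across an epoch.
.obj_parts <- function(W_P, Q, b, X, s, mask, d_u, cw, lambda) {
  K <- sum(mask)
  P <- X %*% W_P
  shat <- sweep(Q %*% t(P), 1L, b, "+")
  wt <- sweep(cw * mask, 2L, d_u, "*")
  wt[!mask] <- 0                     # NA scores at unobserved pairs
  resid <- shat - s
  resid[!mask] <- 0
  data_term <- sum(wt * resid^2)
  reg_term <- lambda * (sum(Q^2) + sum(W_P^2))
  list(loss = 0.5 * (data_term + reg_term) / K,
       data_term = data_term, reg_term = reg_term, K = K,
       shat = shat, wt = wt, resid = resid, P = P)
}

.obj_grads <- function(parts, W_P, Q, X, lambda) {
  K <- parts$K
  R <- parts$wt * parts$resid
  list(b = rowSums(R) / K,
       Q = (R %*% parts$P + lambda * Q) / K,
       W_P = (crossprod(X, crossprod(R, Q)) + lambda * W_P) / K)
}

.align_panel <- function(panel, kernel, config) {
  samples <- rownames(kernel)
  missing <- setdiff(panel$sample_ids, samples)
  if (length(missing) > 0L) {
    abort(sprintf("Panel sample(s) missing from kernel: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  X <- kernel[panel$sample_ids, , drop = FALSE]
  d_u <- config$sample_weights
  if (is.null(d_u)) {
    d_u <- setNames(rep(1, length(panel$sample_ids)), panel$sample_ids)
  } else {
    miss <- setdiff(panel$sample_ids, names(d_u))
    if (length(miss) > 0L) {
      abort(sprintf("Sample weight d_u missing for: %s",
                    paste(head(miss, 5L), collapse = ", ")))
    }
    d_u <- d_u[panel$sample_ids]
  }
  list(X = X, d_u = d_u)
}

#' Calibrated weighted objective of a fitted model
#'
#' Recomputes the training loss
#' `0.5 (sum d_u c_iu (s_iu - shat_iu)^2 + lambda (||Q||^2 + ||W_P||^2)) / K`
#' over the observed drug-sample pairs, with calibration weights c_iu
#' evaluated at the model's current predictions.
#'
#' @param model A `pharmacospace_model`.
#' @param panel A `response_panel` whose samples appear in `kernel`.
#' @param kernel Kernel feature matrix (samples x reference samples).
#' @param sample_weights Optional per-sample weights d_u overriding the
#'   model's training configuration.
#' @return List with `loss`, `data_term`, `reg_term`, `K` (observed pairs)
#'   and the calibration-weight matrix `c`.
#' @export
objective <- function(model, panel, kernel, sample_weights = NULL) {
  stopifnot(inherits(model, "pharmacospace_model"),
            inherits(panel, "response_panel"))
  cfg <- model$config
  if (!is.null(sample_weights)) cfg$sample_weights <- sample_weights
  if (sum(panel$observed) == 0L) abort("Panel has no observed pairs.")
  drugs <- intersect(model$drug_ids, panel$drug_ids)
  if (length(drugs) == 0L) abort("No shared drugs between model and panel.")
  al <- .align_panel(panel, kernel, cfg)
  s <- panel$s[drugs, , drop = FALSE]
  mask <- panel$observed[drugs, , drop = FALSE]
  o <- panel$max_dose_log2[drugs]
  W_P <- model$W_P; Q <- model$Q[drugs, , drop = FALSE]
  b <- model$b_Q[drugs]
  shat <- sweep(Q %*% t(al$X %*% W_P), 1L, b, "+")
  cw <- logistic_weight(s, shat, o, cfg$logistic_slope)
  parts <- .obj_parts(W_P, Q, b, al$X, s, mask, al$d_u, cw, cfg$l2_lambda)
  list(loss = parts$loss, data_term = parts$data_term,
       reg_term = parts$reg_term, K = parts$K, c = cw)
}

#' Learn the pharmacogenomic space from a training panel
#'
#' Fits the calibrated matrix-factorization recommender: sensitivity scores
#' are modeled as `shat_iu = b_i^Q + q_i . p_u` with `p_u = x_u W_P`, where
#' x_u are the kernel features of sample u against the training reference.
#' Training minimizes the calibrated weighted objective by full-batch
#' gradient descent; the calibration weights c_iu are recomputed from the
#' current predictions at the start of each epoch and held fixed within it,
#' so the gradient never pushes predictions insensitive merely to shrink
#' their own weights.
#'
#' @param panel A `response_panel` of training samples.
#' @param train_expr `expr_matrix` (log scale) covering the panel's samples.
#' @param essential_genes Gene panel for kernel features.
#' @param config A [train_config()].
#' @return A `pharmacospace_model`: parameters `W_P` (d x f), `Q`
#'   (drugs x f), `b_Q`, the frozen `basis`, `max_dose_log2`, the `config`,
#'   and a `loss_trace` tibble (epoch, loss).
#' @export
train_pharmacospace <- function(panel, train_expr, essential_genes,
                                config = train_config()) {
  stopifnot(inherits(panel, "response_panel"),
            inherits(train_expr, "expr_matrix"),
            inherits(config, "train_config"))
  missing <- setdiff(panel$sample_ids, colnames(train_expr))
  if (length(missing) > 0L) {
    abort(sprintf("Panel sample(s) missing from expression matrix: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  basis <- fit_reference_basis(
    train_expr[, panel$sample_ids, drop = FALSE], essential_genes)
  kernel <- compute_kernel(train_expr[, panel$sample_ids, drop = FALSE], basis)
  al <- .align_panel(panel, kernel, config)
  X <- al$X; d_u <- al$d_u
  s <- panel$s; mask <- panel$observed; o <- panel$max_dose_log2
  if (sum(mask) == 0L) abort("Panel has no observed pairs.")
  n_drugs <- nrow(s); d <- ncol(X); f <- config$f
  set.seed(config$seed)
  W_P <- matrix(rnorm(d * f, sd = 0.01), d, f,
                dimnames = list(colnames(X), NULL))
  Q <- matrix(rnorm(n_drugs * f, sd = 0.01), n_drugs, f,
              dimnames = list(rownames(s), NULL))
  ## bias starts at its closed-form optimum for the zero-latent model:
  ## the d_u-weighted mean of observed scores per drug
  wobs <- sweep(mask * 1, 2L, d_u, "*")
  b <- rowSums(wobs * ifelse(mask, s, 0)) / pmax(rowSums(wobs), .Machine$double.eps)
  lr <- config$learning_rate
  adam <- config$optimizer == "adam"
  if (adam) {
    m <- list(W_P = W_P * 0, Q = Q * 0, b = b * 0)
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  }
  trace <- numeric(config$max_epochs)
  n_epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    shat <- sweep(Q %*% t(X %*% W_P), 1L, b, "+")
    cw <- logistic_weight(s, shat, o, config$logistic_slope)
    parts <- .obj_parts(W_P, Q, b, X, s, mask, d_u, cw, config$l2_lambda)
    if (!is.finite(parts$loss)) {
      abort("Training diverged (non-finite loss); try a smaller learning_rate.")
    }
    trace[epoch] <- parts$loss
    n_epochs <- epoch
    g <- .obj_grads(parts, W_P, Q, X, config$l2_lambda)
    if (adam) {
      for (nm in c("W_P", "Q", "b")) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mh <- m[[nm]] / (1 - beta1^epoch)
        vh <- v[[nm]] / (1 - beta2^epoch)
        step <- lr * mh / (sqrt(vh) + eps)
        if (nm == "W_P") W_P <- W_P - step
        else if (nm == "Q") Q <- Q - step
        else b <- b - step
      }
    } else {
      W_P <- W_P - lr * g$W_P
      Q <- Q - lr * g$Q
      b <- b - lr * g$b
    }
    if (epoch >= config$min_epochs && epoch > config$patience) {
      prev <- trace[epoch - config$patience]
      if (abs(prev - parts$loss) <= config$tol * max(abs(prev), 1e-12)) break
    }
  }
  structure(list(W_P = W_P, Q = Q, b_Q = b, drug_ids = rownames(s),
                 basis = basis, max_dose_log2 = o, config = config,
                 loss_trace = tibble::tibble(epoch = seq_len(n_epochs),
                                             loss = trace[seq_len(n_epochs)]),
                 converged = n_epochs < config$max_epochs),
            class = "pharmacospace_model")
}

#' @export
print.pharmacospace_model <- function(x, ...) {
  cat(sprintf("<pharmacospace_model> f=%d, %d drugs, %d reference samples; %d epochs, final loss %.6g\n",
              x$config$f, length(x$drug_ids),
              length(x$basis$reference_samples),
              nrow(x$loss_trace), x$loss_trace$loss[nrow(x$loss_trace)]))
  invisible(x)
}

#' Predict sensitivity scores for query samples
#'
#' Computes `shat_iu = b_i^Q + q_i . (x_u W_P)` for every drug i and query
#' sample u. Deterministic given the model and kernel.
#'
#' @param model A `pharmacospace_model`.
#' @param kernel Kernel matrix (query samples x reference samples) from
#'   [compute_kernel()] against the model's basis.
#' @return Numeric matrix drugs x query samples of predicted s scores.
#' @export
predict_scores <- function(model, kernel) {
  stopifnot(inherits(model, "pharmacospace_model"))
  if (!identical(colnames(kernel), model$basis$reference_samples)) {
    abort("Kernel reference axis does not match the model basis.")
  }
  P <- kernel %*% model$W_P
  sweep(model$Q %*% t(P), 1L, model$b_Q, "+")
}

#' @export
predict.pharmacospace_model <- function(object, kernel, ...) {
  predict_scores(object, kernel)
}

#' Predict sensitivity from expression profiles
#'
#' Convenience wrapper: kernelizes `expr` against the model's basis (with
#' `log2(TPM+1)` first when `expr` is on the TPM scale) and returns a tidy
#' prediction table.
#'
#' @param model A `pharmacospace_model`.
#' @param expr `expr_matrix` of query samples.
#' @return Tibble with columns `drug_id`, `sample_id`, `s_pred`, `ic50_uM`,
#'   `max_dose_log2`, `sensitive_pred`.
#' @export
predict_from_expression <- function(model, expr) {
  if (expr_scale(expr) == "tpm") expr <- log_tpm(expr)
  kernel <- compute_kernel(expr, model$basis)
  shat <- predict_scores(model, kernel)
  tibble::tibble(
    drug_id = rep(rownames(shat), times = ncol(shat)),
    sample_id = rep(colnames(shat), each = nrow(shat)),
    s_pred = as.vector(shat),
    ic50_uM = 2^(-as.vector(shat)),
    max_dose_log2 = rep(unname(model$max_dose_log2), times = ncol(shat)),
    sensitive_pred = as.vector(shat) >
      rep(unname(model$max_dose_log2), times = ncol(shat))
  )
}

#' Save a fitted model archive
#'
#' Writes the full model (parameters, axis labels, frozen basis, config,
#' loss trace) as a single serialized archive; the round trip is bit-exact.
#'
#' @param model A `pharmacospace_model`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pharmacospace_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model archive written by [write_model()]
#' @param path Archive path.
#' @return The `pharmacospace_model`.
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pharmacospace_model")) {
    abort(sprintf("'%s' is not a pharmacospace model archive.", path))
  }
  model
}

#' @describeIn train_pharmacospace Per-drug parameter table: bias `b_q` and
#'   latent coordinates `q_1 ... q_f`.
#' @param x,object A `pharmacospace_model`.
#' @param ... Unused.
#' @method tidy pharmacospace_model
#' @export
tidy.pharmacospace_model <- function(x, ...) {
  q <- x$Q
  colnames(q) <- paste0("q_", seq_len(ncol(q)))
  dplyr::bind_cols(
    tibble::tibble(drug_id = x$drug_ids, b_q = unname(x$b_Q),
                   max_dose_log2 = unname(x$max_dose_log2)),
    tibble::as_tibble(q)
  )
}

#' @describeIn train_pharmacospace One-row model summary.
#' @method glance pharmacospace_model
#' @export
glance.pharmacospace_model <- function(x, ...) {
  tibble::tibble(
    f = x$config$f,
    n_drugs = length(x$drug_ids),
    n_reference = length(x$basis$reference_samples),
    n_essential_genes = length(x$basis$essential_genes),
    l2_lambda = x$config$l2_lambda,
    logistic_slope = x$config$logistic_slope,
    epochs = nrow(x$loss_trace),
    final_loss = x$loss_trace$loss[nrow(x$loss_trace)],
    converged = x$converged
  )
}

#' @describeIn train_pharmacospace Training loss trace plot.
#' @method autoplot pharmacospace_model
#' @export
autoplot.pharmacospace_model <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Calibrated weighted loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}
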