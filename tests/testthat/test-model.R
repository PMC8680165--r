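test_that("logistic calibration weight takes the minimum logistic branch", {
  # both scores at the dosage threshold: logistic midpoint
  expect_equal(logistic_weight(-3, -3, o = -3, l = 1), 0.5)
  # deeply insensitive observation dominates a sensitive prediction
  w <- logistic_weight(-20, 10, o = 0, l = 1)
  expect_lt(w, 1e-8)
  expect_equal(w, stats::plogis(-20))
  # closed form away from the threshold
  expect_equal(logistic_weight(0 + 10, 0 + 20, o = 0, l = 1),
               1 / (1 + exp(-10)))
  # strictly increasing in both arguments
  expect_true(logistic_weight(1, 2, 0) < logistic_weight(1.5, 2, 0))
  expect_true(logistic_weight(2, 1, 0) < logistic_weight(2, 1.5, 0))
})

make_manual_model <- function(W_P, Q, b_Q, ref_expr, max_dose = NULL) {
  basis <- fit_reference_basis(ref_expr, rownames(ref_expr))
  drugs <- rownames(Q)
  if (is.null(max_dose)) max_dose <- setNames(rep(0, nrow(Q)), drugs)
  structure(list(W_P = W_P, Q = Q, b_Q = setNames(b_Q, drugs),
                 drug_ids = drugs, basis = basis, max_dose_log2 = max_dose,
                 config = train_config(f = ncol(Q)),
                 loss_trace = tibble::tibble(epoch = 1L, loss = NA_real_),
                 converged = TRUE),
            class = "pharmacospace_model")
}

test_that("prediction is bias plus latent dot product", {
  set.seed(31)
  ref <- tiny_expr(matrix(rnorm(20 * 4), 20, 4), scale = "log_normalized")
  f <- 3L
  # zero latent part: every prediction equals the drug bias
  m0 <- make_manual_model(matrix(0, 4, f),
                          matrix(0, 2, f, dimnames = list(c("d1", "d2"), NULL)),
                          c(1.5, -2), ref)
  k <- compute_kernel(ref, m0$basis)
  p0 <- predict_scores(m0, k)
  expect_true(all(p0["d1", ] == 1.5) && all(p0["d2", ] == -2))

  # random model matches an explicit per-entry loop
  W <- matrix(rnorm(4 * f), 4, f)
  Q <- matrix(rnorm(2 * f), 2, f, dimnames = list(c("d1", "d2"), NULL))
  b <- c(0.3, -0.1)
  m <- make_manual_model(W, Q, b, ref)
  pred <- predict_scores(m, k)
  for (i in 1:2) {
    for (u in rownames(k)) {
      p_u <- as.vector(k[u, , drop = FALSE] %*% W)
      expect_lt(abs(pred[i, u] - (b[i] + sum(Q[i, ] * p_u))), 1e-12)
    }
  }
  # axis mismatch is caught
  bad <- k[, c(2, 1, 3, 4)]
  expect_error(predict_scores(m, bad), "reference axis")
})

test_that("permuting query sample order permutes predictions identically", {
  set.seed(37)
  ref <- tiny_expr(matrix(rnorm(30 * 5), 30, 5), scale = "log_normalized")
  m <- make_manual_model(matrix(rnorm(5 * 2), 5, 2),
                         matrix(rnorm(3 * 2), 3, 2,
                                dimnames = list(paste0("d", 1:3), NULL)),
                         rnorm(3), ref)
  q <- tiny_expr(matrix(rnorm(30 * 6), 30, 6), scale = "log_normalized",
                 genes = rownames(ref), samples = paste0("q", 1:6))
  k <- compute_kernel(q, m$basis)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_identical(predict_scores(m, k)[, perm],
                   predict_scores(m, k[perm, ]))
})

test_that("objective matches a naive per-pair loop oracle", {
  set.seed(41)
  ref <- tiny_expr(matrix(rnorm(25 * 6), 25, 6), scale = "log_normalized")
  drugs <- paste0("d", 1:4)
  s <- matrix(rnorm(4 * 6, sd = 2), 4, 6,
              dimnames = list(drugs, colnames(ref)))
  observed <- matrix(runif(24) > 0.2, 4, 6)
  s[!observed] <- NA
  o <- setNames(rnorm(4), drugs)
  panel <- response_panel(s, o, observed)
  m <- make_manual_model(matrix(rnorm(6 * 2, sd = 0.5), 6, 2),
                         matrix(rnorm(4 * 2, sd = 0.5), 4, 2,
                                dimnames = list(drugs, NULL)),
                         rnorm(4), ref, max_dose = o)
  d_u <- setNames(runif(6, 0.5, 3), colnames(ref))
  lambda <- m$config$l2_lambda
  k <- compute_kernel(ref, m$basis)
  res <- objective(m, panel, k, sample_weights = d_u)

  acc <- 0
  for (i in seq_along(drugs)) {
    for (u in seq_len(ncol(s))) {
      if (!observed[i, u]) next
      p_u <- as.vector(k[u, , drop = FALSE] %*% m$W_P)
      shat <- m$b_Q[i] + sum(m$Q[i, ] * p_u)
      cw <- min(1 / (1 + exp(-(s[i, u] - o[i]))),
                1 / (1 + exp(-(shat - o[i]))))
      acc <- acc + d_u[u] * cw * (s[i, u] - shat)^2
    }
  }
  loop_loss <- 0.5 * (acc + lambda * (sum(m$Q^2) + sum(m$W_P^2))) /
    sum(observed)
  expect_lt(abs(res$loss - loop_loss), 1e-12)
  expect_equal(res$K, sum(observed))
})

test_that("objective edge cases: perfect fit and a single calibrated pair", {
  ref <- tiny_expr(matrix(c(1, 2, 4, 8, 3, 9, 2, 1), 4, 2) + 0.0,
                   scale = "log_normalized")
  # one drug, one observed pair, residual 2, weights forced to ~1 by a steep
  # slope with both scores deep in the sensitive regime
  s <- matrix(10, 1, 2, dimnames = list("d1", colnames(ref)))
  s[1, 2] <- NA
  panel <- response_panel(s, c(d1 = -5))
  m <- make_manual_model(matrix(0, 2, 1), matrix(0, 1, 1,
                                                 dimnames = list("d1", NULL)),
                         8, ref, max_dose = c(d1 = -5))
  m$config$l2_lambda <- 0
  m$config$logistic_slope <- 50
  k <- compute_kernel(ref, m$basis)
  res <- objective(m, panel, k)
  expect_lt(abs(res$loss - 0.5 * 4 / 1), 1e-9)

  # perfect predictions, no regularization: zero loss
  m2 <- m
  m2$b_Q[] <- 10
  expect_equal(objective(m2, panel, k)$loss, 0)
})

test_that("analytic gradients match central finite differences with frozen weights", {
  set.seed(47)
  for (rep in 1:3) {
    n_drugs <- 5L; n_samples <- 8L; f <- 3L
    X <- matrix(rnorm(n_samples * n_samples), n_samples, n_samples)
    s <- matrix(rnorm(n_drugs * n_samples, sd = 2), n_drugs, n_samples)
    mask <- matrix(runif(n_drugs * n_samples) > 0.15, n_drugs, n_samples)
    d_u <- runif(n_samples, 0.5, 2)
    lambda <- 0.05
    W <- matrix(rnorm(n_samples * f, sd = 0.3), n_samples, f)
    Q <- matrix(rnorm(n_drugs * f, sd = 0.3), n_drugs, f)
    b <- rnorm(n_drugs)
    o <- rnorm(n_drugs)
    shat0 <- sweep(Q %*% t(X %*% W), 1L, b, "+")
    cw <- logistic_weight(s, shat0, o, 1)   # frozen for the check

    unpack <- function(v) {
      list(W = matrix(v[seq_len(n_samples * f)], n_samples, f),
           Q = matrix(v[n_samples * f + seq_len(n_drugs * f)], n_drugs, f),
           b = v[n_samples * f + n_drugs * f + seq_len(n_drugs)])
    }
    loss_fn <- function(v) {
      p <- unpack(v)
      pharmacospace:::.obj_parts(p$W, p$Q, p$b, X, s, mask, d_u, cw,
                                 lambda)$loss
    }
    v0 <- c(as.vector(W), as.vector(Q), b)
    parts <- pharmacospace:::.obj_parts(W, Q, b, X, s, mask, d_u, cw, lambda)
    g <- pharmacospace:::.obj_grads(parts, W, Q, X, lambda)
    analytic <- c(as.vector(g$W_P), as.vector(g$Q), g$b)
    numeric <- numeric_gradient(loss_fn, v0)
    rel <- abs(analytic - numeric) / pmax(abs(numeric), 1e-8)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("training interpolates a trivially fittable panel and is seed-deterministic", {
  # one drug, one sample: the bias alone can fit exactly
  expr <- tiny_expr(matrix(c(1, 2, 5, 3, 7, 2), 3, 2),
                    scale = "log_normalized")
  s <- matrix(c(2.5, NA), 1, 2, dimnames = list("d1", colnames(expr)))
  panel <- response_panel(s, c(d1 = 0))
  cfg <- train_config(f = 1, max_epochs = 200, min_epochs = 200, seed = 2,
                      l2_lambda = 0)
  m <- train_pharmacospace(panel, expr, rownames(expr), cfg)
  expect_lt(m$loss_trace$loss[nrow(m$loss_trace)], 1e-6)

  sim <- tiny_training_data(seed = 55, sigma = 0.2, missing = 0.1)
  cfg2 <- quick_config(seed = 9)
  m1 <- train_pharmacospace(sim$panel, sim$expr, rownames(sim$expr), cfg2)
  m2 <- train_pharmacospace(sim$panel, sim$expr, rownames(sim$expr), cfg2)
  expect_identical(m1$W_P, m2$W_P)
  expect_identical(m1$Q, m2$Q)
  expect_identical(m1$b_Q, m2$b_Q)
})

test_that("overwhelming regularization shrinks the latent part to the bias solution", {
  sim <- tiny_training_data(n_lines = 15, n_drugs = 3, seed = 61,
                            sigma = 0.1, missing = 0)
  cfg <- train_config(f = 2, l2_lambda = 2000, max_epochs = 20000,
                      min_epochs = 20000, seed = 4)
  m <- train_pharmacospace(sim$panel, sim$expr, rownames(sim$expr), cfg)
  expect_lt(max(abs(m$Q)), 1e-6)
  expect_lt(max(abs(m$W_P)), 1e-6)
  # with Q = 0 every prediction is the per-drug bias, whose stationary value
  # is the calibration-weighted mean of the observed scores (c evaluated at
  # the bias itself)
  cw <- logistic_weight(sim$panel$s,
                        matrix(m$b_Q, nrow = 3, ncol = 15),
                        sim$panel$max_dose_log2)
  bstar <- rowSums(cw * sim$panel$s) / rowSums(cw)
  expect_lt(max(abs(m$b_Q - bstar)), 1e-3)
})

test_that("training loss is non-increasing under a fixed calibration schedule", {
  sim <- tiny_training_data(n_lines = 20, n_drugs = 4, seed = 71,
                            sigma = 0.2, missing = 0.1)
  # near-zero slope pins every calibration weight at 0.5, giving a fixed
  # weighting schedule for which plain gradient descent must descend
  cfg <- train_config(f = 3, logistic_slope = 1e-9, max_epochs = 2000,
                      min_epochs = 2000, seed = 13)
  m <- train_pharmacospace(sim$panel, sim$expr, rownames(sim$expr), cfg)
  expect_true(all(diff(m$loss_trace$loss) <= 1e-12))
})

test_that("deeply extrapolated pairs contribute under 1% of their unweighted error", {
  o <- 0; l <- 1
  s_obs <- o - 10 / l
  s_pred <- o - 8 / l
  cw <- logistic_weight(s_obs, s_pred, o, l)
  err2 <- (s_obs - s_pred)^2
  expect_lt(cw * err2 / err2, 0.01)
})

test_that("noiseless synthetic panel is recovered on held-out samples", {
  sim <- generate_panel(30, 5, 250, f_true = 2, sigma_response = 0,
                        missing_rate = 0, seed = 83)
  test_ids <- sim$panel$sample_ids[25:30]
  train_ids <- setdiff(sim$panel$sample_ids, test_ids)
  panel_tr <- response_panel(sim$panel$s[, train_ids],
                             sim$panel$max_dose_log2,
                             sim$panel$observed[, train_ids])
  cfg <- train_config(f = 4, max_epochs = 20000, min_epochs = 5000, seed = 3)
  m <- train_pharmacospace(panel_tr, sim$expr[, train_ids],
                           rownames(sim$expr), cfg)
  k_test <- compute_kernel(sim$expr[, test_ids], m$basis)
  pred <- predict_scores(m, k_test)
  truth <- sim$truth$s_true[, test_ids]
  expect_gte(cor(as.vector(pred), as.vector(truth)), 0.95)
})

test_that("divergent learning rates raise an informative error", {
  sim <- tiny_training_data(n_lines = 10, n_drugs = 3, seed = 91)
  cfg <- train_config(f = 2, learning_rate = 1e9, max_epochs = 50,
                      min_epochs = 50, seed = 1)
  expect_error(
    train_pharmacospace(sim$panel, sim$expr, rownames(sim$expr), cfg),
    "learning_rate")
})

test_that("evaluation metrics: accuracy over observed pairs, median AE over observed-sensitive", {
  drugs <- c("d1", "d2")
  s <- matrix(c(2, -1, 3, -4, 1, -2), 2, 3,
              dimnames = list(drugs, c("s1", "s2", "s3")))
  panel <- response_panel(s, c(d1 = 0, d2 = 0))
  # predictions equal to observations
  perfect <- evaluate_predictions(s, panel)
  expect_equal(perfect$accuracy, c(1, 1))
  expect_equal(perfect$mae_sensitive, c(0, NA))  # d2 has no sensitive pairs

  # all predicted insensitive while half the observed pairs are sensitive
  allneg <- matrix(-5, 2, 3, dimnames = dimnames(s))
  res <- evaluate_predictions(allneg, panel)
  pooled_acc <- sum(res$accuracy * res$n_obs) / sum(res$n_obs)
  expect_equal(pooled_acc, 0.5)

  # median of absolute errors {1, 2, 9} over the sensitive pairs
  s3 <- matrix(c(1, 2, 3), 1, 3, dimnames = list("d1", c("a", "b", "c")))
  panel3 <- response_panel(s3, c(d1 = 0))
  pred3 <- matrix(c(1 + 1, 2 - 2, 3 + 9), 1, 3, dimnames = dimnames(s3))
  expect_equal(evaluate_predictions(pred3, panel3)$mae_sensitive, 2)
})

test_that("cross-validation partitions samples into reproducible held-out folds", {
  sim <- tiny_training_data(n_lines = 5, n_drugs = 2, n_genes = 60,
                            seed = 95)
  cfg <- train_config(f = 1, max_epochs = 300, min_epochs = 300, seed = 1)
  cv <- cross_validate(sim$panel, sim$expr, rownames(sim$expr), cfg,
                       k_folds = 5, seed = 42)
  # leave-one-out: 5 singleton folds covering all samples
  expect_equal(as.integer(table(cv$folds)), rep(1L, 5))
  expect_setequal(names(cv$folds), sim$panel$sample_ids)
  cv2 <- cross_validate(sim$panel, sim$expr, rownames(sim$expr), cfg,
                        k_folds = 5, seed = 42)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(cross_validate(sim$panel, sim$expr, rownames(sim$expr), cfg,
                              k_folds = 6), "Fewer samples")
})

test_that("model archives round-trip bit-exactly", {
  sim <- tiny_training_data(n_lines = 12, n_drugs = 3, seed = 99)
  m <- train_pharmacospace(sim$panel, sim$expr, rownames(sim$expr),
                           quick_config(max_epochs = 500, min_epochs = 500,
                                        seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back, m)
  not_model <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), not_model)
  expect_error(read_model(not_model), "not a pharmacospace model")
})

test_that("tidy and glance expose per-drug parameters and a one-row summary", {
  sim <- tiny_training_data(n_lines = 10, n_drugs = 3, seed = 103)
  m <- train_pharmacospace(sim$panel, sim$expr, rownames(sim$expr),
                           quick_config(max_epochs = 300, min_epochs = 300))
  td <- tidy(m)
  expect_setequal(td$drug_id, sim$panel$drug_ids)
  expect_true(all(c("b_q", "q_1", "q_3") %in% names(td)))
  gl <- glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$f, 3L)
  expect_s3_class(autoplot(m), "ggplot")
})
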