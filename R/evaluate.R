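#' Per-drug evaluation of predicted sensitivity scores
#'
#' Two complementary metrics per drug: classification `accuracy` — the
#' fraction of observed pairs whose predicted sensitive/insensitive call
#' (s > o) matches the observed call — and `mae_sensitive`, the median
#' absolute error |s - shat| over pairs whose *observed* class is sensitive
#' (conditioning on the observed label keeps the metric independent of the
#' model under evaluation).
#'
#' @param pred Matrix drugs x samples of predicted scores (from
#'   [predict_scores()]), or a tibble with columns `drug_id`, `sample_id`,
#'   `s_pred`.
#' @param panel The `response_panel` holding observed scores and per-drug
#'   maximum dosages.
#' @return Tibble with columns `drug_id`, `n_obs`, `n_sensitive`,
#'   `accuracy`, `mae_sensitive` (`NA` where a drug has no observed /
#'   no sensitive pairs).
#' @export
evaluate_predictions <- function(pred, panel) {
  stopifnot(inherits(panel, "response_panel"))
  if (is.data.frame(pred)) {
    m <- matrix(NA_real_, length(panel$drug_ids), length(panel$sample_ids),
                dimnames = list(panel$drug_ids, panel$sample_ids))
    m[cbind(match(pred$drug_id, panel$drug_ids),
            match(pred$sample_id, panel$sample_ids))] <- pred$s_pred
    pred <- m
  }
  drugs <- intersect(rownames(pred), panel$drug_ids)
  if (length(drugs) == 0L) abort("No shared drugs between predictions and panel.")
  purrr::map_dfr(drugs, function(dr) {
    obs_mask <- panel$observed[dr, ] & !is.na(pred[dr, panel$sample_ids])
    s <- panel$s[dr, obs_mask]
    shat <- pred[dr, panel$sample_ids][obs_mask]
    o <- panel$max_dose_log2[[dr]]
    n <- sum(obs_mask)
    if (n == 0L) {
      return(tibble::tibble(drug_id = dr, n_obs = 0L, n_sensitive = 0L,
                            accuracy = NA_real_, mae_sensitive = NA_real_))
    }
    sens_obs <- classify_sensitive(s, o)
    sens_pred <- classify_sensitive(shat, o)
    tibble::tibble(
      drug_id = dr, n_obs = n, n_sensitive = sum(sens_obs),
      accuracy = mean(sens_obs == sens_pred),
      mae_sensitive = if (any(sens_obs)) median(abs(s - shat)[sens_obs])
                      else NA_real_
    )
  })
}

#' Cross-validate the pharmacogenomic model
#'
#' Samples are partitioned into `k_folds` seeded folds; each fold is held
#' out entirely (both its expression profiles and its response column), a
#' model is trained on the remainder with its own reference basis, and the
#' held-out samples are predicted through kernel features against that
#' basis.
#'
#' @param panel Full `response_panel`.
#' @param expr `expr_matrix` (log scale) covering the panel's samples.
#' @param essential_genes Gene panel for kernel features.
#' @param config A [train_config()].
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the fold partition (default `config$seed`).
#' @return A `cv_result`: list with `predictions` (tibble: `fold`,
#'   `drug_id`, `sample_id`, `s_obs`, `s_pred`, `sensitive_obs`,
#'   `sensitive_pred`), `per_drug` and `per_fold` metric tibbles, `pooled`
#'   (one-row tibble) and `folds` (named fold assignment).
#' @export
cross_validate <- function(panel, expr, essential_genes,
                           config = train_config(), k_folds = 5L,
                           seed = config$seed) {
  stopifnot(inherits(panel, "response_panel"))
  n <- length(panel$sample_ids)
  if (n < k_folds) abort("Fewer samples than folds.")
  set.seed(seed)
  fold <- setNames(sample(rep(seq_len(k_folds), length.out = n)),
                   panel$sample_ids)
  preds <- purrr::map_dfr(seq_len(k_folds), function(k) {
    test_ids <- names(fold)[fold == k]
    train_ids <- setdiff(panel$sample_ids, test_ids)
    sub <- response_panel(panel$s[, train_ids, drop = FALSE],
                          panel$max_dose_log2,
                          panel$observed[, train_ids, drop = FALSE])
    cfg <- config
    if (!is.null(cfg$sample_weights)) {
      cfg$sample_weights <- cfg$sample_weights[train_ids]
    }
    model <- train_pharmacospace(sub, expr[, train_ids, drop = FALSE],
                                 essential_genes, cfg)
    kernel <- compute_kernel(expr[, test_ids, drop = FALSE], model$basis)
    shat <- predict_scores(model, kernel)
    o <- rep(unname(panel$max_dose_log2), times = length(test_ids))
    tibble::tibble(
      fold = k,
      drug_id = rep(panel$drug_ids, times = length(test_ids)),
      sample_id = rep(test_ids, each = length(panel$drug_ids)),
      s_obs = as.vector(panel$s[, test_ids, drop = FALSE]),
      s_pred = as.vector(shat),
      observed = as.vector(panel$observed[, test_ids, drop = FALSE]),
      sensitive_obs = as.vector(panel$s[, test_ids, drop = FALSE]) > o,
      sensitive_pred = as.vector(shat) > o
    )
  })
  obs <- preds[preds$observed, , drop = FALSE]
  per_fold <- obs |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      accuracy = mean(.data$sensitive_obs == .data$sensitive_pred),
      mae_sensitive = median(abs(.data$s_obs - .data$s_pred)[.data$sensitive_obs]),
      pearson_r = cor(.data$s_obs, .data$s_pred),
      .groups = "drop")
  per_drug <- obs |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      n_sensitive = sum(.data$sensitive_obs),
      accuracy = mean(.data$sensitive_obs == .data$sensitive_pred),
      mae_sensitive = if (any(.data$sensitive_obs))
        median(abs(.data$s_obs - .data$s_pred)[.data$sensitive_obs])
      else NA_real_,
      .groups = "drop")
  pooled <- tibble::tibble(
    n_obs = nrow(obs),
    accuracy = mean(obs$sensitive_obs == obs$sensitive_pred),
    mae_sensitive = median(abs(obs$s_obs - obs$s_pred)[obs$sensitive_obs]),
    pearson_r = cor(obs$s_obs, obs$s_pred)
  )
  structure(list(predictions = preds, per_drug = per_drug,
                 per_fold = per_fold, pooled = pooled, folds = fold,
                 k_folds = k_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV, %d observed held-out pairs\n",
              x$k_folds, x$pooled$n_obs))
  cat(sprintf("  pooled accuracy %.3f, MAE(sensitive) %.3f, Pearson r %.3f\n",
              x$pooled$accuracy, x$pooled$mae_sensitive, x$pooled$pearson_r))
  invisible(x)
}

#' @describeIn cross_validate Per-drug cross-validated metrics.
#' @param x,object A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$per_drug

#' @describeIn cross_validate Pooled one-row summary.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) x$pooled

#' @describeIn cross_validate Observed-vs-predicted scatter, colored by fold.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  obs <- object$predictions[object$predictions$observed, , drop = FALSE]
  ggplot2::ggplot(obs, ggplot2::aes(.data$s_obs, .data$s_pred,
                                    color = factor(.data$fold))) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = "Observed sensitivity s", y = "Predicted s",
                  color = "Fold",
                  title = "Held-out predictions (cross-validation)") +
    ggplot2::theme_minimal()
}
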