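## Kernelize a genes x units profile matrix (TPM or log scale) against a
## model basis and return the predicted sensitivity row for one drug.
.predict_units <- function(model, profiles, gene_ids, drug_id,
                           profile_scale) {
  if (!drug_id %in% model$drug_ids) {
    abort(sprintf("Unknown drug '%s'.", drug_id))
  }
  expr <- expression_matrix(profiles, scale = profile_scale)
  if (profile_scale == "tpm") expr <- log_tpm(expr)
  kernel <- compute_kernel(expr, model$basis)
  shat <- predict_scores(model, kernel)
  shat[drug_id, , drop = TRUE]
}

.composition_profiles <- function(composition) {
  validate_clonal_composition(composition)
  profiles <- do.call(cbind, composition$clusters$mean_profile)
  colnames(profiles) <- composition$clusters$cluster_id
  rownames(profiles) <- composition$gene_ids
  profiles
}

#' Patient-level monotherapy response at a dosage
#'
#' Predicts the cell-death fraction a drug achieves in a patient at a given
#' dosage, at one of three granularities: per `cell` (death per cell,
#' patient value = unweighted mean), per `cluster` (death per cluster mean
#' profile, patient value = cell-fraction weighted average), or `patient`
#' (single pseudo-bulk profile). Each unit's predicted sensitivity score is
#' converted to an IC50 curve (`m = -shat`, configurable slope) and
#' evaluated at the dosage.
#'
#' @param model A `pharmacospace_model`.
#' @param composition A `clonal_composition` (cluster fractions + mean TPM
#'   profiles).
#' @param drug_id Drug to predict.
#' @param dose_log2 log2 of the dosage in uM (`log2(dose_uM)`).
#' @param level `"cluster"` (default), `"cell"`, or `"patient"`.
#' @param cells_expr For `level = "cell"`: `expr_matrix` of the patient's
#'   cells (TPM scale).
#' @param slope Dose-response slope used for all units (default 1).
#' @param profile_scale Scale of the composition profiles: `"tpm"`
#'   (default, log2(TPM+1) applied before kernelization) or
#'   `"log_normalized"`.
#' @return A `monotherapy_prediction`: list with `patient_id`, `drug_id`,
#'   `dose_log2`, `level`, `units` (tibble: `unit_id`, `fraction`,
#'   `s_pred`, `ic50_uM`, `death`) and `patient_death`.
#' @export
predict_patient_response <- function(model, composition, drug_id, dose_log2,
                                     level = c("cluster", "cell", "patient"),
                                     cells_expr = NULL, slope = 1,
                                     profile_scale = c("tpm", "log_normalized")) {
  level <- match.arg(level)
  profile_scale <- match.arg(profile_scale)
  stopifnot(inherits(model, "pharmacospace_model"),
            inherits(composition, "clonal_composition"))
  if (!is.finite(dose_log2)) abort("Dosage must be finite.")
  if (level == "cell") {
    if (is.null(cells_expr)) {
      abort("Cell-level prediction needs `cells_expr` (genes x cells).")
    }
    profiles <- unclass(cells_expr)
    fractions <- rep(1 / ncol(profiles), ncol(profiles))
    units <- colnames(profiles)
  } else if (level == "cluster") {
    profiles <- .composition_profiles(composition)
    fractions <- composition$clusters$fraction
    units <- composition$clusters$cluster_id
  } else {
    cl <- .composition_profiles(composition)
    profiles <- cbind(as.vector(cl %*% composition$clusters$fraction))
    dimnames(profiles) <- list(composition$gene_ids, composition$patient_id)
    fractions <- 1
    units <- composition$patient_id
  }
  s_pred <- .predict_units(model, profiles, composition$gene_ids, drug_id,
                           profile_scale)
  death <- vapply(s_pred, function(s) {
    cell_death_fraction(dose_response_curve(-s, slope), dose_log2)
  }, numeric(1L))
  structure(list(
    patient_id = composition$patient_id, drug_id = drug_id,
    dose_log2 = dose_log2, level = level,
    units = tibble::tibble(unit_id = units, fraction = fractions,
                           s_pred = unname(s_pred),
                           ic50_uM = 2^(-unname(s_pred)),
                           death = unname(death)),
    patient_death = sum(fractions * death)
  ), class = "monotherapy_prediction")
}

#' @export
print.monotherapy_prediction <- function(x, ...) {
  cat(sprintf("<monotherapy_prediction> patient '%s', drug '%s' at %.3g uM (%s level): %.1f%% cell death\n",
              x$patient_id, x$drug_id, 2^x$dose_log2, x$level,
              100 * x$patient_death))
  invisible(x)
}

#' @describeIn predict_patient_response Per-unit prediction table with the
#'   patient aggregate attached to each row.
#' @param x A `monotherapy_prediction`.
#' @param ... Unused.
#' @method tidy monotherapy_prediction
#' @export
tidy.monotherapy_prediction <- function(x, ...) {
  dplyr::mutate(x$units, patient_id = x$patient_id, drug_id = x$drug_id,
                dose_uM = 2^x$dose_log2, level = x$level,
                patient_death = x$patient_death,
                .before = 1L)
}

#' Independent-action combination of two kill fractions
#'
#' Under independent drug action, the combined kill of a clone is
#' `h_i + h_j - h_i h_j` (the product term being the cells inhibited by
#' both drugs). Symmetric, bounded by `[max(h_i, h_j), min(1, h_i + h_j)]`.
#'
#' @param h_i,h_j Kill fractions in \[0, 1\] (vectorized).
#' @return Combined kill fraction(s).
#' @export
combine_independent <- function(h_i, h_j) {
  if (any(h_i < 0 | h_i > 1 | h_j < 0 | h_j > 1)) {
    abort("Kill fractions must lie in [0, 1].")
  }
  h_i + h_j - h_i * h_j
}

#' Combination response for a patient
#'
#' Applies the independent-action rule per cluster at each drug's dosage,
#' then aggregates across clusters by cell-fraction weighting. The
#' improvement is the patient-level combination kill minus the better of
#' the two patient-level monotherapy kills.
#'
#' @param model A `pharmacospace_model`.
#' @param composition A `clonal_composition`.
#' @param drug_i,drug_j The drug pair (a warning is issued if identical;
#'   the combination then degenerates to `1 - (1 - h)^2` per cluster).
#' @param dose_i_log2,dose_j_log2 log2 dosages (uM) for each drug.
#' @param slope Dose-response slope (default 1).
#' @param profile_scale Passed to [predict_patient_response()].
#' @return A `combination_prediction`: list with the pair, dosages,
#'   `clusters` tibble (`cluster_id`, `fraction`, `death_i`, `death_j`,
#'   `death_combo`), patient-level `mono_i`, `mono_j`, `combo_death` and
#'   `improvement`.
#' @export
predict_combination <- function(model, composition, drug_i, dose_i_log2,
                                drug_j, dose_j_log2, slope = 1,
                                profile_scale = c("tpm", "log_normalized")) {
  profile_scale <- match.arg(profile_scale)
  if (identical(drug_i, drug_j)) {
    warn("Combining a drug with itself; independent action degenerates to 1 - (1 - h)^2.")
  }
  mono_i <- predict_patient_response(model, composition, drug_i, dose_i_log2,
                                     level = "cluster", slope = slope,
                                     profile_scale = profile_scale)
  mono_j <- predict_patient_response(model, composition, drug_j, dose_j_log2,
                                     level = "cluster", slope = slope,
                                     profile_scale = profile_scale)
  combo <- combine_independent(mono_i$units$death, mono_j$units$death)
  w <- composition$clusters$fraction
  patient_combo <- sum(w * combo)
  structure(list(
    patient_id = composition$patient_id,
    drug_i = drug_i, drug_j = drug_j,
    dose_i_log2 = dose_i_log2, dose_j_log2 = dose_j_log2,
    clusters = tibble::tibble(cluster_id = composition$clusters$cluster_id,
                              fraction = w,
                              death_i = mono_i$units$death,
                              death_j = mono_j$units$death,
                              death_combo = combo),
    mono_i = mono_i$patient_death, mono_j = mono_j$patient_death,
    combo_death = patient_combo,
    improvement = patient_combo - max(mono_i$patient_death,
                                      mono_j$patient_death)
  ), class = "combination_prediction")
}

#' @export
print.combination_prediction <- function(x, ...) {
  cat(sprintf("<combination_prediction> patient '%s': %s + %s -> %.1f%% death (best mono %.1f%%, improvement %.1f%%)\n",
              x$patient_id, x$drug_i, x$drug_j, 100 * x$combo_death,
              100 * max(x$mono_i, x$mono_j), 100 * x$improvement))
  invisible(x)
}

#' Rank candidate drug combinations across patients
#'
#' Evaluates every candidate pair in every patient and ranks by the
#' improvement of the combination over the best monotherapy, descending;
#' ties are broken by the pair's lexicographic order.
#'
#' @param model A `pharmacospace_model`.
#' @param compositions List of `clonal_composition` objects (one per
#'   patient).
#' @param pairs Data frame with columns `drug_i`, `drug_j`.
#' @param doses Named vector of log2 dosages (uM) per drug; must cover every
#'   drug in `pairs`.
#' @param slope Dose-response slope (default 1).
#' @param profile_scale Passed through to the per-patient predictions.
#' @return Tibble with columns `patient_id`, `drug_i`, `drug_j`,
#'   `combo_death`, `best_mono`, `improvement`, sorted by improvement.
#' @export
rank_combinations <- function(model, compositions, pairs, doses, slope = 1,
                              profile_scale = c("tpm", "log_normalized")) {
  profile_scale <- match.arg(profile_scale)
  if (nrow(pairs) < 1L) abort("Need at least one candidate pair.")
  need <- setdiff(unique(c(pairs$drug_i, pairs$drug_j)), names(doses))
  if (length(need) > 0L) {
    abort(sprintf("Missing dosage for drug(s): %s",
                  paste(head(need, 5L), collapse = ", ")))
  }
  out <- purrr::map_dfr(compositions, function(comp) {
    purrr::pmap_dfr(pairs[, c("drug_i", "drug_j")], function(drug_i, drug_j) {
      cp <- predict_combination(model, comp, drug_i, doses[[drug_i]],
                                drug_j, doses[[drug_j]], slope = slope,
                                profile_scale = profile_scale)
      tibble::tibble(patient_id = cp$patient_id, drug_i = drug_i,
                     drug_j = drug_j, combo_death = cp$combo_death,
                     best_mono = max(cp$mono_i, cp$mono_j),
                     improvement = cp$improvement)
    })
  })
  dplyr::arrange(out, dplyr::desc(.data$improvement), .data$drug_i,
                 .data$drug_j, .data$patient_id)
}

#' Filter candidate combinations by monotherapy reliability and benefit
#'
#' Implements the qualitative prioritization used before experimental
#' follow-up: keep pairs whose constituent drugs each reach a minimum
#' cross-validated monotherapy accuracy, and which are predicted to improve
#' over the best monotherapy by at least `min_improvement` in at least one
#' patient.
#'
#' @param ranked Output of [rank_combinations()].
#' @param drug_accuracy Named vector of per-drug CV accuracy (e.g. from
#'   `tidy(cv)`).
#' @param min_accuracy Minimum per-drug accuracy (default 0.7).
#' @param min_improvement Minimum predicted improvement in >= 1 patient
#'   (default 0, i.e. any positive benefit).
#' @return Filtered ranked tibble.
#' @export
prioritize_combinations <- function(ranked, drug_accuracy,
                                    min_accuracy = 0.7,
                                    min_improvement = 0) {
  acc_ok <- function(d) {
    d %in% names(drug_accuracy) & drug_accuracy[d] >= min_accuracy
  }
  keep <- acc_ok(ranked$drug_i) & acc_ok(ranked$drug_j)
  kept <- ranked[keep, , drop = FALSE]
  pair_ok <- kept |>
    dplyr::group_by(.data$drug_i, .data$drug_j) |>
    dplyr::summarise(any_gain = any(.data$improvement > min_improvement),
                     .groups = "drop")
  dplyr::inner_join(kept,
                    pair_ok[pair_ok$any_gain, c("drug_i", "drug_j")],
                    by = c("drug_i", "drug_j"))
}
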