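#' Drug response panel
#'
#' Holds sensitivity scores s = -log2(IC50 in uM) for a drugs x samples
#' screen, an observation mask (screens are incomplete), and the per-drug
#' maximum tested dosage on the same scale, o = -log2(max dose uM). Larger s
#' means more sensitive; a sample is called sensitive to a drug when its IC50
#' lies strictly below the maximum tested dosage, i.e. s > o.
#'
#' @param s Numeric matrix drugs x samples of sensitivity scores, with drug
#'   ids as rownames and sample ids as colnames. `NA` entries are allowed and
#'   marked unobserved.
#' @param max_dose_log2 Named numeric vector, per drug, of -log2(max dose uM).
#' @param observed Optional logical mask, same shape as `s`; defaults to
#'   `!is.na(s)`.
#' @return A `response_panel` object.
#' @export
response_panel <- function(s, max_dose_log2, observed = NULL) {
  if (!is.matrix(s) || !is.numeric(s)) abort("`s` must be a numeric matrix.")
  if (is.null(rownames(s)) || is.null(colnames(s))) {
    abort("`s` needs drug ids as rownames and sample ids as colnames.")
  }
  if (is.null(observed)) observed <- !is.na(s)
  if (!identical(dim(observed), dim(s))) {
    abort("`observed` mask must match the shape of `s`.")
  }
  dimnames(observed) <- dimnames(s)
  missing <- setdiff(rownames(s), names(max_dose_log2))
  if (length(missing) > 0L) {
    abort(sprintf("Missing max dosage for drug(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  o <- max_dose_log2[rownames(s)]
  if (any(!is.finite(o))) abort("max_dose_log2 must be finite for every drug.")
  if (any(!is.finite(s[observed]))) {
    abort("Observed sensitivity scores must be finite.")
  }
  structure(list(s = s, observed = observed, max_dose_log2 = o,
                 drug_ids = rownames(s), sample_ids = colnames(s)),
            class = "response_panel")
}

#' @export
print.response_panel <- function(x, ...) {
  cat(sprintf("<response_panel> %d drugs x %d samples, %d/%d observed pairs\n",
              length(x$drug_ids), length(x$sample_ids),
              sum(x$observed), length(x$observed)))
  invisible(x)
}

#' Read a drug response panel from long-format CSV
#'
#' The response table has columns `drug_id`, `sample_id`, `ic50_uM`; the
#' max-dose table has `drug_id`, `max_dose_uM`. IC50s are converted to
#' sensitivity scores s = -log2(IC50 uM) at ingest; (drug, sample) pairs
#' absent from the table are marked unobserved.
#'
#' @param path Long-format response CSV.
#' @param max_dose_path CSV of per-drug maximum tested dosages; must cover
#'   every drug in the response table.
#' @return A `response_panel`.
#' @export
read_response_panel <- function(path, max_dose_path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("drug_id", "sample_id", "ic50_uM")
  if (!all(need %in% names(tb))) {
    abort(sprintf("Response table '%s' must have columns: %s",
                  path, paste(need, collapse = ", ")))
  }
  if (any(tb$ic50_uM <= 0, na.rm = TRUE)) {
    abort("IC50 values must be positive where observed.")
  }
  md <- readr::read_csv(max_dose_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("drug_id", "max_dose_uM") %in% names(md))) {
    abort(sprintf("Max-dose table '%s' must have columns drug_id, max_dose_uM.",
                  max_dose_path))
  }
  drugs <- unique(tb$drug_id)
  samples <- unique(tb$sample_id)
  s <- matrix(NA_real_, length(drugs), length(samples),
              dimnames = list(drugs, samples))
  keep <- !is.na(tb$ic50_uM)
  s[cbind(match(tb$drug_id[keep], drugs), match(tb$sample_id[keep], samples))] <-
    -log2(tb$ic50_uM[keep])
  max_dose_log2 <- setNames(-log2(md$max_dose_uM), md$drug_id)
  response_panel(s, max_dose_log2)
}

#' Long-format view of a response panel
#'
#' @param x A `response_panel`.
#' @param ... Unused.
#' @return A tibble with columns `drug_id`, `sample_id`, `s`, `observed`,
#'   `max_dose_log2`, `sensitive` (NA where unobserved).
#' @method tidy response_panel
#' @export
tidy.response_panel <- function(x, ...) {
  tb <- tibble::tibble(
    drug_id = rep(x$drug_ids, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$drug_ids)),
    s = as.vector(x$s),
    observed = as.vector(x$observed),
    max_dose_log2 = rep(unname(x$max_dose_log2), times = length(x$sample_ids))
  )
  tb$sensitive <- ifelse(tb$observed, tb$s > tb$max_dose_log2, NA)
  tb
}

#' Write a response panel to long-format CSV
#'
#' Inverse of [read_response_panel()]: observed pairs become rows with
#' `ic50_uM = 2^(-s)`; the max-dose table is written alongside.
#'
#' @param panel A `response_panel`.
#' @param path Output response CSV.
#' @param max_dose_path Output max-dose CSV.
#' @return `path`, invisibly.
#' @export
write_response_panel <- function(panel, path, max_dose_path) {
  stopifnot(inherits(panel, "response_panel"))
  tb <- tidy.response_panel(panel)
  tb <- tb[tb$observed, c("drug_id", "sample_id", "s")]
  tb$ic50_uM <- 2^(-tb$s)
  readr::write_csv(tb[, c("drug_id", "sample_id", "ic50_uM")], path)
  readr::write_csv(
    tibble::tibble(drug_id = names(panel$max_dose_log2),
                   max_dose_uM = 2^(-unname(panel$max_dose_log2))),
    max_dose_path)
  invisible(path)
}

#' Sensitive / insensitive call for a drug-sample pair
#'
#' Sensitive means the IC50 is strictly lower than the maximum tested dosage,
#' equivalently s > o on the -log2 scale. A pair exactly at the maximum
#' dosage is insensitive.
#'
#' @param s Sensitivity score(s), s = -log2(IC50 uM).
#' @param max_dose_log2 Per-drug threshold o = -log2(max dose uM), recycled.
#' @return Logical vector/matrix of the same shape as `s`.
#' @export
classify_sensitive <- function(s, max_dose_log2) {
  s > max_dose_log2
}

#' Restrict a panel to drugs effective in a focus cohort
#'
#' Keeps drugs that elicit a response (observed sensitive call) in at least
#' `min_fraction` of the focus samples with an observation — the eligibility
#' pre-filter used when training indication-specific models.
#'
#' @param panel A `response_panel`.
#' @param focus_samples Sample ids defining the focus cohort.
#' @param min_fraction Minimum fraction of responding focus samples
#'   (default 0.3).
#' @return A `response_panel` restricted to eligible drugs.
#' @export
filter_drugs_by_response <- function(panel, focus_samples, min_fraction = 0.3) {
  stopifnot(inherits(panel, "response_panel"))
  cols <- intersect(focus_samples, panel$sample_ids)
  if (length(cols) == 0L) abort("No focus samples present in the panel.")
  sens <- classify_sensitive(panel$s[, cols, drop = FALSE],
                             panel$max_dose_log2)
  obs <- panel$observed[, cols, drop = FALSE]
  frac <- rowSums(sens & obs, na.rm = TRUE) / pmax(rowSums(obs), 1L)
  keep <- frac >= min_fraction & rowSums(obs) > 0L
  if (!any(keep)) abort("No drug passes the responder-fraction filter.")
  response_panel(panel$s[keep, , drop = FALSE],
                 panel$max_dose_log2[keep],
                 panel$observed[keep, , drop = FALSE])
}

#' Indication-specific sample weights
#'
#' Builds the per-sample weight vector d_u used to focus training on one
#' cancer type: focus samples get `focus_weight` (default 10), all others 1.
#'
#' @param sample_ids All training sample ids.
#' @param focus_samples Ids of the focus indication.
#' @param focus_weight Weight for focus samples (default 10).
#' @return Named numeric vector over `sample_ids`.
#' @export
indication_weights <- function(sample_ids, focus_samples, focus_weight = 10) {
  w <- setNames(rep(1, length(sample_ids)), sample_ids)
  w[intersect(focus_samples, sample_ids)] <- focus_weight
  w
}
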