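#' Sigmoid dose-response curve
#'
#' A two-parameter logistic in log2 dose with asymptotes at 0% and 100%
#' cell death: `death(x) = 1 / (1 + 2^(b (m - x)))` where `m = log2(IC50 uM)`
#' and `b > 0` is the slope. Death is exactly 0.5 at the IC50 and strictly
#' increasing in dose.
#'
#' @param m log2(IC50 in uM).
#' @param slope Curve slope b (default 1).
#' @return A `dose_response_curve`.
#' @export
dose_response_curve <- function(m, slope = 1) {
  if (!is.finite(m)) abort("IC50 parameter `m` must be finite.")
  if (slope <= 0) abort("Curve slope must be > 0.")
  structure(list(m = m, slope = slope), class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> IC50 = %.4g uM (m = %.4g), slope = %.3g\n",
              2^x$m, x$m, x$slope))
  invisible(x)
}

#' Cell-death fraction at a dosage
#'
#' @param curve A `dose_response_curve`.
#' @param dose_log2 log2 of the dosage in uM (vectorized).
#' @return Cell-death fraction(s) in (0, 1).
#' @export
cell_death_fraction <- function(curve, dose_log2) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (any(!is.finite(dose_log2))) abort("Dosage must be finite.")
  1 / (1 + 2^(curve$slope * (curve$m - dose_log2)))
}

#' Mixture of clone dose-response curves
#'
#' A tumor is modeled as a mixture of clones, each with its own curve and a
#' cell-fraction weight; weights must sum to 1.
#'
#' @param weights Positive weights summing to 1.
#' @param curves List of `dose_response_curve`s, same length.
#' @return A `mixture_curve`.
#' @export
mixture_curve <- function(weights, curves) {
  if (length(weights) != length(curves)) {
    abort("`weights` and `curves` must have the same length.")
  }
  if (any(weights <= 0)) abort("Mixture weights must be > 0.")
  if (abs(sum(weights) - 1) > 1e-9) abort("Mixture weights must sum to 1.")
  ok <- vapply(curves, inherits, logical(1L), "dose_response_curve")
  if (!all(ok)) abort("All components must be dose_response_curve objects.")
  structure(list(weights = weights, curves = curves), class = "mixture_curve")
}

#' @export
print.mixture_curve <- function(x, ...) {
  cat(sprintf("<mixture_curve> %d component(s)\n", length(x$weights)))
  invisible(x)
}

#' Cell-death fraction of a clone mixture at a dosage
#'
#' Weighted sum of the component death fractions.
#'
#' @param mix A `mixture_curve`.
#' @param dose_log2 log2 dosage in uM (vectorized).
#' @return Mixture death fraction(s).
#' @export
mixture_death_fraction <- function(mix, dose_log2) {
  stopifnot(inherits(mix, "mixture_curve"))
  out <- 0
  for (k in seq_along(mix$weights)) {
    out <- out + mix$weights[k] * cell_death_fraction(mix$curves[[k]], dose_log2)
  }
  out
}

#' Naive aggregate IC50 of a mixture
#'
#' The weighted average of component log2-IC50 values. This ignores the
#' sigmoid shape of the individual curves and is biased whenever components
#' differ; it is retained as the initializer for the Newton aggregation and
#' as the contrast illustrating that bias.
#'
#' @param mix A `mixture_curve`.
#' @return log2 aggregate IC50 (naive estimate).
#' @export
naive_aggregate <- function(mix) {
  stopifnot(inherits(mix, "mixture_curve"))
  sum(mix$weights * vapply(mix$curves, `[[`, numeric(1L), "m"))
}

#' Aggregate IC50 of a clone mixture by Newton's method
#'
#' Finds the dosage at which the mixture kills exactly half the cells:
#' the root of `g(x) = mixture_death(x) - 0.5`, which is strictly increasing
#' and hence has a unique root within `[min m_k, max m_k]`. Iterations start
#' from the naive (weighted-average) estimate; each Newton step is
#' safeguarded by a maintained bracket — if a step leaves
#' `[min m - 1, max m + 1]` or fails to shrink |g|, a bisection step is
#' taken instead.
#'
#' @param mix A `mixture_curve`.
#' @param tol Convergence tolerance on |g| (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @return log2 of the aggregate IC50 (uM).
#' @export
aggregate_ic50_newton <- function(mix, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(mix, "mixture_curve"))
  ms <- vapply(mix$curves, `[[`, numeric(1L), "m")
  bs <- vapply(mix$curves, `[[`, numeric(1L), "slope")
  ws <- mix$weights
  if (length(ms) == 1L) return(ms[[1L]])
  g <- function(x) {
    sum(ws / (1 + 2^(bs * (ms - x)))) - 0.5
  }
  gprime <- function(x) {
    y <- 1 / (1 + 2^(bs * (ms - x)))
    y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
    sum(ws * log(2) * bs * y * (1 - y))
  }
  lo <- min(ms) - 1; hi <- max(ms) + 1   # g(lo) < 0 < g(hi)
  x <- sum(ws * ms)                       # naive initialization
  gx <- g(x)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (gx == 0) { converged <- TRUE; break }
    if (gx > 0) hi <- min(hi, x) else lo <- max(lo, x)
    x_new <- x - gx / gprime(x)
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi ||
        abs(g(x_new)) >= abs(gx)) {
      x_new <- (lo + hi) / 2              # bisection fallback
    }
    # converge on the dose axis (g can be nearly flat between well-separated
    # clones, so a residual-based stop would overstate precision)
    if (abs(x_new - x) <= tol || (hi - lo) <= tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
    gx <- g(x)
  }
  if (!converged) {
    abort("Aggregate IC50 root-finding failed to converge.")
  }
  min(max(x, min(ms)), max(ms))
}

#' @describeIn dose_response_curve Dose-response curve plot over a dose range.
#' @param object A `dose_response_curve` or `mixture_curve`.
#' @param dose_range log2-dose plotting range (default m +/- 6).
#' @param ... Unused.
#' @method autoplot dose_response_curve
#' @export
autoplot.dose_response_curve <- function(object, dose_range = NULL, ...) {
  if (is.null(dose_range)) dose_range <- object$m + c(-6, 6)
  x <- seq(dose_range[1L], dose_range[2L], length.out = 200L)
  tb <- tibble::tibble(dose_log2 = x,
                       death = cell_death_fraction(object, x))
  ggplot2::ggplot(tb, ggplot2::aes(.data$dose_log2, .data$death)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "log2 dose (uM)", y = "Cell-death fraction") +
    ggplot2::theme_minimal()
}

#' @describeIn mixture_curve Mixture and component curves with the Newton
#'   and naive aggregate IC50s marked.
#' @param object A `mixture_curve`.
#' @param ... Unused.
#' @method autoplot mixture_curve
#' @export
autoplot.mixture_curve <- function(object, ...) {
  ms <- vapply(object$curves, `[[`, numeric(1L), "m")
  x <- seq(min(ms) - 4, max(ms) + 4, length.out = 300L)
  comp <- purrr::imap_dfr(object$curves, function(cv, k) {
    tibble::tibble(dose_log2 = x, death = cell_death_fraction(cv, x),
                   component = paste0("clone ", k))
  })
  mixed <- tibble::tibble(dose_log2 = x,
                          death = mixture_death_fraction(object, x),
                          component = "mixture")
  agg <- aggregate_ic50_newton(object)
  ggplot2::ggplot(dplyr::bind_rows(comp, mixed),
                  ggplot2::aes(.data$dose_log2, .data$death,
                               color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::geom_vline(xintercept = agg, linetype = 2) +
    ggplot2::geom_vline(xintercept = naive_aggregate(object), linetype = 4,
                        color = "grey50") +
    ggplot2::labs(x = "log2 dose (uM)", y = "Cell-death fraction",
                  title = "Mixture dose-response (dashed: Newton aggregate, dotdash: naive)") +
    ggplot2::theme_minimal()
}
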