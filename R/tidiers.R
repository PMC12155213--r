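# broom-style tidiers so results drop into dplyr chains.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ROC result into its per-threshold trace
#'
#' @param x An [roc_curve()] result.
#' @param ... Unused.
#' @return A tibble `(threshold, sensitivity, specificity)`.
#' @export
tidy.rrs_roc <- function(x, ...) x$curve

#' One-row ROC summary
#'
#' @param x An [roc_curve()] result.
#' @param ... Unused.
#' @return A tibble `(auc, se, p_value, direction, n_pos, n_neg)`.
#' @export
glance.rrs_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, p_value = x$p_value,
                 direction = x$direction, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a decomposition into a long coefficient table
#'
#' @param x An [decompose_frames()] result.
#' @param ... Unused.
#' @return A tibble `(term, estimate)` over the five signal coefficients.
#' @export
tidy.rrs_decomposition <- function(x, ...) {
  tibble::tibble(term = c("a (HbR)", "b (HbO)", "m_r (MitoRed)",
                          "m_o (MitoOx)", "c (fluorescence)"),
                 estimate = c(x$a, x$b, x$m_r, x$m_o, x$c))
}

#' One-row decomposition diagnostics
#'
#' @param x An [decompose_frames()] result.
#' @param ... Unused.
#' @return A tibble `(residual_rms, condition_number, baseline_converged,
#'   n_despiked)`.
#' @export
glance.rrs_decomposition <- function(x, ...) {
  tibble::tibble(residual_rms = x$residual_rms,
                 condition_number = x$condition_number,
                 baseline_converged = x$baseline_converged,
                 n_despiked = x$n_despiked)
}

#' Tidy a ROUT result
#'
#' @param x An [rout_outliers()] result.
#' @param ... Unused.
#' @return A tibble `(value, removed)` in input order.
#' @export
tidy.rrs_rout <- function(x, ...) {
  v <- numeric(length(x$removed_index))
  v[!x$removed_index] <- x$kept
  v[x$removed_index] <- x$removed
  tibble::tibble(value = v, removed = x$removed_index)
}

#' One-row ROUT summary
#'
#' @param x An [rout_outliers()] result.
#' @param ... Unused.
#' @return A tibble `(center, rsdr, q, n, n_removed)`.
#' @export
glance.rrs_rout <- function(x, ...) {
  tibble::tibble(center = x$center, rsdr = x$rsdr, q = x$q,
                 n = length(x$removed_index), n_removed = length(x$removed))
}
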