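#' ROUT-style robust outlier detection (one-group location model)
#'
#' Robust outlier removal controlling a false-discovery rate Q, specialized to
#' a single group of pooled index values. The robust center is the median; the
#' robust spread (RSDR) is the 68.27th percentile of the absolute residuals
#' with the small-sample correction n / (n - 1). Candidates are tested from
#' the most extreme inward: the j-th most extreme residual gets a two-sided
#' t-type p-value (|residual| / RSDR, df = n - 1) compared against the
#' step-down threshold Q * (n - j + 1) / n; testing stops at the first
#' non-significant candidate, so removal is monotone in |residual|.
#'
#' This follows the published description of the method (robust fit plus
#' FDR-based detection); exact numerical agreement with the commercial
#' implementation is not guaranteed and the surrounding pipeline relies only
#' on the documented invariants (monotone removal, ~Q-level false removal on
#' clean data, shift/scale equivariance).
#'
#' @param values Numeric vector of pooled measurements (n >= 3 for any
#'   removal to be attempted).
#' @param q False-discovery level (default 0.02).
#' @param max_frac Largest fraction of points that may be flagged
#'   (default 0.3).
#' @return A list of class `rrs_rout`: `kept`, `removed`, `removed_index`
#'   (logical per input value), `center`, `rsdr`, `q`.
#' @export
rout_outliers <- function(values, q = 0.02, max_frac = 0.3) {
  stopifnot(is.numeric(values))
  n <- length(values)
  out <- list(kept = values, removed = numeric(0),
              removed_index = rep(FALSE, n),
              center = stats::median(values), rsdr = NA_real_, q = q)
  class(out) <- "rrs_rout"
  if (n < 3) {
    warning("rout_outliers: fewer than 3 values; no removal attempted", call. = FALSE)
    return(out)
  }
  resid <- values - out$center
  aresid <- abs(resid)
  p68 <- stats::quantile(aresid, 0.6827, names = FALSE)
  rsdr <- p68 * n / (n - 1)
  out$rsdr <- rsdr
  if (q <= 0 || rsdr <= 0) return(out)
  ord <- order(aresid, decreasing = TRUE)
  m <- max(1L, floor(max_frac * n))
  flagged <- logical(n)
  for (j in seq_len(m)) {
    i <- ord[j]
    tstat <- aresid[i] / rsdr
    p <- 2 * stats::pt(-tstat, df = n - 1)
    if (p < q * (n - j + 1) / n) flagged[i] <- TRUE else break
  }
  out$removed_index <- flagged
  out$kept <- values[!flagged]
  out$removed <- values[flagged]
  out
}
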