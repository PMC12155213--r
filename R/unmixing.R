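#' Iterative polynomial fluorescence baseline (ModPoly)
#'
#' Tissue fluorescence under 441 nm excitation is a smooth, broad background
#' that dominates the sharp resonance Raman bands. It is modeled as a
#' 5th-degree polynomial fitted iteratively to the lower envelope of the
#' spectrum: fit the polynomial by least squares, clip the working spectrum to
#' the fitted curve wherever it exceeds it, and repeat until the working
#' spectrum stops changing (max absolute change below `tol` relative to the
#' spectrum scale) or `max_iter` is reached. A single-pass polynomial would
#' ride on top of the Raman peaks; the clipped iteration converges onto the
#' peak-free floor.
#'
#' The scalar fluorescence magnitude `c` is defined as the mean of the fitted
#' baseline over the (already cropped) analysis window.
#'
#' @param spectrum A cropped spectrum tibble (typically 600--1700 cm^-1).
#' @param degree Polynomial degree (default 5).
#' @param max_iter Maximum clip-and-refit iterations (default 100).
#' @param tol Relative convergence tolerance on the working spectrum
#'   (default 1e-4).
#' @return A list with elements `baseline` (spectrum tibble), `c` (mean
#'   baseline), `iterations`, and `converged` (logical; `FALSE` means the last
#'   iterate was returned with a warning).
#' @export
fit_baseline <- function(spectrum, degree = 5, max_iter = 100, tol = 1e-4) {
  wn <- spectrum$wavenumber
  y0 <- spectrum$intensity
  if (length(wn) < degree + 2) {
    stop(sprintf("need at least %d channels for a degree-%d baseline", degree + 2, degree),
         call. = FALSE)
  }
  # centered/scaled abscissa keeps the Vandermonde well conditioned
  x <- (wn - mean(wn)) / (diff(range(wn)) / 2)
  X <- stats::poly(x, degree = degree, raw = FALSE)
  scale <- max(abs(y0), .Machine$double.eps)
  y <- y0
  converged <- FALSE
  it <- 0L
  base <- rep(0, length(y0))
  repeat {
    it <- it + 1L
    fit <- stats::lm.fit(cbind(1, X), y)
    base <- drop(cbind(1, X) %*% fit$coefficients)
    y_new <- pmin(y, base)
    delta <- max(abs(y_new - y)) / scale
    y <- y_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) {
    warning("fit_baseline: did not converge; returning last iterate", call. = FALSE)
  }
  # Peak-masked refinement: the clipped iteration identifies where the Raman
  # peaks are, but its envelope absorbs a few percent of the peak intensity
  # wherever bands crowd together. Refitting the polynomial by plain least
  # squares on the peak-free channels only removes that bias (exactly, for
  # peaks without long tails).
  for (ref in 1:3) {
    r <- y0 - base
    thr <- stats::median(r) + 3 * stats::mad(r)
    peak <- r > thr
    # widen each peak run so shoulder channels (where the band has decayed
    # below the threshold but not to zero) stay out of the baseline fit
    if (any(peak)) {
      pad <- 12L
      idx <- which(peak)
      lo <- pmax(idx - pad, 1L); hi <- pmin(idx + pad, length(peak))
      for (k in seq_along(idx)) peak[lo[k]:hi[k]] <- TRUE
    }
    mask <- !peak
    if (sum(mask) < degree + 2) break
    fit <- stats::lm.fit(cbind(1, X)[mask, , drop = FALSE], y0[mask])
    base_new <- drop(cbind(1, X) %*% fit$coefficients)
    if (max(abs(base_new - base)) <= tol * scale) { base <- base_new; break }
    base <- base_new
  }
  list(baseline = spectrum_tbl(wn, base),
       c = mean(base),
       iterations = it,
       converged = converged)
}

# Exact non-negative least squares for a small number of columns: enumerate
# every support subset, solve unconstrained LS on it, keep feasible solutions
# and return the one with minimum RSS. The NNLS optimum satisfies the KKT
# stationarity condition on its support, so it appears among the candidates.
nnls_exact <- function(A, y) {
  p <- ncol(A)
  best <- list(coef = rep(0, p), rss = sum(y^2))
  for (mask in seq_len(2^p - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    As <- A[, S, drop = FALSE]
    fit <- tryCatch(stats::lm.fit(As, y), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) next
    if (any(fit$coefficients < 0)) next
    rss <- sum(fit$residuals^2)
    if (rss < best$rss - 1e-12 * max(1, best$rss)) {
      cf <- rep(0, p)
      cf[S] <- fit$coefficients
      best <- list(coef = cf, rss = rss)
    }
  }
  best
}

#' Fit reference libraries to a baseline-subtracted spectrum
#'
#' The fluorescence-free residual is regressed onto the four reference
#' libraries by non-negative least squares (library weights are concentration
#' proxies, so negative weights are nonphysical). Weights are reported under
#' their conventional names: `a` (HbR), `b` (HbO), `m_r` (MitoRed), `m_o`
#' (MitoOx), together with the root-mean-square residual of the fit and the
#' condition number of the library design matrix.
#'
#' @param residual A spectrum tibble (measurement minus baseline) on the same
#'   grid as the libraries.
#' @param libraries Stacked library tibble containing `HbO`, `HbR`, `MitoOx`,
#'   `MitoRed` (see [default_libraries()]).
#' @return A one-row tibble with columns `a`, `b`, `m_r`, `m_o`,
#'   `residual_rms`, `condition_number`.
#' @export
fit_libraries <- function(residual, libraries) {
  M <- library_matrix(libraries)
  need <- c("HbR", "HbO", "MitoRed", "MitoOx")
  if (!all(need %in% colnames(M))) {
    stop("libraries must include HbR, HbO, MitoRed, MitoOx", call. = FALSE)
  }
  wn <- attr(M, "wavenumber")
  L <- M[, need, drop = FALSE]
  if (nrow(residual) != nrow(L) ||
      any(abs(residual$wavenumber - wn) > 1e-8)) {
    stop("residual and libraries are not on the same wavenumber grid", call. = FALSE)
  }
  sv <- svd(L, nu = 0, nv = 0)$d
  kappa <- sv[1] / sv[length(sv)]
  if (!is.finite(kappa) || kappa > 1e8) {
    sims <- outer(seq_len(ncol(L)), seq_len(ncol(L)),
                  Vectorize(function(i, j) cosine_sim(L[, i], L[, j])))
    diag(sims) <- 0
    worst <- which(sims == max(sims), arr.ind = TRUE)[1, ]
    stop(sprintf("library set is rank-deficient; most collinear pair: %s / %s",
                 colnames(L)[worst[1]], colnames(L)[worst[2]]), call. = FALSE)
  }
  sol <- nnls_exact(L, residual$intensity)
  tibble::tibble(
    a = sol$coef[1], b = sol$coef[2], m_r = sol$coef[3], m_o = sol$coef[4],
    residual_rms = sqrt(sol$rss / nrow(L)),
    condition_number = kappa
  )
}

#' Full three-step decomposition of a raw frame sequence
#'
#' Composes the pipeline the instrument software applies to each acquisition:
#' optional dark subtraction, cosmic-spike removal, trailing-window frame
#' averaging, crop to the analysis window, iterative polynomial baseline
#' extraction, and non-negative library regression. Returns the full signal
#' coefficient set used by the downstream indices.
#'
#' @param frames Long frame tibble (`frame`, `wavenumber`, `intensity`).
#' @param libraries Stacked library tibble (cropped automatically).
#' @param dark Optional dark spectrum tibble on the raw grid.
#' @param window Frame-averaging window (default 180).
#' @param crop_low,crop_high Analysis window in cm^-1 (defaults 600, 1700).
#' @param degree Baseline polynomial degree (default 5).
#' @param despike_z Spike threshold in robust SDs (default 8).
#' @param max_iter,tol Baseline iteration controls.
#' @return A one-row tibble of class `rrs_decomposition` with columns `a`,
#'   `b`, `m_r`, `m_o`, `c`, `residual_rms`, `condition_number`,
#'   `baseline_converged`, `n_despiked`.
#' @export
decompose_frames <- function(frames, libraries, dark = NULL, window = 180,
                             crop_low = 600, crop_high = 1700, degree = 5,
                             despike_z = 8, max_iter = 100, tol = 1e-4) {
  if (!is.null(dark)) frames <- subtract_dark(frames, dark)
  frames <- despike(frames, z = despike_z)
  n_despiked <- attr(frames, "n_despiked") %||% 0L
  avg <- rolling_average(frames, window = window)
  avg <- crop_spectrum(avg, crop_low, crop_high)
  bl <- fit_baseline(avg, degree = degree, max_iter = max_iter, tol = tol)
  resid <- spectrum_tbl(avg$wavenumber, avg$intensity - bl$baseline$intensity)
  libs_crop <- dplyr::filter(libraries, .data$wavenumber >= crop_low,
                             .data$wavenumber <= crop_high)
  coefs <- fit_libraries(resid, libs_crop)
  out <- dplyr::mutate(coefs, c = bl$c, .after = "m_o")
  out$baseline_converged <- bl$converged
  out$n_despiked <- as.integer(n_despiked)
  class(out) <- c("rrs_decomposition", class(out))
  attr(out, "spectrum") <- avg
  attr(out, "baseline") <- bl$baseline
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
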