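#' Uniform wavenumber grid
#'
#' Builds the uniform Raman-shift axis (in cm^-1) that spectra, libraries and
#' simulated frames share. The default covers 500--1800 cm^-1 at 2 cm^-1
#' spacing, wide enough that the analysis crop (600--1700 cm^-1) sits strictly
#' inside it and fine enough to resolve heme bands with FWHM around
#' 10--20 cm^-1.
#'
#' @param start,stop Grid limits in cm^-1 (`start < stop`).
#' @param step Grid spacing in cm^-1 (`> 0`).
#' @return A numeric vector of wavenumbers.
#' @export
wn_grid <- function(start = 500, stop = 1800, step = 2) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) stop("`start` must be < `stop`", call. = FALSE)
  if (!(step > 0)) stop("`step` must be > 0", call. = FALSE)
  seq(start, stop, by = step)
}

# Checks that a wavenumber vector is uniformly spaced (within fp tolerance).
is_uniform_grid <- function(wavenumber, tol = 1e-8) {
  if (length(wavenumber) < 2) return(TRUE)
  d <- diff(wavenumber)
  all(abs(d - d[1]) <= tol * max(1, abs(d[1])))
}

#' Construct a spectrum tibble
#'
#' A spectrum is a two-column tibble (`wavenumber`, `intensity`) on a uniform
#' grid. Intensities are detector counts in arbitrary units; negatives are
#' allowed (e.g. after dark subtraction).
#'
#' @param wavenumber Numeric vector of Raman shifts (cm^-1), strictly
#'   increasing and uniformly spaced.
#' @param intensity Numeric vector, same length, all finite.
#' @return A tibble with columns `wavenumber`, `intensity`.
#' @export
spectrum_tbl <- function(wavenumber, intensity) {
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("spectrum intensities must be finite", call. = FALSE)
  }
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    stop("`wavenumber` must be strictly increasing", call. = FALSE)
  }
  if (!is_uniform_grid(wavenumber)) {
    stop("`wavenumber` must be uniformly spaced", call. = FALSE)
  }
  tibble::tibble(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity))
}

#' Crop a spectrum to a wavenumber window
#'
#' Closed-interval crop: channels with `low <= wavenumber <= high` are kept.
#' The analysis window used throughout the pipeline is 600--1700 cm^-1.
#'
#' @param spectrum A spectrum tibble (see [spectrum_tbl()]).
#' @param low,high Window limits in cm^-1.
#' @return The cropped spectrum tibble.
#' @export
crop_spectrum <- function(spectrum, low = 600, high = 1700) {
  stopifnot(is.data.frame(spectrum), all(c("wavenumber", "intensity") %in% names(spectrum)))
  keep <- spectrum$wavenumber >= low & spectrum$wavenumber <= high
  if (!any(keep)) {
    stop(sprintf("crop window [%g, %g] does not overlap the grid [%g, %g]",
                 low, high, min(spectrum$wavenumber), max(spectrum$wavenumber)),
         call. = FALSE)
  }
  dplyr::filter(spectrum, .data$wavenumber >= low, .data$wavenumber <= high)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation onto `target` wavenumbers, used at load time when a
#' reference library and a measurement were recorded on different grids.
#' Extrapolation beyond the source grid is refused.
#'
#' @param spectrum A spectrum tibble.
#' @param target Numeric vector of target wavenumbers.
#' @return A spectrum tibble on `target`.
#' @export
resample_spectrum <- function(spectrum, target) {
  rng <- range(spectrum$wavenumber)
  if (min(target) < rng[1] || max(target) > rng[2]) {
    stop("target grid extends beyond the source spectrum; refusing to extrapolate",
         call. = FALSE)
  }
  out <- stats::approx(spectrum$wavenumber, spectrum$intensity, xout = target)$y
  spectrum_tbl(target, out)
}

# Pseudo-Voigt profile: eta * Lorentzian + (1 - eta) * Gaussian, unit height
# at the center, FWHM-parameterized.
pseudo_voigt <- function(x, center, fwhm, eta) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  g <- exp(-((x - center)^2) / (2 * sigma^2))
  l <- gamma^2 / ((x - center)^2 + gamma^2)
  eta * l + (1 - eta) * g
}

#' Build a reference spectral library from peak descriptions
#'
#' A library is a named, max-normalized reference spectrum built as a sum of
#' pseudo-Voigt peaks. The instrument's true libraries (oxidized/reduced
#' hemoglobin, oxidized/reduced mitochondria) are proprietary; these synthetic
#' stand-ins only need the geometric properties the unmixing relies on:
#' non-negative, max = 1, and mutually distinguishable band positions.
#'
#' @param name Library name (e.g. `"HbO"`).
#' @param peaks A data frame with columns `center` (cm^-1), `fwhm` (cm^-1,
#'   `> 0`), `height` (relative, `>= 0`) and optionally `eta` (Lorentzian
#'   fraction in \[0, 1\], default 0.4).
#' @param grid Numeric wavenumber vector, e.g. [wn_grid()].
#' @return A tibble with columns `library`, `wavenumber`, `intensity`;
#'   `max(intensity) == 1`.
#' @export
make_library <- function(name, peaks, grid = wn_grid()) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0) stop("`peaks` must contain at least one peak", call. = FALSE)
  if (!all(c("center", "fwhm", "height") %in% names(peaks))) {
    stop("`peaks` needs columns center, fwhm, height", call. = FALSE)
  }
  if (!("eta" %in% names(peaks))) peaks$eta <- 0.4
  bad <- which(peaks$center < min(grid) | peaks$center > max(grid))
  if (length(bad)) {
    stop(sprintf("peak center %g cm^-1 lies outside the grid [%g, %g]",
                 peaks$center[bad[1]], min(grid), max(grid)), call. = FALSE)
  }
  if (any(peaks$fwhm <= 0)) stop("peak FWHM must be > 0", call. = FALSE)
  if (any(peaks$height < 0)) stop("peak height must be >= 0", call. = FALSE)
  y <- Reduce(`+`, purrr::pmap(
    list(peaks$center, peaks$fwhm, peaks$height, peaks$eta),
    function(c0, w, h, e) h * pseudo_voigt(grid, c0, w, e)
  ))
  m <- max(y)
  if (m <= 0) stop("library spectrum is identically zero", call. = FALSE)
  tibble::tibble(library = name, wavenumber = as.numeric(grid), intensity = y / m)
}

#' Default reference libraries
#'
#' Four synthetic libraries at heme-band-like positions: oxidized hemoglobin
#' (HbO, nu4 near 1375 cm^-1, nu2 near 1585), reduced hemoglobin (HbR, nu4
#' near 1357), and oxidized/reduced mitochondrial (cytochrome-like) spectra
#' with bands near 750/1128/1314/1585 cm^-1. Positions are configuration, not
#' measured truth; the only contract is pairwise cosine similarity < 0.99 so
#' the regression design is well conditioned.
#'
#' @param grid Numeric wavenumber vector.
#' @return A tibble with columns `library`, `wavenumber`, `intensity` stacking
#'   the four libraries (`HbO`, `HbR`, `MitoOx`, `MitoRed`).
#' @export
default_libraries <- function(grid = wn_grid()) {
  # eta = 0 (Gaussian limit of the pseudo-Voigt): Lorentzian tails would put
  # a slowly varying pedestal under the whole window that is indistinguishable
  # from fluorescence, biasing the baseline split. Band positions stay
  # configurable via make_library().
  peaksets <- list(
    HbO = tibble::tibble(
      center = c(675, 1375, 1505, 1585, 1640),
      fwhm   = c(16, 12, 14, 12, 14),
      height = c(0.35, 1.0, 0.4, 0.8, 0.5), eta = 0),
    HbR = tibble::tibble(
      center = c(672, 1357, 1473, 1552, 1607),
      fwhm   = c(16, 13, 15, 13, 14),
      height = c(0.4, 1.0, 0.35, 0.7, 0.45), eta = 0),
    MitoOx = tibble::tibble(
      center = c(750, 1128, 1314, 1560, 1636),
      fwhm   = c(12, 13, 15, 14, 13),
      height = c(0.8, 0.5, 0.6, 1.0, 0.3), eta = 0),
    MitoRed = tibble::tibble(
      center = c(748, 1170, 1300, 1494, 1620),
      fwhm   = c(12, 14, 16, 13, 14),
      height = c(1.0, 0.45, 0.7, 0.55, 0.6), eta = 0)
  )
  dplyr::bind_rows(purrr::imap(peaksets, function(p, nm) make_library(nm, p, grid)))
}

# Cosine similarity between two intensity vectors.
cosine_sim <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# Wide channel-by-library matrix from a stacked library tibble; errors on
# grid mismatch across libraries.
library_matrix <- function(libraries) {
  wide <- tidyr::pivot_wider(libraries, names_from = "library",
                             values_from = "intensity")
  if (anyNA(wide)) stop("libraries do not share a common wavenumber grid", call. = FALSE)
  m <- as.matrix(wide[, setdiff(names(wide), "wavenumber")])
  rownames(m) <- NULL
  attr(m, "wavenumber") <- wide$wavenumber
  m
}
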