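#' @importFrom rlang .data
NULL

# Frames are long tibbles: frame (integer), wavenumber (cm^-1), intensity.
# Internally most steps work on a channels x frames matrix.
frames_matrix <- function(frames) {
  stopifnot(all(c("frame", "wavenumber", "intensity") %in% names(frames)))
  wide <- tidyr::pivot_wider(frames, names_from = "frame",
                             values_from = "intensity")
  wide <- dplyr::arrange(wide, .data$wavenumber)
  if (anyNA(wide)) stop("frames do not share a common wavenumber grid", call. = FALSE)
  m <- as.matrix(wide[, setdiff(names(wide), "wavenumber")])
  attr(m, "wavenumber") <- wide$wavenumber
  m
}

matrix_frames <- function(m) {
  wn <- attr(m, "wavenumber")
  tibble::tibble(
    frame = rep(as.integer(colnames(m)), each = nrow(m)),
    wavenumber = rep(wn, times = ncol(m)),
    intensity = as.vector(m)
  )
}

#' Subtract a dark (detector background) spectrum from every frame
#'
#' The instrument records a dark spectrum in a lightless chamber; it is
#' subtracted channel-wise from each raw frame. Negative results are kept
#' (clipping would bias the later regression) and counted in a message.
#'
#' @param frames Long tibble with columns `frame`, `wavenumber`, `intensity`.
#' @param dark A spectrum tibble on the same wavenumber grid.
#' @return The frame tibble with dark-subtracted intensities.
#' @export
subtract_dark <- function(frames, dark) {
  stopifnot(is.data.frame(dark), all(c("wavenumber", "intensity") %in% names(dark)))
  grid <- sort(unique(frames$wavenumber))
  if (length(grid) != nrow(dark) ||
      any(abs(grid - sort(dark$wavenumber)) > 1e-8)) {
    stop("dark spectrum grid does not match the frame grid", call. = FALSE)
  }
  dk <- dark[order(dark$wavenumber), ]
  out <- dplyr::mutate(
    dplyr::arrange(frames, .data$frame, .data$wavenumber),
    intensity = .data$intensity - rep(dk$intensity, times = dplyr::n_distinct(.data$frame))
  )
  n_neg <- sum(out$intensity < 0)
  if (n_neg > 0) {
    rlang::inform(sprintf("subtract_dark: %d channel values went negative (kept)", n_neg))
  }
  out
}

#' Remove cosmic-ray spikes across frames
#'
#' Cosmic rays hit single CCD channels in single frames with large positive
#' amplitude. For each channel, values exceeding the across-frame median by
#' more than `z` robust standard deviations (1.4826 x MAD across frames) are
#' replaced by that median; everything else is untouched. With fewer than
#' three frames the across-frame statistics are meaningless and the input is
#' passed through with a warning.
#'
#' @param frames Long frame tibble.
#' @param z Threshold in robust SD units (default 8).
#' @return The despiked frame tibble.
#' @export
despike <- function(frames, z = 8) {
  m <- frames_matrix(frames)
  if (ncol(m) < 3) {
    warning("despike: fewer than 3 frames; returning input unchanged", call. = FALSE)
    return(frames)
  }
  med <- apply(m, 1, stats::median)
  rsd <- apply(m, 1, stats::mad)  # 1.4826 * MAD
  dev <- m - med
  hit <- dev > z * rsd            # strict: noiseless identical frames untouched
  if (any(hit)) {
    m[hit] <- med[row(m)[hit]]
  }
  out <- matrix_frames(m)
  attr(out, "n_despiked") <- sum(hit)
  out
}

#' Average the trailing window of frames into one spectrum
#'
#' Acquisitions are at least 180 s long at roughly one frame per second; the
#' analysis uses the average over the trailing 180-frame window (or all frames
#' when fewer are available), collapsing the sequence to a single raw spectrum
#' per measurement.
#'
#' @param frames Long frame tibble.
#' @param window Number of trailing frames to average (default 180).
#' @return A spectrum tibble (`wavenumber`, `intensity`).
#' @export
rolling_average <- function(frames, window = 180) {
  m <- frames_matrix(frames)
  n <- ncol(m)
  if (n < 1) stop("rolling_average: empty frame sequence", call. = FALSE)
  k <- min(window, n)
  sel <- seq.int(n - k + 1, n)
  spectrum_tbl(attr(m, "wavenumber"), rowMeans(m[, sel, drop = FALSE]))
}
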