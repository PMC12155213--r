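# Plain-text readers/writers for the pipeline's external formats. All files
# are headered CSVs; grids are validated on read.

#' Read and write spectral data as CSV
#'
#' Library CSVs have columns `wavenumber_cm1,intensity` (one file per
#' library, named by file stem unless `name` is given); frame CSVs are long
#' with `frame_index,wavenumber_cm1,intensity`; wound-metadata CSVs have
#' `pig_id,wound_id,block_temp_c,contact_s,heal_pod,depth_um,
#' epidermis_missing` with an empty `heal_pod` meaning unhealed at study end.
#'
#' @param path CSV file path.
#' @param name Library name; default the file stem.
#' @return The corresponding tibble in the package's internal column naming.
#' @name rrs_io
NULL

#' @rdname rrs_io
#' @export
read_library_csv <- function(path, name = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("wavenumber_cm1", "intensity") %in% names(d)))
  name <- name %||% sub("\\.csv$", "", basename(path))
  out <- tibble::tibble(library = name, wavenumber = d$wavenumber_cm1,
                        intensity = d$intensity)
  if (!is_uniform_grid(sort(out$wavenumber))) {
    stop(sprintf("%s: wavenumber grid is not uniform", path), call. = FALSE)
  }
  out
}

#' @rdname rrs_io
#' @param library A one-library tibble (`library`, `wavenumber`, `intensity`).
#' @export
write_library_csv <- function(library, path) {
  readr::write_csv(tibble::tibble(wavenumber_cm1 = library$wavenumber,
                                  intensity = library$intensity), path)
  invisible(path)
}

#' @rdname rrs_io
#' @export
read_frames_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("frame_index", "wavenumber_cm1", "intensity") %in% names(d)))
  tibble::tibble(frame = as.integer(d$frame_index),
                 wavenumber = d$wavenumber_cm1, intensity = d$intensity)
}

#' @rdname rrs_io
#' @param frames A long frame tibble.
#' @export
write_frames_csv <- function(frames, path) {
  readr::write_csv(tibble::tibble(frame_index = frames$frame,
                                  wavenumber_cm1 = frames$wavenumber,
                                  intensity = frames$intensity), path)
  invisible(path)
}

#' @rdname rrs_io
#' @export
read_wounds_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(heal_pod = readr::col_double()))
  need <- c("pig_id", "wound_id", "block_temp_c", "contact_s", "heal_pod",
            "depth_um", "epidermis_missing")
  stopifnot(all(need %in% names(d)))
  dplyr::mutate(d, epidermis_missing = as.logical(.data$epidermis_missing))
}

#' @rdname rrs_io
#' @param wounds A wound-metadata tibble.
#' @export
write_wounds_csv <- function(wounds, path) {
  readr::write_csv(wounds, path)
  invisible(path)
}
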