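# ggplot2 displays for the main result types. Styling is intentionally plain;
# these are working diagnostics, not figure-preparation tools.

#' Plot a decomposition: averaged spectrum, baseline, and library fit
#'
#' @param object An [decompose_frames()] result.
#' @param libraries The stacked library tibble used for the fit (needed to
#'   draw the fitted Raman component).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrs_decomposition <- function(object, libraries = NULL, ...) {
  spec <- attr(object, "spectrum")
  base <- attr(object, "baseline")
  d <- dplyr::bind_rows(
    dplyr::mutate(spec, component = "averaged spectrum"),
    dplyr::mutate(base, component = "fluorescence baseline"))
  if (!is.null(libraries)) {
    libs <- dplyr::filter(libraries,
                          .data$wavenumber >= min(spec$wavenumber),
                          .data$wavenumber <= max(spec$wavenumber))
    M <- library_matrix(libs)
    fitv <- drop(M[, c("HbR", "HbO", "MitoRed", "MitoOx")] %*%
                   c(object$a, object$b, object$m_r, object$m_o))
    d <- dplyr::bind_rows(d, tibble::tibble(
      wavenumber = attr(M, "wavenumber"),
      intensity = fitv + base$intensity,
      component = "baseline + library fit"))
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$intensity,
                                  color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "intensity (counts)", color = NULL)
}

#' Plot a ROC curve
#'
#' @param object An [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrs_roc <- function(object, ...) {
  cv <- dplyr::arrange(object$curve, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(cv, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.2f", object$auc))
}

#' Heatmap of category-by-day mean index
#'
#' Cells hold the mean index; the fill is saturated at `clamp` (default 10,
#' the display convention) while the underlying values stay unclamped. Rows
#' follow the hierarchical-clustering order.
#'
#' @param hm An [heatmap_matrix()] result.
#' @param clamp Display saturation level (default 10).
#' @return A ggplot object.
#' @export
plot_heatmap <- function(hm, clamp = 10) {
  stopifnot(inherits(hm, "rrs_heatmap"))
  d <- tibble::as_tibble(hm$matrix, rownames = "category")
  d <- tidyr::pivot_longer(d, -"category", names_to = "pod", values_to = "value")
  d$pod <- factor(as.numeric(d$pod), levels = sort(unique(as.numeric(d$pod))))
  d$category <- factor(d$category, levels = rev(hm$row_order))
  ggplot2::ggplot(d, ggplot2::aes(.data$pod, .data$category,
                                  fill = pmin(.data$value, clamp))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, clamp), name = "mean index") +
    ggplot2::labs(x = "post-operation day", y = NULL)
}

#' Category HI trajectories over time
#'
#' Mean +/- SEM per category per day from the per-wound table, the line-graph
#' view of the early healing phase.
#'
#' @param wound_table Per-wound tibble with `category`, `pod`, and the value
#'   column.
#' @param kind Value column (default `"hi"`).
#' @param max_pod Truncate the time axis (default `Inf`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(wound_table, kind = "hi", max_pod = Inf) {
  d <- dplyr::filter(wound_table, .data$pod <= max_pod, !is.na(.data[[kind]]))
  s <- dplyr::summarise(
    dplyr::group_by(d, .data$category, .data$pod),
    mean = mean(.data[[kind]]),
    sem = stats::sd(.data[[kind]]) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(.data$pod, .data$mean, color = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "post-operation day", y = toupper(kind), color = NULL)
}
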