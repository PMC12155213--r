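#' One-way ANOVA of index values across categories on one day
#'
#' Fixed-effects one-way ANOVA of the per-wound index against category for a
#' single assessment day. When the between-group sum of squares is exactly
#' zero (identical group constants) the conventional F = 0, p = 1 is
#' returned rather than 0/0.
#'
#' @param table Per-wound tibble with `category`, `pod` and the value column.
#' @param kind Value column name (default `"hi"`).
#' @param pod Assessment day to test.
#' @return A one-row tibble `(pod, kind, df_between, df_within, f, p)`.
#' @export
per_day_anova <- function(table, kind = "hi", pod) {
  d <- anova_day_data(table, kind, pod)
  ss <- stats::anova(stats::lm(value ~ category, data = d))
  f <- ss$`F value`[1]; p <- ss$`Pr(>F)`[1]
  if (ss$`Sum Sq`[1] <= 1e-12 * max(1, sum(ss$`Sum Sq`))) { f <- 0; p <- 1 }
  tibble::tibble(pod = pod, kind = kind,
                 df_between = ss$Df[1], df_within = ss$Df[2], f = f, p = p)
}

anova_day_data <- function(table, kind, pod) {
  stopifnot(kind %in% names(table))
  d <- dplyr::filter(table, .data$pod == !!pod, !is.na(.data[[kind]]))
  d <- tibble::tibble(category = factor(d$category), value = d[[kind]])
  sizes <- table(d$category)
  if (sum(sizes >= 2) < 2) {
    stop(sprintf("POD %g needs at least 2 categories with >= 2 wounds each", pod),
         call. = FALSE)
  }
  d
}

#' Tukey HSD pairwise comparisons for one day
#'
#' Studentized-range adjusted pairwise category comparisons following the
#' one-way ANOVA. With a zero residual variance the adjusted p is taken as 1
#' for zero differences and 0 otherwise (the studentized range statistic is
#' degenerate there).
#'
#' @inheritParams per_day_anova
#' @return A tibble `(pod, kind, comparison, diff, p_adj)`.
#' @export
tukey_hsd <- function(table, kind = "hi", pod) {
  d <- anova_day_data(table, kind, pod)
  fit <- stats::aov(value ~ category, data = d)
  mse <- sum(stats::residuals(fit)^2)
  tk <- suppressWarnings(stats::TukeyHSD(fit)$category)
  out <- tibble::tibble(pod = pod, kind = kind,
                        comparison = rownames(tk),
                        diff = tk[, "diff"], p_adj = tk[, "p adj"])
  if (mse <= 1e-12) {
    out$p_adj <- ifelse(abs(out$diff) <= 1e-12, 1, 0)
  }
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Thin, checked wrapper around the t-transform Pearson test used for the
#' index-vs-depth and index-vs-time-to-heal correlations.
#'
#' @param x,y Numeric vectors, `n >= 3`, finite, non-constant.
#' @return A one-row tibble `(r, p, n)`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson is undefined for a zero-variance argument", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Category-by-day mean index matrix with clustering
#'
#' Aggregates the per-wound table into the heatmap matrix: one cell per
#' (category, POD) holding the mean index over wounds, with missing POD 7
#' cells imputed from PODs 3 and 14 ([impute_pod7()]). Rows (categories) are
#' clustered hierarchically (Euclidean distance, average linkage) and, for
#' comparison, partitioned by seeded k-means; the stored values are never
#' clamped -- the 0--10 saturation is applied by the plotting function only.
#'
#' @param table Per-wound tibble (`category`, `pod`, value column).
#' @param kind Value column (default `"hi"`).
#' @param k Number of k-means clusters (default 2; the study's choice of k is
#'   unreported and k-means labels on 4 rows are fragile, so the hierarchical
#'   ordering is the authoritative output).
#' @param seed Seed for k-means restarts.
#' @return A list of class `rrs_heatmap`: `matrix` (categories x PODs),
#'   `imputed` (logical matrix), `hclust`, `row_order`, `kmeans_cluster`.
#' @export
heatmap_matrix <- function(table, kind = "hi", k = 2, seed = 1L) {
  stopifnot(kind %in% names(table))
  cells <- dplyr::summarise(
    dplyr::group_by(table, .data$category, .data$pod),
    value = mean(.data[[kind]], na.rm = TRUE), .groups = "drop")
  cells$value[is.nan(cells$value)] <- NA_real_
  cells <- impute_pod7(cells)
  if (anyNA(cells$value)) {
    bad <- cells[is.na(cells$value), ][1, ]
    stop(sprintf("empty heatmap cell after imputation: (%s, POD %g)",
                 bad$category, bad$pod), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(dplyr::select(cells, -"imputed"),
                             names_from = "pod", values_from = "value")
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$category
  imp <- tidyr::pivot_wider(dplyr::select(cells, -"value"),
                            names_from = "pod", values_from = "imputed")
  im <- as.matrix(imp[, -1]); rownames(im) <- imp$category
  hc <- if (nrow(m) > 1) stats::hclust(stats::dist(m), method = "average") else NULL
  km <- if (nrow(m) > k) {
    withr::with_seed(seed, stats::kmeans(m, centers = k, nstart = 10)$cluster)
  } else stats::setNames(rep(1L, nrow(m)), rownames(m))
  structure(list(matrix = m, imputed = im, hclust = hc,
                 row_order = if (is.null(hc)) rownames(m) else rownames(m)[hc$order],
                 kmeans_cluster = km),
            class = "rrs_heatmap")
}

#' Categories joined by the first hierarchical merge
#'
#' Convenience accessor: the pair of heatmap rows merged first by the
#' agglomerative clustering, i.e. the two categories with the most similar
#' index time courses.
#'
#' @param hm An [heatmap_matrix()] result.
#' @return Character vector of the two category names (or `NA` if fewer than
#'   2 rows).
#' @export
first_merge_pair <- function(hm) {
  stopifnot(inherits(hm, "rrs_heatmap"))
  if (is.null(hm$hclust)) return(NA_character_)
  m1 <- hm$hclust$merge[1, ]
  if (any(m1 > 0)) return(NA_character_)  # first merge always joins singletons
  rownames(hm$matrix)[-m1]
}
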