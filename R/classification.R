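#' Primary wound categorization from the burn-creation protocol
#'
#' Block temperature and skin-contact duration determine the intended depth:
#' 45 C gives Superficial, 96 C gives Full-thickness, and 63 C gives
#' PT-Superficial at 15--20 s or PT-Deep at 30--45 s of contact. 63 C contact
#' times outside those bands are a protocol gap and are rejected.
#'
#' @param temp Block temperature in C; one of 45, 63, 96.
#' @param duration Contact duration in seconds (required at 63 C).
#' @return Category string. Vectorized over `temp`/`duration`.
#' @export
primary_categorize <- function(temp, duration = NA_real_) {
  n <- max(length(temp), length(duration))
  temp <- rep_len(temp, n); duration <- rep_len(duration, n)
  purrr::map2_chr(temp, duration, function(tp, du) {
    if (!tp %in% c(45, 63, 96)) {
      stop(sprintf("block temperature %g C is not part of the protocol (45/63/96)", tp),
           call. = FALSE)
    }
    if (tp == 45) return("Superficial")
    if (tp == 96) return("Full-thickness")
    if (is.na(du) || du <= 0) stop("63 C wounds need a positive contact duration", call. = FALSE)
    if (du >= 15 && du <= 20) return("PT-Superficial")
    if (du >= 30 && du <= 45) return("PT-Deep")
    stop(sprintf("63 C contact duration %g s is outside the protocol bands (15-20, 30-45)", du),
         call. = FALSE)
  })
}

#' Secondary categorization by time to heal
#'
#' The primary partial-thickness assignment is confirmed against healing:
#' PT-Superficial is retained only if the wound closed by POD `pt_cutoff`
#' (56); PT-Deep only if it was still open at study end (POD `study_end`,
#' 64). Partial-thickness wounds violating their rule are excluded with
#' reason `"secondary-criterion"`. Superficial and Full-thickness wounds pass
#' through unchanged.
#'
#' @param records Wound tibble with columns `heal_pod` (`NA` = unhealed at
#'   study end) and `primary_category` (or `category`).
#' @param pt_cutoff Latest heal POD kept as PT-Superficial (default 56).
#' @param study_end Final assessment POD (default 64).
#' @return The tibble with `final_category` (`"Excluded"` where dropped),
#'   `included`, and `exclusion_reason` columns.
#' @export
secondary_categorize <- function(records, pt_cutoff = 56, study_end = 64) {
  cat_col <- if ("primary_category" %in% names(records)) "primary_category" else "category"
  stopifnot(cat_col %in% names(records), "heal_pod" %in% names(records))
  pc <- records[[cat_col]]
  if (any(pc %in% c("PT-Superficial", "PT-Deep") & is.na(records$heal_pod) == FALSE &
          records$heal_pod > study_end)) {
    stop("heal_pod beyond the study end is inconsistent", call. = FALSE)
  }
  healed_by_cutoff <- !is.na(records$heal_pod) & records$heal_pod <= pt_cutoff
  unhealed_at_end <- is.na(records$heal_pod)
  keep <- dplyr::case_when(
    pc == "PT-Superficial" ~ healed_by_cutoff,
    pc == "PT-Deep" ~ unhealed_at_end,
    TRUE ~ TRUE
  )
  dplyr::mutate(records,
                final_category = dplyr::if_else(keep, pc, "Excluded"),
                included = keep,
                exclusion_reason = dplyr::if_else(keep, NA_character_, "secondary-criterion"))
}

#' Adjust a histological depth score for a missing epidermis
#'
#' Depth is measured from the top of the section; when the epidermal layer
#' was lost, an average epidermal thickness of 100 um is added so scores are
#' comparable with intact-epidermis measurements.
#'
#' @param depth Raw depth score in um (`>= 0`).
#' @param epidermis_missing Logical flag.
#' @return Adjusted depth in um. Vectorized.
#' @export
adjust_depth_score <- function(depth, epidermis_missing) {
  if (any(depth < 0)) stop("depth scores must be >= 0", call. = FALSE)
  depth + 100 * as.numeric(epidermis_missing)
}

#' Histology depth-score quality control
#'
#' Inclusion filters on the adjusted depth score: Superficial < 250 um;
#' PT-Superficial <= 680 um; PT-Deep > 680 um; Full-thickness > 1750 um. The
#' 680 um papillary/reticular boundary itself is assigned to PT-Superficial
#' (the published rule removes scores "above" the cutoff for PT-Superficial
#' and "below" it for PT-Deep, leaving the boundary ambiguous); the
#' convention is overridable.
#'
#' @param category Final wound category. Vectorized with `depth`.
#' @param depth Adjusted depth score in um.
#' @param pt_boundary Papillary/reticular cutoff (default 680).
#' @param superficial_max,full_min Superficial and full-thickness cutoffs
#'   (defaults 250 and 1750).
#' @param boundary_to Category that keeps a score exactly at `pt_boundary`
#'   (default `"PT-Superficial"`).
#' @return Logical vector: `TRUE` = score passes QC.
#' @export
depth_score_qc <- function(category, depth, pt_boundary = 680,
                           superficial_max = 250, full_min = 1750,
                           boundary_to = "PT-Superficial") {
  if (any(depth < 0)) stop("depth scores must be >= 0", call. = FALSE)
  n <- max(length(category), length(depth))
  category <- rep_len(category, n); depth <- rep_len(depth, n)
  purrr::map2_lgl(category, depth, function(cat, d) {
    switch(cat,
           "Superficial" = d < superficial_max,
           "PT-Superficial" = if (boundary_to == "PT-Superficial") d <= pt_boundary else d < pt_boundary,
           "PT-Deep" = if (boundary_to == "PT-Superficial") d > pt_boundary else d >= pt_boundary,
           "Full-thickness" = d > full_min,
           stop(sprintf("unknown category `%s`", cat), call. = FALSE))
  })
}

#' Binary classification of an index value at a fixed cutoff
#'
#' Strict-inequality convention matching the published cutoffs ("HI > 3.54
#' indicates partial thickness"; "HI < 6.58 indicates PT-Deep"): a value
#' exactly at the threshold gets the negative class.
#'
#' @param value Index value(s).
#' @param threshold Cutoff.
#' @param direction `"greater"` (positive when value > threshold) or
#'   `"less"` (positive when value < threshold).
#' @return Logical vector: `TRUE` = positive class.
#' @export
classify_hi <- function(value, threshold, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(threshold))
  if (direction == "greater") value > threshold else value < threshold
}

#' Empirical ROC curve and Mann-Whitney AUC
#'
#' AUC is the Mann-Whitney concordance: the probability that a random
#' positive exceeds (direction `"greater"`) or falls below (`"less"`) a
#' random negative, ties counted one half. Computed via the rank-sum formula;
#' the per-threshold sensitivity/specificity trace is evaluated at midpoints
#' between consecutive observed values. The Hanley-McNeil standard error and
#' the two-sided Wilcoxon rank-sum p-value are reported.
#'
#' @param pos Values of the positive class (the deeper category in every
#'   pairing used here).
#' @param neg Values of the negative class.
#' @param direction Whether larger (`"greater"`) or smaller (`"less"`) values
#'   indicate the positive class; `"auto"` picks the direction whose AUC is
#'   >= 0.5.
#' @return A list of class `rrs_roc`: `curve` (tibble `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `se`, `p_value`, `direction`,
#'   `n_pos`, `n_neg`, plus the input values.
#' @export
roc_curve <- function(pos, neg, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (length(pos) < 1 || length(neg) < 1) {
    stop("both groups need at least one value", call. = FALSE)
  }
  auc_greater <- {
    r <- rank(c(pos, neg), ties.method = "average")
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }
  if (direction == "auto") direction <- if (auc_greater >= 0.5) "greater" else "less"
  auc <- if (direction == "greater") auc_greater else 1 - auc_greater
  vals <- sort(unique(c(pos, neg)))
  cand <- if (length(vals) > 1) (utils::head(vals, -1) + utils::tail(vals, -1)) / 2 else vals
  cand <- c(min(vals) - 1, cand, max(vals) + 1)
  curve <- purrr::map_dfr(cand, function(t) {
    called <- classify_hi(c(pos, neg), t, direction)
    tibble::tibble(threshold = t,
                   sensitivity = mean(called[seq_along(pos)]),
                   specificity = mean(!called[-seq_along(pos)]))
  })
  n1 <- length(pos); n2 <- length(neg)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n2 - 1) * (q2 - auc^2)) /
               (n1 * n2))
  p <- tryCatch(
    suppressWarnings(stats::wilcox.test(pos, neg, exact = FALSE)$p.value),
    error = function(e) NA_real_)
  structure(list(curve = curve, auc = auc, se = se, p_value = p,
                 direction = direction, n_pos = n1, n_neg = n2,
                 pos = pos, neg = neg),
            class = "rrs_roc")
}

#' @export
print.rrs_roc <- function(x, ...) {
  cat(sprintf("ROC (%s-is-positive): AUC = %.3f (SE %.3f, p = %.3g), n = %d vs %d\n",
              x$direction, x$auc, x$se, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal cutoff from a ROC curve
#'
#' Returns the threshold maximizing Youden's J = sensitivity + specificity -
#' 1. Thresholds are midpoints between consecutive observed values; among
#' tied maxima the highest-specificity (then highest) threshold is returned.
#' A flat J = 0 curve (AUC 0.5, identical groups) returns the lowest
#' candidate with a `degenerate` flag.
#'
#' @param roc An [roc_curve()] result.
#' @return A one-row tibble `(threshold, sensitivity, specificity, j,
#'   degenerate)`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "rrs_roc"))
  cv <- dplyr::mutate(roc$curve, j = .data$sensitivity + .data$specificity - 1)
  jmax <- max(cv$j)
  if (jmax <= 1e-12) {
    best <- cv[which.min(cv$threshold), ]
    return(dplyr::mutate(best, degenerate = TRUE))
  }
  ties <- cv[abs(cv$j - jmax) < 1e-12, ]
  ties <- dplyr::arrange(ties, dplyr::desc(.data$specificity), dplyr::desc(.data$threshold))
  dplyr::mutate(ties[1, ], degenerate = FALSE)
}
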