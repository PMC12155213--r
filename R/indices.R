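#' Hemoglobin Index of a single wound measurement
#'
#' HI is the wound's summed hemoglobin signal coefficients `a + b` divided by
#' the average `a + b` over exactly four healthy-skin measurements taken on
#' the same pig on the same day. The same-pig same-day normalization removes
#' device- and animal-level intensity differences; a wound at the healthy
#' perfusion level has HI = 1.
#'
#' @param wound One-row data frame with columns `a`, `b` (and optionally
#'   `pig`, `pod` for consistency checking).
#' @param healthy Four-row data frame of healthy measurements with `a`, `b`
#'   (and optionally `pig`, `pod`).
#' @return The HI value (scalar).
#' @export
hemoglobin_index <- function(wound, healthy) {
  index_ratio(wound, healthy, function(d) d$a + d$b, "a + b")
}

#' Fluorescence Index of a single wound measurement
#'
#' FI is the wound's fluorescence-baseline magnitude `c` divided by the
#' average `c` of the four same-pig same-day healthy measurements; a proxy
#' for endogenous fluorophores (collagen/elastin crosslinks, NADH).
#'
#' @inheritParams hemoglobin_index
#' @return The FI value (scalar).
#' @export
fluorescence_index <- function(wound, healthy) {
  index_ratio(wound, healthy, function(d) d$c, "c")
}

index_ratio <- function(wound, healthy, f, what) {
  if (nrow(wound) != 1) stop("`wound` must be a single measurement", call. = FALSE)
  if (nrow(healthy) != 4) {
    stop(sprintf("normalization requires exactly 4 healthy measurements, got %d",
                 nrow(healthy)), call. = FALSE)
  }
  for (key in c("pig", "pod")) {
    if (key %in% names(wound) && key %in% names(healthy) &&
        !all(healthy[[key]] == wound[[key]])) {
      stop(sprintf("healthy measurements must match the wound's `%s`", key), call. = FALSE)
    }
  }
  denom <- mean(f(healthy))
  if (denom <= 0) {
    stop(sprintf("healthy normalization factor mean(%s) must be > 0", what), call. = FALSE)
  }
  f(wound) / denom
}

#' Average surviving site values into one index per wound
#'
#' Each wound is measured at two central sites; after outlier screening 1 or 2
#' values survive and are averaged into the wound's unique index for the day.
#' A single-survivor average is flagged; zero survivors mark the wound missing
#' for that day.
#'
#' @param values Numeric vector of 0--2 surviving site index values.
#' @return A one-row tibble `(value, n_sites, single_site, missing)`.
#' @export
per_wound_index <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) > 2) stop("at most 2 site values per wound per day", call. = FALSE)
  if (length(values) == 0) {
    return(tibble::tibble(value = NA_real_, n_sites = 0L,
                          single_site = FALSE, missing = TRUE))
  }
  tibble::tibble(value = mean(values), n_sites = length(values),
                 single_site = length(values) == 1, missing = FALSE)
}

#' Impute a missing POD 7 cell from its neighbors
#'
#' The study lost POD 7 measurements for some categories (device malfunction
#' plus categorization removals); for heatmap aggregation only, a missing
#' POD 7 mean is imputed as the average of the POD 3 and POD 14 means. The
#' imputation is flagged and must never feed per-day inference.
#'
#' @param series Tibble `(category, pod, value)` of per-category means.
#' @return The series with missing POD 7 cells filled and a logical
#'   `imputed` column.
#' @export
impute_pod7 <- function(series) {
  stopifnot(all(c("category", "pod", "value") %in% names(series)))
  series <- dplyr::mutate(series, imputed = FALSE)
  for (cat in unique(series$category)) {
    rows <- series$category == cat
    p7 <- which(rows & series$pod == 7)
    needs <- length(p7) == 0 || all(is.na(series$value[p7]))
    if (!needs) next
    v3 <- series$value[rows & series$pod == 3]
    v14 <- series$value[rows & series$pod == 14]
    if (length(v3) != 1 || length(v14) != 1 || is.na(v3) || is.na(v14)) {
      stop(sprintf("cannot impute POD 7 for %s: POD 3 and POD 14 must both be present", cat),
           call. = FALSE)
    }
    if (length(p7) == 0) {
      series <- dplyr::bind_rows(series, tibble::tibble(
        category = cat, pod = 7, value = mean(c(v3, v14)), imputed = TRUE))
    } else {
      series$value[p7] <- mean(c(v3, v14))
      series$imputed[p7] <- TRUE
    }
  }
  dplyr::arrange(series, .data$category, .data$pod)
}

#' Per-wound index table from a study coefficient table
#'
#' Table-level pipeline from decomposed acquisitions to one HI and FI per
#' wound per day: (1) per-site HI/FI against the same-pig same-day healthy
#' average, (2) ROUT outlier screening on the site HIs pooled per category per
#' day, (3) averaging of surviving sites per wound.
#'
#' @param coefficients Tibble with `pig`, `wound` (`NA` for healthy rows),
#'   `category`, `pod`, `site`, `a`, `b`, `c`.
#' @param q ROUT false-discovery level (default 0.02); `q = 0` disables
#'   removal.
#' @return A list with `site` (per-site indices with a `removed` flag) and
#'   `wound` (per-wound table: `pig`, `wound`, `category`, `pod`, `hi`, `fi`,
#'   `n_sites`, `single_site`, `missing`).
#' @export
index_table <- function(coefficients, q = 0.02) {
  healthy <- dplyr::filter(coefficients, .data$category == "healthy")
  wounds <- dplyr::filter(coefficients, .data$category != "healthy")
  hmean <- dplyr::summarise(
    dplyr::group_by(healthy, .data$pig, .data$pod),
    n_healthy = dplyr::n(),
    healthy_ab = mean(.data$a + .data$b),
    healthy_c = mean(.data$c), .groups = "drop")
  if (any(hmean$n_healthy != 4)) {
    bad <- hmean[hmean$n_healthy != 4, ][1, ]
    stop(sprintf("pig %s POD %g has %d healthy measurements; exactly 4 are required",
                 bad$pig, bad$pod, bad$n_healthy), call. = FALSE)
  }
  site <- dplyr::left_join(wounds, hmean, by = c("pig", "pod"))
  if (anyNA(site$healthy_ab)) {
    stop("some wound measurements have no same-pig same-day healthy normalization",
         call. = FALSE)
  }
  site <- dplyr::mutate(site,
                        hi = (.data$a + .data$b) / .data$healthy_ab,
                        fi = .data$c / .data$healthy_c)
  # ROUT per category per day on the pooled site HIs
  site <- dplyr::group_modify(
    dplyr::group_by(site, .data$category, .data$pod),
    function(d, key) {
      if (q <= 0 || nrow(d) < 3) {
        d$removed <- FALSE
      } else {
        res <- rout_outliers(d$hi, q = q)
        d$removed <- res$removed_index
      }
      d
    })
  site <- dplyr::ungroup(site)
  wound <- dplyr::reframe(
    dplyr::group_by(site, .data$pig, .data$wound, .data$category, .data$pod),
    {
      kept <- !.data$removed
      hi_s <- per_wound_index(.data$hi[kept])
      fi_s <- per_wound_index(.data$fi[kept])
      tibble::tibble(hi = hi_s$value, fi = fi_s$value, n_sites = hi_s$n_sites,
                     single_site = hi_s$single_site, missing = hi_s$missing)
    })
  list(site = site, wound = dplyr::ungroup(wound))
}
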