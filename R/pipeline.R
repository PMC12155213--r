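#' Pipeline configuration
#'
#' Every numeric constant of the analysis in one flat, serializable list:
#' analysis window, baseline degree, frame window, outlier Q, published HI
#' cutoffs, histology QC cutoffs, secondary-criterion PODs, and the laser
#' metadata (recorded for provenance, never computed on). Round-trips
#' losslessly through JSON ([write_config()] / [read_config()]).
#'
#' @param crop_low,crop_high Analysis window, cm^-1 (600, 1700).
#' @param degree Baseline polynomial degree (5).
#' @param window Frame-averaging window (180).
#' @param q ROUT false-discovery level (0.02).
#' @param cutoff_pt HI cutoff above which a wound is called partial-thickness
#'   (3.54).
#' @param cutoff_pt_deep HI cutoff below which a partial-thickness wound is
#'   called PT-Deep (6.58).
#' @param depth_superficial,depth_pt_boundary,depth_full Depth QC cutoffs in
#'   um (250, 680, 1750).
#' @param epidermis_add Depth added for a missing epidermis, um (100).
#' @param pt_heal_cutoff,study_end Secondary-criterion PODs (56, 64).
#' @param seed Integer seed for all randomness.
#' @param laser_nm,laser_mw Laser metadata (441 nm, 8.9 mW).
#' @return A list of class `rrs_config`.
#' @export
pipeline_config <- function(crop_low = 600, crop_high = 1700, degree = 5,
                            window = 180, q = 0.02,
                            cutoff_pt = 3.54, cutoff_pt_deep = 6.58,
                            depth_superficial = 250, depth_pt_boundary = 680,
                            depth_full = 1750, epidermis_add = 100,
                            pt_heal_cutoff = 56, study_end = 64,
                            seed = 1L, laser_nm = 441, laser_mw = 8.9) {
  structure(list(crop_low = crop_low, crop_high = crop_high, degree = degree,
                 window = window, q = q, cutoff_pt = cutoff_pt,
                 cutoff_pt_deep = cutoff_pt_deep,
                 depth_superficial = depth_superficial,
                 depth_pt_boundary = depth_pt_boundary,
                 depth_full = depth_full, epidermis_add = epidermis_add,
                 pt_heal_cutoff = pt_heal_cutoff, study_end = study_end,
                 seed = as.integer(seed), laser_nm = laser_nm,
                 laser_mw = laser_mw),
            class = "rrs_config")
}

#' @rdname pipeline_config
#' @param config An `rrs_config` object.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Run the whole simulated-study pipeline
#'
#' End-to-end: simulate the study layout, decompose every acquisition through
#' the spectral pipeline, compute per-site and per-wound indices with ROUT
#' screening, run the POD 3 ROC comparisons and fixed-cutoff classifiers, and
#' aggregate the heatmap. Identical `config`/`sim`/`design` inputs give an
#' identical bundle.
#'
#' @param config An [pipeline_config()].
#' @param design An [study_design()].
#' @param sim An [sim_config()]; its seed defaults to `config$seed`.
#' @param days Subset of PODs to run (default: all design days; the full
#'   12-day study through the spectral pipeline is minutes of compute).
#' @param roc_pod Day used for the ROC analyses (default 3).
#' @return A list of class `rrs_bundle`: `coefficients`, `indices` (site +
#'   wound tables), `anova`, `roc` (list per category pairing), `cutoffs`,
#'   `heatmap` (only when all design days were run), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), design = study_design(),
                         sim = NULL, days = NULL, roc_pod = 3) {
  sim <- sim %||% sim_config(seed = config$seed)
  study <- simulate_study(design, sim, days = days)
  libraries <- default_libraries(sim$grid)
  coefs <- decompose_study(study, libraries)
  idx <- index_table(coefs, q = config$q)
  wound <- idx$wound
  pods <- sort(unique(wound$pod))
  anova_tbl <- purrr::map_dfr(pods, function(p) {
    tryCatch(per_day_anova(wound, "hi", p), error = function(e) tibble::tibble())
  })
  day3 <- dplyr::filter(wound, .data$pod == roc_pod, !.data$missing)
  grp <- function(cats) day3$hi[day3$category %in% cats]
  rocs <- list(
    superficial_vs_pt = roc_curve(grp(c("PT-Superficial", "PT-Deep")),
                                  grp("Superficial"), direction = "greater"),
    pt_vs_full = roc_curve(grp(c("PT-Superficial", "PT-Deep")),
                           grp("Full-thickness"), direction = "greater"),
    pts_vs_ptd = roc_curve(grp("PT-Deep"), grp("PT-Superficial"),
                           direction = "less")
  )
  cutoffs <- tibble::tibble(
    comparison = c("superficial_vs_pt", "pts_vs_ptd"),
    published = c(config$cutoff_pt, config$cutoff_pt_deep),
    youden = c(youden_cutoff(rocs$superficial_vs_pt)$threshold,
               youden_cutoff(rocs$pts_vs_ptd)$threshold)
  )
  hm <- if (setequal(pods, design$days)) heatmap_matrix(wound, "hi", seed = config$seed) else NULL
  structure(list(coefficients = coefs, indices = idx, anova = anova_tbl,
                 roc = rocs, cutoffs = cutoffs, heatmap = hm, config = config),
            class = "rrs_bundle")
}

#' Validate pipeline input tables
#'
#' Report-only structural checks: required columns, uniform wavenumber grids,
#' exactly four healthy sites per pig per day (the index denominator averages
#' four), and at most two central sites per wound per day. Returns a tibble
#' of findings rather than erroring, so malformed inputs can be triaged.
#'
#' @param frames Optional long frame tibble.
#' @param libraries Optional stacked library tibble.
#' @param coefficients Optional study coefficient table (as from
#'   [decompose_study()]).
#' @return A tibble `(severity, check, message)`; zero rows means all checks
#'   passed.
#' @export
validate_inputs <- function(frames = NULL, libraries = NULL, coefficients = NULL) {
  findings <- list()
  note <- function(severity, check, message) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      severity = severity, check = check, message = message)
  }
  if (!is.null(frames)) {
    need <- c("frame", "wavenumber", "intensity")
    if (!all(need %in% names(frames))) {
      note("error", "frames-columns",
           paste("frames must have columns", paste(need, collapse = ", ")))
    } else {
      grids <- dplyr::summarise(dplyr::group_by(frames, .data$frame),
                                uniform = is_uniform_grid(sort(.data$wavenumber)),
                                .groups = "drop")
      if (!all(grids$uniform)) {
        note("error", "frames-grid", "non-uniform wavenumber grid in at least one frame")
      }
    }
  }
  if (!is.null(libraries)) {
    if (!all(c("library", "wavenumber", "intensity") %in% names(libraries))) {
      note("error", "library-columns", "libraries must have columns library, wavenumber, intensity")
    } else {
      ok <- tryCatch({ library_matrix(libraries); TRUE }, error = function(e) FALSE)
      if (!ok) note("error", "library-grid", "libraries do not share one wavenumber grid")
      mx <- dplyr::summarise(dplyr::group_by(libraries, .data$library),
                             m = max(.data$intensity), .groups = "drop")
      if (any(abs(mx$m - 1) > 1e-6)) {
        note("warning", "library-normalization",
             "library maxima differ from 1; libraries are expected max-normalized")
      }
    }
  }
  if (!is.null(coefficients)) {
    healthy <- dplyr::filter(coefficients, .data$category == "healthy")
    cnt <- dplyr::count(healthy, .data$pig, .data$pod)
    bad <- dplyr::filter(cnt, .data$n != 4)
    for (i in seq_len(nrow(bad))) {
      note("error", "healthy-count",
           sprintf("pig %s POD %g has %d healthy sites; the index normalization averages exactly 4",
                   bad$pig[i], bad$pod[i], bad$n[i]))
    }
    wcnt <- dplyr::count(dplyr::filter(coefficients, .data$category != "healthy"),
                         .data$pig, .data$wound, .data$pod)
    over <- dplyr::filter(wcnt, .data$n > 2)
    for (i in seq_len(nrow(over))) {
      note("error", "site-count",
           sprintf("pig %s wound %s POD %g has %d central sites (max 2)",
                   over$pig[i], over$wound[i], over$pod[i], over$n[i]))
    }
  }
  if (length(findings) == 0) {
    tibble::tibble(severity = character(), check = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}
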