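#' Simulation configuration
#'
#' Settings for the synthetic frame generator. Defaults follow the measurement
#' protocol: 180 one-second frames per acquisition, 500--1800 cm^-1 raw grid
#' at 2 cm^-1. The noise SD is expressed as a fraction of the maximum of the
#' clean (noiseless) frame so that "1% noise" means the same thing whatever
#' the hemoglobin amplitude. Cosmic spikes hit one random channel per affected
#' frame with large positive amplitude.
#'
#' @param grid Raw wavenumber grid.
#' @param n_frames Frames per acquisition (default 180).
#' @param noise_sd Gaussian noise SD as a fraction of the clean-frame maximum
#'   (default 0.01).
#' @param spike_prob Per-frame probability of a cosmic spike (default 0.02).
#' @param spike_amp Spike amplitude as a multiple of the clean-frame maximum
#'   (default 5).
#' @param baseline_coefs Six coefficients of the degree-5 fluorescence
#'   polynomial on the normalized abscissa; the curve is rescaled so its mean
#'   over the analysis window equals the requested `c`. The default is a
#'   broad positive hump.
#' @param crop_low,crop_high Analysis window used for the `c` normalization.
#' @param seed Integer seed; every generator is a pure function of
#'   (inputs, seed).
#' @return A list of class `rrs_sim_config`.
#' @export
sim_config <- function(grid = wn_grid(), n_frames = 180, noise_sd = 0.01,
                       spike_prob = 0.02, spike_amp = 5,
                       baseline_coefs = c(1.0, -0.15, -0.55, 0.05, 0.12, -0.02),
                       crop_low = 600, crop_high = 1700, seed = 1L) {
  stopifnot(n_frames >= 1, noise_sd >= 0, spike_prob >= 0, spike_prob < 1,
            length(baseline_coefs) == 6)
  structure(list(grid = grid, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, spike_prob = spike_prob,
                 spike_amp = spike_amp, baseline_coefs = baseline_coefs,
                 crop_low = crop_low, crop_high = crop_high,
                 seed = as.integer(seed)),
            class = "rrs_sim_config")
}

# Degree-5 fluorescence curve on `grid`, rescaled so its mean over the
# analysis window equals c_target. Returns zeros when c_target is 0.
baseline_curve <- function(grid, coefs, c_target, crop_low, crop_high) {
  x <- (grid - mean(grid)) / (diff(range(grid)) / 2)
  raw <- drop(outer(x, 0:5, `^`) %*% coefs)
  raw <- raw - min(raw) + 0.05 * (max(raw) - min(raw) + .Machine$double.eps)
  inwin <- grid >= crop_low & grid <= crop_high
  m <- mean(raw[inwin])
  if (c_target == 0) return(rep(0, length(grid)))
  raw * (c_target / m)
}

#' Simulate a raw frame sequence
#'
#' Each frame is the weighted library sum `a*HbR + b*HbO + m_r*MitoRed +
#' m_o*MitoOx`, plus a smooth degree-5 fluorescence baseline scaled so that
#' its mean over the analysis window equals `c`, plus i.i.d. Gaussian noise,
#' plus sparse single-channel cosmic spikes. Identical seeds give bit-identical
#' sequences.
#'
#' @param coeffs Named list or one-row data frame with non-negative `a`, `b`,
#'   `m_r`, `m_o`, `c`.
#' @param libraries Stacked library tibble on `config$grid`.
#' @param config An [sim_config()] object.
#' @return A long frame tibble (`frame`, `wavenumber`, `intensity`).
#' @export
simulate_frames <- function(coeffs, libraries, config = sim_config()) {
  co <- as.list(coeffs)
  for (nm in c("a", "b", "m_r", "m_o", "c")) {
    if (is.null(co[[nm]])) co[[nm]] <- 0
    if (co[[nm]] < 0) stop(sprintf("true coefficient `%s` must be >= 0", nm), call. = FALSE)
  }
  M <- library_matrix(libraries)
  grid <- attr(M, "wavenumber")
  if (length(grid) != length(config$grid) || any(abs(grid - config$grid) > 1e-8)) {
    stop("libraries are not on the configured grid", call. = FALSE)
  }
  need <- c("HbR", "HbO", "MitoRed", "MitoOx")
  if (!all(need %in% colnames(M))) stop("libraries must include HbR, HbO, MitoRed, MitoOx", call. = FALSE)
  clean <- drop(M[, need] %*% c(co$a, co$b, co$m_r, co$m_o)) +
    baseline_curve(grid, config$baseline_coefs, co$c, config$crop_low, config$crop_high)
  peak <- max(clean, 0)
  nch <- length(grid)
  withr::with_seed(config$seed, {
    noise <- if (config$noise_sd > 0 && peak > 0) {
      matrix(stats::rnorm(nch * config$n_frames, sd = config$noise_sd * peak),
             nch, config$n_frames)
    } else matrix(0, nch, config$n_frames)
    m <- clean + noise
    if (config$spike_prob > 0 && peak > 0) {
      hit <- stats::runif(config$n_frames) < config$spike_prob
      for (j in which(hit)) {
        ch <- sample.int(nch, 1)
        m[ch, j] <- m[ch, j] + config$spike_amp * peak
      }
    }
  })
  colnames(m) <- seq_len(config$n_frames)
  attr(m, "wavenumber") <- grid
  matrix_frames(m)
}

#' Study design for the multi-depth porcine burn model
#'
#' Describes the study layout the simulator emulates: 3 pigs with 8 wounds
#' each, four depth categories (4 superficial at 45 C, 8 PT-Superficial at
#' 63 C/15-20 s, 6 PT-Deep at 63 C/30-45 s, 6 full-thickness at 96 C),
#' assessed on 12 post-operation days with 2 central wound sites and 4 healthy
#' sites per pig per day. Category-to-position assignment is randomized but
#' seed-reproducible.
#'
#' @param pigs Number of pigs (default 3).
#' @param days Assessment days (PODs).
#' @param category_counts Named integer vector of initial wound counts per
#'   category; must sum to `pigs * 8`.
#' @param sites_per_wound Central measurement sites per wound per day (2).
#' @param healthy_sites Healthy sites per pig per day (4; the Hemoglobin Index
#'   denominator averages exactly four).
#' @param trajectories Trajectory tibble `(category, pod, hi_multiplier,
#'   fi_multiplier)`; default [default_trajectories()].
#' @param baseline_amplitude Healthy-skin summed hemoglobin amplitude `a + b`
#'   in detector units (default 10).
#' @param baseline_c Healthy-skin fluorescence magnitude `c` (default 50;
#'   fluorescence dominates the raw spectrum in tissue).
#' @param hbo_fraction Fraction of the hemoglobin amplitude assigned to HbO
#'   (default 0.7; the Hemoglobin Index uses the sum `a + b`, so this split
#'   does not affect it).
#' @param site_cv Site-to-site coefficient of variation of the hemoglobin
#'   amplitude (default 0.05), modeling local heterogeneity of perfusion.
#' @return A list of class `rrs_study_design`.
#' @export
study_design <- function(pigs = 3,
                         days = c(0, 2, 3, 7, 14, 21, 28, 35, 42, 49, 56, 64),
                         category_counts = c("Superficial" = 4, "PT-Superficial" = 8,
                                             "PT-Deep" = 6, "Full-thickness" = 6),
                         sites_per_wound = 2, healthy_sites = 4,
                         trajectories = default_trajectories(),
                         baseline_amplitude = 10, baseline_c = 50,
                         hbo_fraction = 0.7, site_cv = 0.05) {
  if (healthy_sites < 1) {
    stop("healthy_sites must be >= 1: the index normalization is impossible without healthy measurements",
         call. = FALSE)
  }
  if (baseline_amplitude <= 0) stop("baseline_amplitude must be > 0", call. = FALSE)
  if (sum(category_counts) != pigs * 8) {
    stop("category_counts must sum to 8 wounds per pig", call. = FALSE)
  }
  structure(list(pigs = pigs, days = days, category_counts = category_counts,
                 sites_per_wound = sites_per_wound, healthy_sites = healthy_sites,
                 trajectories = tibble::as_tibble(trajectories),
                 baseline_amplitude = baseline_amplitude, baseline_c = baseline_c,
                 hbo_fraction = hbo_fraction, site_cv = site_cv),
            class = "rrs_study_design")
}

#' Default category-level index trajectories
#'
#' Ground-truth Hemoglobin Index multipliers per (category, POD): the value by
#' which a wound's hemoglobin amplitude exceeds the healthy baseline, so the
#' pipeline's recovered HI has this multiplier as its expectation. Anchors are
#' the published category means (e.g. PT-Superficial POD3 = 9.19,
#' Full-thickness POD3 = 0.18); cells without a printed value are linear
#' interpolations between anchors, with late unreported days decaying gently
#' toward the healthy baseline. Fluorescence multipliers are a mild late-phase
#' rise for the deeper categories (fibrotic fluorophore deposition), not
#' asserted against any printed value.
#'
#' @return A tibble `(category, pod, hi_multiplier, fi_multiplier)` covering
#'   all 4 categories x 12 PODs.
#' @export
default_trajectories <- function() {
  pods <- c(0, 2, 3, 7, 14, 21, 28, 35, 42, 49, 56, 64)
  hi <- list(
    "Superficial"    = c(0.80, 1.20, 1.67, 1.40, 1.20, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    "PT-Superficial" = c(1.31, 6.56, 9.19, 7.29, 5.39, 1.70, 1.50, 1.40, 1.30, 1.20, 1.10, 1.00),
    "PT-Deep"        = c(2.02, 5.03, 6.54, 5.81, 4.53, 3.26, 3.00, 2.70, 2.40, 2.10, 1.80, 1.50),
    "Full-thickness" = c(2.63, 1.00, 0.18, 7.23, 9.85, 4.03, 3.80, 3.57, 3.35, 3.12, 2.86, 2.63)
  )
  fi <- list(
    "Superficial"    = rep(1, 12),
    "PT-Superficial" = c(1, 1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.6, 1.6, 1.5, 1.5, 1.4),
    "PT-Deep"        = c(1, 1, 1.2, 1.4, 1.6, 1.9, 2.2, 2.5, 2.8, 3.0, 3.2, 3.4),
    "Full-thickness" = c(1, 1, 1.3, 1.6, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5)
  )
  dplyr::bind_rows(purrr::imap(hi, function(v, nm) {
    tibble::tibble(category = nm, pod = pods, hi_multiplier = v,
                   fi_multiplier = fi[[nm]])
  }))
}

#' Simulate a whole study (ground truth + acquisition plan)
#'
#' Assigns wound categories to positions (seed-reproducible), then lays out
#' one acquisition per site per pig per day: healthy sites at the baseline
#' hemoglobin amplitude, wound sites at `hi_multiplier(category, pod)` times
#' the baseline, with mild per-site multiplicative jitter of CV
#' `site_cv`. Raw frames are not stored (a full study is hundreds of
#' acquisitions); each acquisition row carries its own sub-seed so
#' [decompose_study()] can regenerate its frames deterministically on demand.
#'
#' @param design An [study_design()] object.
#' @param config An [sim_config()] object; `config$seed` drives all
#'   randomness.
#' @param days Optional subset of PODs to lay out (default: all design days).
#' @return A list of class `rrs_study` with `wounds` (ground-truth wound
#'   table: pig, wound, category, temperature, contact time, heal day, depth
#'   score) and `truth` (acquisition-level table with true `a`, `b`, `c` and
#'   the embedded multiplier).
#' @export
simulate_study <- function(design = study_design(), config = sim_config(),
                           days = NULL) {
  days <- days %||% design$days
  traj <- design$trajectories
  needed <- tidyr::expand_grid(category = names(design$category_counts), pod = days)
  missing <- dplyr::anti_join(needed, traj, by = c("category", "pod"))
  if (nrow(missing) > 0) {
    stop(sprintf("trajectory table is missing (%s, POD %g)",
                 missing$category[1], missing$pod[1]), call. = FALSE)
  }
  withr::with_seed(config$seed, {
    categories <- sample(rep(names(design$category_counts), design$category_counts))
    wounds <- tibble::tibble(
      pig = rep(seq_len(design$pigs), each = 8),
      wound = rep(seq_len(8), times = design$pigs),
      category = categories
    )
    wounds <- dplyr::mutate(
      wounds,
      block_temp_c = dplyr::case_when(
        .data$category == "Superficial" ~ 45,
        .data$category == "Full-thickness" ~ 96,
        TRUE ~ 63),
      contact_s = dplyr::case_when(
        .data$category == "PT-Superficial" ~ sample(15:20, dplyr::n(), replace = TRUE),
        .data$category == "PT-Deep" ~ sample(30:45, dplyr::n(), replace = TRUE),
        TRUE ~ 30L)
    )
    site_rows <- dplyr::bind_rows(
      tidyr::expand_grid(wounds, pod = days,
                         site = paste0("central-", seq_len(design$sites_per_wound))),
      tidyr::expand_grid(
        tibble::tibble(pig = seq_len(design$pigs), wound = NA_integer_,
                       category = "healthy", block_temp_c = NA_real_,
                       contact_s = NA_integer_),
        pod = days, site = paste0("healthy-", seq_len(design$healthy_sites)))
    )
    site_rows <- dplyr::left_join(site_rows, traj, by = c("category", "pod"))
    site_rows <- dplyr::mutate(
      site_rows,
      hi_multiplier = dplyr::if_else(.data$category == "healthy", 1, .data$hi_multiplier),
      fi_multiplier = dplyr::if_else(.data$category == "healthy", 1, .data$fi_multiplier),
      site_factor = pmax(stats::rnorm(dplyr::n(), mean = 1, sd = design$site_cv), 0.05),
      amplitude = design$baseline_amplitude * .data$hi_multiplier * .data$site_factor,
      a = .data$amplitude * (1 - design$hbo_fraction),
      b = .data$amplitude * design$hbo_fraction,
      c = design$baseline_c * .data$fi_multiplier,
      sub_seed = sample.int(.Machine$integer.max - 1L, dplyr::n())
    )
  })
  structure(list(wounds = wounds, truth = site_rows, design = design,
                 config = config),
            class = "rrs_study")
}

#' Decompose every acquisition of a simulated study
#'
#' Regenerates each acquisition's frames from its stored sub-seed and runs the
#' full spectral pipeline ([decompose_frames()]) on them, returning the
#' study's signal-coefficient table keyed by (pig, wound/healthy, POD, site).
#'
#' @param study An [simulate_study()] result.
#' @param libraries Stacked library tibble on the configured grid (default
#'   [default_libraries()] on `study$config$grid`).
#' @return A tibble: one row per acquisition with identifiers, recovered `a`,
#'   `b`, `m_r`, `m_o`, `c`, `residual_rms`, plus the embedded ground-truth
#'   multiplier.
#' @export
decompose_study <- function(study, libraries = NULL) {
  stopifnot(inherits(study, "rrs_study"))
  libraries <- libraries %||% default_libraries(study$config$grid)
  cfg <- study$config
  rows <- study$truth
  res <- purrr::map(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    cfg_i <- cfg
    cfg_i$seed <- r$sub_seed
    fr <- simulate_frames(list(a = r$a, b = r$b, m_r = 0, m_o = 0, c = r$c),
                          libraries, cfg_i)
    decompose_frames(fr, libraries, window = cfg$n_frames)
  })
  dplyr::bind_cols(
    dplyr::select(rows, "pig", "wound", "category", "pod", "site",
                  "hi_multiplier", "fi_multiplier"),
    dplyr::bind_rows(lapply(res, function(x) {
      tibble::as_tibble(unclass(x)[c("a", "b", "m_r", "m_o", "c",
                                     "residual_rms", "baseline_converged")])
    }))
  )
}
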