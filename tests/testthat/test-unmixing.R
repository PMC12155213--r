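# Baseline extraction, non-negative library regression, and the composed
# decomposition.

test_that("fit_baseline recovers a pure polynomial as its own baseline", {
  wn <- wn_grid(600, 1700, 2)
  x <- (wn - mean(wn)) / 550
  y <- 10 + 3 * x - 2 * x^2 + 0.5 * x^5
  bl <- fit_baseline(spectrum_tbl(wn, y))
  expect_equal(bl$baseline$intensity, y, tolerance = 1e-8)
  expect_equal(bl$c, mean(y), tolerance = 1e-8)
  expect_true(bl$converged)
})

test_that("fit_baseline separates a narrow peak from the fluorescence floor", {
  wn <- wn_grid(600, 1700, 2)
  x <- (wn - mean(wn)) / 550
  poly_true <- 20 + 5 * x - 8 * x^2 + 2 * x^3
  peak <- 30 * exp(-((wn - 1150)^2) / (2 * 5^2))
  bl <- fit_baseline(spectrum_tbl(wn, poly_true + peak))
  expect_equal(bl$c, mean(poly_true), tolerance = 0.02 * mean(poly_true))
  resid <- poly_true + peak - bl$baseline$intensity
  expect_gt(min(resid), -0.05 * max(peak))  # baseline stays at or below peaks
})

test_that("fit_baseline handles degenerate inputs per contract", {
  wn <- wn_grid(600, 1700, 2)
  bl <- fit_baseline(spectrum_tbl(wn, rep(0, length(wn))))
  expect_equal(bl$baseline$intensity, rep(0, length(wn)))
  expect_equal(bl$c, 0)
  expect_error(fit_baseline(spectrum_tbl(wn_grid(600, 610, 2), rep(1, 6))),
               "channels")
})

test_that("fit_libraries solves exact and noisy mixtures", {
  libs <- dplyr::filter(default_libraries(), wavenumber >= 600, wavenumber <= 1700)
  M <- rrsburn:::library_matrix(libs)
  wn <- attr(M, "wavenumber")

  exact <- fit_libraries(spectrum_tbl(wn, 2 * M[, "HbO"]), libs)
  expect_equal(exact$b, 2, tolerance = 1e-8)
  expect_equal(exact$a + exact$m_r + exact$m_o, 0, tolerance = 1e-8)

  set.seed(0)
  truth <- 1.5 * M[, "HbR"] + 0.5 * M[, "MitoOx"]
  noisy <- truth + rnorm(length(wn), sd = 0.01 * max(truth))
  fit <- fit_libraries(spectrum_tbl(wn, noisy), libs)
  expect_equal(fit$a, 1.5, tolerance = 0.05 * 1.5)
  expect_equal(fit$m_o, 0.5, tolerance = 0.05 * 0.5)

  neg <- fit_libraries(spectrum_tbl(wn, -M[, "HbO"]), libs)
  expect_equal(neg$a + neg$b + neg$m_r + neg$m_o, 0)
  expect_equal(neg$residual_rms, sqrt(mean(M[, "HbO"]^2)), tolerance = 1e-10)
})

test_that("fit_libraries rejects grid mismatch and collinear designs", {
  libs <- dplyr::filter(default_libraries(), wavenumber >= 600, wavenumber <= 1700)
  wn <- sort(unique(libs$wavenumber))
  expect_error(fit_libraries(spectrum_tbl(wn[-1], rep(1, length(wn) - 1)), libs),
               "grid")
  dup <- dplyr::bind_rows(
    dplyr::filter(libs, library %in% c("HbO", "MitoOx", "MitoRed")),
    dplyr::mutate(dplyr::filter(libs, library == "HbO"), library = "HbR"))
  expect_error(fit_libraries(spectrum_tbl(wn, rep(1, length(wn))), dup),
               "collinear|rank")
})

test_that("non-negative solver matches a grid-search oracle on a toy design", {
  libs <- toy_design()
  M <- rrsburn:::library_matrix(libs)
  wn <- attr(M, "wavenumber")
  set.seed(4)
  for (truth in list(c(0.7, 0.2), c(0, 1.3), c(2, 0))) {
    y <- drop(M %*% truth) + rnorm(length(wn), sd = 0.02)
    sol <- rrsburn:::nnls_exact(M, y)
    # exhaustive grid search over non-negative weight pairs
    grid <- seq(0, 3, by = 0.005)
    best <- c(0, 0); best_rss <- sum(y^2)
    for (w1 in grid) {
      r1 <- y - w1 * M[, 1]
      w2 <- pmax(grid, 0)
      rss <- colSums((outer(M[, 2], w2, `*`) - r1)^2)
      j <- which.min(rss)
      if (rss[j] < best_rss) { best_rss <- rss[j]; best <- c(w1, w2[j]) }
    }
    expect_equal(sol$coef, best, tolerance = 1e-2)
    expect_lte(sol$rss, best_rss + 1e-9)
  }
})

test_that("noiseless decomposition round-trips the generator coefficients", {
  libs <- default_libraries()
  for (truth in list(c(a = 1.2, b = 3.4, m_r = 0, m_o = 0, c = 10),
                     c(a = 0.3, b = 0.1, m_r = 0.5, m_o = 2, c = 50))) {
    fr <- simulate_frames(as.list(truth), libs, clean_config())
    dec <- decompose_frames(fr, libs, window = 5)
    got <- c(a = dec$a, b = dec$b, m_r = dec$m_r, m_o = dec$m_o, c = dec$c)
    expect_equal(got, truth, tolerance = 1e-3)
  }
})

test_that("decomposition is scale-equivariant", {
  libs <- default_libraries()
  fr <- simulate_frames(list(a = 1, b = 2, m_r = 0, m_o = 0, c = 20), libs,
                        sim_config(n_frames = 10, noise_sd = 0.005,
                                   spike_prob = 0, seed = 11))
  k <- 3.7
  fr_k <- dplyr::mutate(fr, intensity = intensity * k)
  d1 <- decompose_frames(fr, libs, window = 10)
  d2 <- decompose_frames(fr_k, libs, window = 10)
  expect_equal(d2$a, k * d1$a, tolerance = 1e-6)
  expect_equal(d2$b, k * d1$b, tolerance = 1e-6)
  expect_equal(d2$c, k * d1$c, tolerance = 1e-6)
})

test_that("a smooth additive offset moves c but not the hemoglobin weights", {
  libs <- default_libraries()
  cfg <- sim_config(n_frames = 10, noise_sd = 0.002, spike_prob = 0, seed = 12)
  fr <- simulate_frames(list(a = 1, b = 2, c = 20), libs, cfg)
  wn <- sort(unique(fr$wavenumber))
  offset <- 15 + 5 * ((wn - mean(wn)) / 650)^2
  fr_off <- dplyr::group_by(fr, frame)
  fr_off <- dplyr::ungroup(dplyr::mutate(fr_off, intensity = intensity + offset[match(wavenumber, wn)]))
  d1 <- decompose_frames(fr, libs, window = 10)
  d2 <- decompose_frames(fr_off, libs, window = 10)
  expect_gt(d2$c, d1$c + 10)
  expect_equal(d2$a + d2$b, d1$a + d1$b, tolerance = 0.02 * (d1$a + d1$b))
})

test_that("frames of zeros decompose to all-zero coefficients", {
  libs <- default_libraries()
  g <- wn_grid()
  fr <- tibble::tibble(frame = rep(1:3, each = length(g)),
                       wavenumber = rep(g, 3), intensity = 0)
  dec <- decompose_frames(fr, libs, window = 3)
  expect_equal(dec$a + dec$b + dec$m_r + dec$m_o + dec$c, 0, tolerance = 1e-10)
})
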