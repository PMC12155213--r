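# Library construction, frame simulation and the deterministic study fixtures.

test_that("make_library builds normalized pseudo-Voigt sums", {
  g <- wn_grid(500, 1800, 1)  # 1 cm^-1 grid so the peak center is a channel
  one <- make_library("x", data.frame(center = 1375, fwhm = 12, height = 1), g)
  expect_equal(one$wavenumber[which.max(one$intensity)], 1375)
  expect_equal(max(one$intensity), 1)
  expect_true(all(one$intensity >= 0))

  two <- make_library("x", data.frame(center = c(800, 1400), fwhm = c(12, 12),
                                      height = c(1, 0.5)), g)
  expect_equal(two$wavenumber[which.max(two$intensity)], 800)
  # tiny Lorentzian wing of the 800 cm^-1 peak rides on top of the second one
  expect_equal(two$intensity[two$wavenumber == 1400], 0.5, tolerance = 1e-3)

  expect_error(make_library("x", data.frame()[0, ], g), "at least one peak")
  expect_error(
    make_library("x", data.frame(center = 300, fwhm = 10, height = 1), g),
    "300")
})

test_that("default libraries are mutually distinguishable", {
  M <- rrsburn:::library_matrix(default_libraries())
  nm <- colnames(M)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) {
      expect_lt(rrsburn:::cosine_sim(M[, i], M[, j]), 0.99)
    }
  }
  expect_true(all(M >= 0))
  expect_equal(unname(apply(M, 2, max)), rep(1, 4))
})

test_that("simulate_frames honors noiseless identities and the seed contract", {
  libs <- default_libraries()
  cfg <- clean_config(n_frames = 3)

  # pure HbO signal, nothing else
  fr <- simulate_frames(list(a = 0, b = 1, m_r = 0, m_o = 0, c = 0), libs, cfg)
  hbo <- dplyr::filter(libs, library == "HbO")
  for (i in 1:3) {
    f <- dplyr::filter(fr, frame == i)
    expect_equal(f$intensity, hbo$intensity, tolerance = 1e-12)
  }

  # baseline only: mean over the analysis window equals c
  fr_bl <- simulate_frames(list(a = 0, b = 0, m_r = 0, m_o = 0, c = 7.5), libs, cfg)
  f1 <- dplyr::filter(fr_bl, frame == 1, wavenumber >= 600, wavenumber <= 1700)
  expect_equal(mean(f1$intensity), 7.5, tolerance = 1e-10)

  # seeding: identical seeds identical frames, different seeds differ
  noisy <- function(seed) simulate_frames(
    list(a = 1, b = 1, c = 5), libs,
    sim_config(n_frames = 3, noise_sd = 0.05, spike_prob = 0.1, seed = seed))
  expect_identical(noisy(42), noisy(42))
  expect_false(isTRUE(all.equal(noisy(42)$intensity, noisy(43)$intensity)))

  expect_error(simulate_frames(list(a = -1, b = 0, c = 0), libs, cfg), "a")
})

test_that("study simulation records ground-truth multipliers and rejects bad designs", {
  design <- study_design()
  study <- simulate_study(design, sim_config(seed = 7), days = 3)
  pts <- dplyr::filter(study$truth, category == "PT-Superficial", pod == 3)
  expect_true(all(pts$hi_multiplier == 9.19))
  expect_equal(
    unique(dplyr::filter(study$truth, category == "Full-thickness", pod == 3)$hi_multiplier),
    0.18)
  healthy <- dplyr::filter(study$truth, category == "healthy")
  expect_equal(nrow(healthy), 3 * 4)  # 3 pigs x 4 sites on one day
  expect_true(all(healthy$hi_multiplier == 1))
  # category assignment is seed-reproducible
  study2 <- simulate_study(design, sim_config(seed = 7), days = 3)
  expect_identical(study$wounds, study2$wounds)

  expect_error(study_design(healthy_sites = 0), "normalization")
  expect_error(study_design(baseline_amplitude = 0), "baseline_amplitude")
  bad_traj <- dplyr::filter(default_trajectories(), pod != 3)
  expect_error(
    simulate_study(study_design(trajectories = bad_traj), sim_config(), days = 3),
    "POD 3")
})

test_that("pod3_fixture reproduces printed means and SEMs exactly", {
  fx <- suppressMessages(pod3_fixture())
  stats <- dplyr::summarise(
    dplyr::group_by(fx, category),
    n = dplyr::n(), m = mean(hi), sem = sd(hi) / sqrt(dplyr::n()), .groups = "drop")
  expected <- tibble::tibble(
    category = c("Full-thickness", "PT-Deep", "PT-Superficial", "Superficial"),
    n = c(6L, 4L, 5L, 4L), m = c(0.18, 6.54, 9.19, 1.67),
    sem = c(0.09, 0.79, 1.38, 0.45))
  expect_equal(dplyr::arrange(stats, category), expected, tolerance = 1e-10)

  # the unique symmetric equally spaced 5-point set for PT-Superficial
  pts <- sort(fx$hi[fx$category == "PT-Superficial"])
  d <- 1.38 * sqrt(5) / sqrt(2.5)
  expect_equal(pts, 9.19 + (-2:2) * d, tolerance = 1e-10)
  expect_equal(round(pts, 4), c(5.2868, 7.2384, 9.1900, 11.1416, 13.0932))
  # exactly one PT-Superficial wound falls below the PT-Deep cutoff
  expect_equal(sum(pts < 6.58), 1L)

  # PT-Deep SD rebuilt from the returned values
  ptd <- fx$hi[fx$category == "PT-Deep"]
  expect_equal(sd(ptd), 0.79 * sqrt(4), tolerance = 1e-10)

  # negative full-thickness values flagged, clamped variant available
  expect_true("Full-thickness" %in% attr(fx, "negative_values"))
  expect_true(all(pod3_fixture(clamp = TRUE)$hi >= 0))
})

test_that("wound_table_fixture mirrors the study's attrition structure", {
  wt <- wound_table_fixture()
  expect_equal(nrow(wt), 24)
  expect_equal(sum(wt$block_temp_c == 45), 4)
  expect_equal(sum(wt$block_temp_c == 63), 14)  # all partial-thickness attempts
  heal_pts <- wt$heal_pod[wt$block_temp_c == 63 & wt$contact_s <= 20 & !is.na(wt$heal_pod)]
  expect_equal(round(mean(heal_pts), 2), 43.17)
  expect_equal(range(heal_pts), c(35, 56))
})
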