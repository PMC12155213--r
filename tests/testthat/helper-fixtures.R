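# Shared in-code fixtures: tiny grids and library sets used across tests.

tiny_grid <- function() wn_grid(600, 1700, 2)

tiny_libs <- function(grid = tiny_grid()) default_libraries(grid = wn_grid())

# A minimal two-library set on an 8-channel grid for brute-force NNLS checks.
toy_design <- function() {
  g <- seq(1000, 1014, by = 2)
  l1 <- make_library("HbO", data.frame(center = 1004, fwhm = 6, height = 1), g)
  l2 <- make_library("HbR", data.frame(center = 1010, fwhm = 6, height = 1), g)
  dplyr::bind_rows(l1, l2)
}

# Quiet noiseless configuration for round-trip tests.
clean_config <- function(n_frames = 5, seed = 1) {
  sim_config(n_frames = n_frames, noise_sd = 0, spike_prob = 0, seed = seed)
}

# Brute-force AUC by pair counting (independent of the rank-based route).
auc_pairs <- function(pos, neg, direction = "greater") {
  s <- 0
  for (p in pos) for (q in neg) {
    cmp <- if (direction == "greater") sign(p - q) else sign(q - p)
    s <- s + if (cmp > 0) 1 else if (cmp == 0) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}
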