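# Shared fixtures: cheap acquisition grids and fixed-truth cohorts so tests
# stay fast without touching the default protocol.

quick_acq <- function(n_pre = 5, post_duration = 15) {
  frap_acquisition(n_pre = n_pre, post_duration = post_duration,
                   n_pre_norm = min(n_pre, 3))
}

# A one-cluster preset with zero spread: every cell's truth equals `truth`.
fixed_preset <- function(truth, name = "custom") {
  frap_preset_custom(
    tibble::tibble(
      cluster = 1L,
      if_frac_mean = truth$if_frac, if_frac_sd = 0,
      ratio_mean = truth$ratio, ratio_sd = 0,
      t_half_fast_mean = truth$t_half_fast, t_half_fast_sd = 0,
      t_half_slow_mean = truth$t_half_slow, t_half_slow_sd = 0,
      f0_mean = truth$f0, f0_sd = 0),
    weights = 1, name = name)
}

healthy_truth <- function() kinetic_truth(0.6082, 0.85, 1.85, 15.04, f0 = 0.3)

# Noiseless single-cell trace for a truth on the full acquisition grid.
noiseless_trace <- function(truth, acq = frap_acquisition(), seed = 1,
                            cell_id = "cell_001") {
  simulate_frap_trace(truth, acq = acq, noise = frap_noise(sigma_add = 0),
                      seed = seed, cell_id = cell_id)
}

# O(n^3) average-linkage oracle: merge heights by brute-force averaging of
# raw pairwise distances between clusters.
naive_average_linkage_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    i <- best[2]; j <- best[3]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
  }
  sort(heights)
}
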