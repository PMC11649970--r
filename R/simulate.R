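#' Simulate one single-cell FRAP trace
#'
#' Produces the raw-intensity table for one cell on the acquisition grid:
#' `n_pre` pre-bleach frames with expected value 1, then post-bleach frames
#' following the two-component recovery model, with additive Gaussian noise
#' and an optional per-frame acquisition-bleaching drift. Intensities are on
#' the normalized scale (pre-bleach plateau 1), which loses no generality
#' because downstream normalization is scale-invariant.
#'
#' @param truth One-row tibble from [kinetic_truth()].
#' @param acq [frap_acquisition()] settings.
#' @param noise [frap_noise()] settings.
#' @param seed Integer seed; required, so traces are reproducible.
#' @param cell_id,donor_id,health_state,condition Metadata carried on every
#'   frame row.
#'
#' @return Trace tibble with columns `cell_id`, `donor_id`, `health_state`,
#'   `condition`, `frame_index`, `time_s`, `phase`, `intensity`.
#' @export
#' @examples
#' tr <- simulate_frap_trace(kinetic_truth(0.5, 1, 1.5, 15), seed = 1)
#' dplyr::count(tr, phase)
simulate_frap_trace <- function(truth, acq = frap_acquisition(),
                                noise = frap_noise(), seed,
                                cell_id = "cell_001", donor_id = "donor_1",
                                health_state = "unknown",
                                condition = "control") {
  if (missing(seed) || !is.finite(seed)) {
    abort("`seed` is required (no implicit global randomness)")
  }
  stopifnot(inherits(acq, "frap_acquisition"), inherits(noise, "frap_noise"))
  grid <- acquisition_times(acq)
  expected <- c(rep(1, acq$n_pre), recovery_curve(truth, grid$model))
  n <- length(expected)
  if (noise$drift_rate > 0) {
    expected <- expected * (1 - noise$drift_rate)^(seq_len(n) - 1)
  }
  intensity <- withr::with_seed(as.integer(seed), {
    expected + rnorm(n, 0, noise$sigma_add)
  })
  tibble(
    cell_id = cell_id, donor_id = donor_id, health_state = health_state,
    condition = condition,
    frame_index = seq_len(n) - 1L,
    time_s = c(grid$pre, grid$post),
    phase = rep(c("pre", "post"), c(acq$n_pre, grid$n_post)),
    intensity = intensity
  )
}

#' Population presets for synthetic FRAP cohorts
#'
#' A preset describes a donor/health-state cell population as a two-cluster
#' mixture: cluster weights plus truncated-normal mean/SD for every kinetic
#' parameter in each cluster. Built-in presets encode the state-level
#' averages reported for SOX9-mGFP in human primary chondrocytes (immobile
#' fraction, a1/a2 ratio and both half-times, mean +/- SD across cells), with
#' the two clusters separated in immobile fraction by +/- 1 state SD around
#' the state mean (cluster 1 higher) and within-cluster IF SD of half the
#' state SD, so the state-level marginal spread stays close to the reported
#' SD. Healthy cohorts weight cluster 1 at 0.6; preserved and OA cohorts at
#' 0.4, reflecting the lower share of high-binding cells in diseased joints.
#' The bleach floor is not part of the reported table; presets use mean 0.3,
#' SD 0.05, a typical confocal spot-bleach depth.
#'
#' @param name One of `"healthy"`, `"preserved"`, `"oa"`.
#' @param cluster_weights Length-2 nonnegative weights summing to 1
#'   (cluster 1, cluster 2).
#' @param f0_mean,f0_sd Bleach-floor distribution.
#'
#' @return A list of class `frap_preset` with elements `name`, `weights`, and
#'   `clusters` (tibble: one row per cluster with `*_mean` / `*_sd` columns).
#' @export
#' @examples
#' frap_preset("healthy")
frap_preset <- function(name = c("healthy", "preserved", "oa"),
                        cluster_weights = NULL, f0_mean = 0.3, f0_sd = 0.05) {
  name <- match.arg(name)
  state <- switch(name,
    healthy   = list(if_ = c(0.6082, 0.0553), ratio = c(0.85, 0.29),
                     thf = c(1.85, 0.44), ths = c(15.04, 3.92), w = c(0.6, 0.4)),
    preserved = list(if_ = c(0.4914, 0.0802), ratio = c(1.31, 0.38),
                     thf = c(1.48, 0.38), ths = c(13.34, 3.56), w = c(0.4, 0.6)),
    oa        = list(if_ = c(0.4629, 0.0855), ratio = c(1.17, 0.36),
                     thf = c(1.65, 0.47), ths = c(14.24, 4.1), w = c(0.4, 0.6))
  )
  w <- cluster_weights %||% state$w
  if (length(w) != 2 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort("`cluster_weights` must be two nonnegative values summing to 1")
  }
  clusters <- tibble(
    cluster = 1:2,
    if_frac_mean = state$if_[1] + c(1, -1) * state$if_[2],
    if_frac_sd = state$if_[2] / 2,
    ratio_mean = state$ratio[1], ratio_sd = state$ratio[2],
    t_half_fast_mean = state$thf[1], t_half_fast_sd = state$thf[2],
    t_half_slow_mean = state$ths[1], t_half_slow_sd = state$ths[2],
    f0_mean = f0_mean, f0_sd = f0_sd
  )
  structure(list(name = name, weights = w, clusters = clusters),
            class = "frap_preset")
}

#' Fully specified custom preset
#'
#' @param clusters Tibble with one row per cluster and columns `cluster`,
#'   `if_frac_mean`, `if_frac_sd`, `ratio_mean`, `ratio_sd`,
#'   `t_half_fast_mean`, `t_half_fast_sd`, `t_half_slow_mean`,
#'   `t_half_slow_sd`, `f0_mean`, `f0_sd`.
#' @param weights Cluster weights (same length as `nrow(clusters)`, sum 1).
#' @param name Label stored with the preset.
#' @return A `frap_preset` object.
#' @export
frap_preset_custom <- function(clusters, weights, name = "custom") {
  clusters <- as_tibble(clusters)
  need <- c("cluster", "if_frac_mean", "if_frac_sd", "ratio_mean", "ratio_sd",
            "t_half_fast_mean", "t_half_fast_sd", "t_half_slow_mean",
            "t_half_slow_sd", "f0_mean", "f0_sd")
  missing_cols <- setdiff(need, names(clusters))
  if (length(missing_cols)) {
    abort(paste("preset clusters lack columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if (length(weights) != nrow(clusters) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be nonnegative, one per cluster, summing to 1")
  }
  sds <- unlist(clusters[grep("_sd$", names(clusters))])
  if (any(sds < 0)) abort("preset SDs must be >= 0")
  structure(list(name = name, weights = weights, clusters = clusters),
            class = "frap_preset")
}

#' @export
print.frap_preset <- function(x, ...) {
  cat(sprintf("<frap_preset> '%s', %d clusters, weights (%s)\n", x$name,
              nrow(x$clusters), paste(signif(x$weights, 3), collapse = ", ")))
  print(x$clusters)
  invisible(x)
}

# Truncated-normal draw of one valid truth record; resamples until the
# kinetic invariants hold, erroring after `max_tries`.
sample_truth <- function(row, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    if_frac <- rnorm(1, row$if_frac_mean, row$if_frac_sd)
    ratio <- rnorm(1, row$ratio_mean, row$ratio_sd)
    thf <- rnorm(1, row$t_half_fast_mean, row$t_half_fast_sd)
    ths <- rnorm(1, row$t_half_slow_mean, row$t_half_slow_sd)
    f0 <- rnorm(1, row$f0_mean, row$f0_sd)
    ok <- is.finite(if_frac) && if_frac >= 0 && if_frac <= 1 &&
      is.finite(ratio) && ratio > 0 &&
      is.finite(thf) && is.finite(ths) && thf > 0 && ths > thf &&
      is.finite(f0) && f0 >= 0 && f0 < 1
    if (ok) {
      return(tibble(if_frac = if_frac, ratio = ratio, t_half_fast = thf,
                    t_half_slow = ths, f0 = f0))
    }
  }
  abort(sprintf(
    "could not draw valid kinetic parameters after %d tries (cluster %s); check preset means/SDs against the parameter bounds",
    max_tries, row$cluster))
}

#' Simulate a synthetic FRAP cohort
#'
#' Draws `n_cells` cells from a population preset: each cell is assigned a
#' cluster according to the preset weights, its kinetic truth is sampled from
#' that cluster's truncated-normal distributions, and its trace is simulated
#' on the acquisition grid. All randomness derives from `seed`: the master
#' seed drives cluster assignment, truth sampling, and a per-cell trace seed
#' drawn once per cell (documented splitting rule), so the same call is
#' bit-identical on rerun.
#'
#' @param preset A [frap_preset()] object.
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer master seed.
#' @param acq,noise Acquisition and noise settings shared by all cells.
#' @param donor_id,condition Metadata for the cohort.
#'
#' @return List with `traces` (stacked trace tibble) and `truth` (one row per
#'   cell: metadata, true cluster, kinetic parameters, per-cell seed).
#' @export
#' @examples
#' sim <- simulate_frap_cells(frap_preset("healthy"), n_cells = 3, seed = 7)
#' sim$truth
simulate_frap_cells <- function(preset, n_cells, seed,
                                acq = frap_acquisition(),
                                noise = frap_noise(),
                                donor_id = "donor_1", condition = "control") {
  stopifnot(inherits(preset, "frap_preset"))
  if (!is.finite(n_cells) || n_cells < 1) abort("`n_cells` must be >= 1")
  if (missing(seed) || !is.finite(seed)) abort("`seed` is required")
  n_cells <- as.integer(n_cells)

  truth <- withr::with_seed(as.integer(seed), {
    cl <- sample.int(nrow(preset$clusters), n_cells, replace = TRUE,
                     prob = preset$weights)
    rows <- purrr::map(cl, function(k) sample_truth(preset$clusters[k, ]))
    cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
    dplyr::bind_cols(
      tibble(cell_id = sprintf("cell_%04d", seq_len(n_cells)),
             donor_id = donor_id, health_state = preset$name,
             condition = condition, true_cluster = cl),
      dplyr::bind_rows(rows),
      tibble(trace_seed = cell_seeds)
    )
  })

  traces <- purrr::pmap(
    list(seq_len(n_cells), truth$trace_seed, truth$cell_id),
    function(i, s, id) {
      simulate_frap_trace(truth[i, c("if_frac", "ratio", "t_half_fast",
                                     "t_half_slow", "f0")],
                          acq = acq, noise = noise, seed = s, cell_id = id,
                          donor_id = donor_id, health_state = preset$name,
                          condition = condition)
    })
  list(traces = dplyr::bind_rows(traces), truth = truth)
}
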