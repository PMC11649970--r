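# frapdyn

Single-cell FRAP analysis of transcription-factor binding dynamics.

In a fluorescence recovery after photobleaching (FRAP) experiment, a
fluorescently tagged protein pool inside the nucleus is bleached in a small
circular region and the return of fluorescence is recorded. For a
DNA-binding transcription factor (the motivating case is SOX9-mGFP in human
primary articular chondrocytes), the shape of the recovery curve separates
three pools: freely diffusing protein, protein transiently bound to DNA,
and protein stably bound on the time scale of the experiment. `frapdyn`
implements the full analysis path from raw per-cell intensity traces to
population statistics:

- **Normalization** of each trace against the mean of its last 10
  pre-bleach frames, with time rebased to the first post-bleach frame.
- **Kinetic model fitting.** Each cell's post-bleach curve is fitted with a
  diffusion-uncoupled two-component model,

  F(t) = f₀ + A₁(1 − 2^(−t/t½,₁)) + A₂(1 − 2^(−t/t½,₂)),

  where f₀ is the bleach floor, A₁/t½,₁ describe the fast (unbound)
  component, A₂/t½,₂ the slow (DNA-bound) component. The immobile fraction
  IF = 1 − (A₁+A₂)/(1−f₀) is the bleach-depth-corrected share of protein
  that never exchanges — the proxy for stable DNA binding. A nested
  one-component model handles free-fluorophore controls.
- **Subpopulation discovery** by Euclidean hierarchical clustering of the
  per-cell parameters with an adaptive (dynamic) tree cut; the cluster with
  the higher mean immobile fraction is always labeled cluster 1, and the
  cluster-1:cluster-2 cell-count ratio summarizes population composition.
- **Nonparametric statistics**: Mann-Whitney U tests (exact by enumeration
  for small samples, tie- and continuity-corrected normal approximation
  otherwise), mean ± SD summary tables, and treatment-versus-control effect
  matrices with conventional star annotations.
- **Relative gene expression** by the comparative Ct method
  (2^−ΔΔCt, Livak), the usual companion readout for target-gene activity.
- **A synthetic-data generator** that emulates the acquisition protocol
  (25 pre-bleach frames, 4 frames/s, 60 s post-bleach, 60 ms bleach gap)
  and two-cluster population structure, so every stage is testable against
  known ground truth.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe.

## Worked example

Simulate a healthy-state cohort, fit every cell, and look for
subpopulations:

```r
library(frapdyn)

sim <- simulate_frap_cells(frap_preset("healthy"), n_cells = 150, seed = 42)
params <- sim$traces |> normalize_frap() |> fit_frap()
#> 40 of 150 cells flagged non-converged and excluded from downstream statistics

summarize_frap(params, health_state)
#> # A tibble: 4 × 5
#>   health_state parameter               mean    sd     n
#>   <chr>        <chr>                  <dbl> <dbl> <int>
#> 1 healthy      immobile_fraction_pct 59.7   6.28    110
#> 2 healthy      ratio_a1_a2            0.855 0.281   110
#> 3 healthy      t_half_fast_s          1.64  0.554   110
#> 4 healthy      t_half_slow_s         15.4   4.92    110

assignments <- cluster_frap(params, vars = "if-only")
cluster_ratio(assignments, health_state)
#> # A tibble: 1 × 4
#>   health_state n_cluster1 n_cluster2 ratio_1_to_2
#>   <chr>             <int>      <int>        <dbl>
#> 1 healthy              52         58        0.897
```

The summary means sit close to the generating preset (immobile fraction
60.8%, ratio 0.85, half-times 1.85 s and 15.04 s): per-cell fits are noisy,
population averages are not. The adaptive cut finds the two simulated
subpopulations; because their immobile-fraction distributions overlap, the
recovered 52:58 split blurs the generating 60:40 weights — boundary cells
are genuinely ambiguous. Cells whose slow half-time cannot be pinned down
at this noise level (here 40 of 150) are flagged rather than silently kept.

A single cell:

```r
fit <- sim$traces |>
  dplyr::filter(cell_id == "cell_0001") |>
  normalize_frap() |>
  fit_frap_trace()
fit
#> <frap_fit> 2-component, converged (rss 0.0943, 241 points)
#>          f0          a1          a2 t_half_fast t_half_slow
#>      0.3384      0.1148      0.1619      1.8659     11.9950
#> immobile fraction 58.2%, a1/a2 0.709, recovery 41.8%
autoplot(fit)       # data + fitted curve; tidy(fit), glance(fit) also work
```

Whole runs (simulate or ingest → normalize → fit → cluster → stats, with
logs and a config echo) go through `run_frap_pipeline()`, or from a shell
via `inst/scripts/frap-pipeline.R`.

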