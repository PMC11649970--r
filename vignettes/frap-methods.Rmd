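---
title: "Models and methods behind frapdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind frapdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frapdyn)
```

This vignette explains the models, parameters and numerical choices in
`frapdyn`, and what the synthetic-data tests do and do not establish about
real data.

## The recovery model

FRAP of a nuclear transcription factor is interpreted here with a
diffusion-uncoupled two-component model: diffusion of the unbound pool is
fast relative to the acquisition frame interval, so the spatial problem
collapses and recovery is a sum of exponential exchange terms. On the
normalized intensity scale (pre-bleach plateau = 1), with `t = 0` at the
first post-bleach frame,

$$F(t) = f_0 + A_1\left(1 - 2^{-t/t_{1/2,1}}\right)
             + A_2\left(1 - 2^{-t/t_{1/2,2}}\right).$$

* `f0` — bleach floor, the normalized intensity right after the bleach
  pulse; dimensionless, in [0, 1). It measures bleach depth, not biology.
* `A1`, `t_half_fast` — amplitude and half-time of the fast component, the
  freely diffusing (unbound) pool. Seconds for half-times.
* `A2`, `t_half_slow` — the slow component, protein transiently bound to
  DNA; its half-time tracks residence time on chromatin.
* Immobile fraction `IF = 1 - (A1 + A2)/(1 - f0)` — the share of the
  *bleach-affected* pool that never exchanges during the window; the proxy
  for stable DNA binding. The uncorrected alternative
  `1 - (f0 + A1 + A2)` is available via
  `frap_fit_options(if_definition = "uncorrected")`; the corrected form is
  the default because it is invariant to bleach depth, so cells with
  different bleach efficiencies remain comparable. All synthetic-data
  results in this package are generated and fitted under the same
  convention, so the choice never silently mixes scales.

Half-times parameterize the exponentials in base 2 because that is the
quantity reported and compared across conditions; the equivalent
exponential time constant is $\tau = t_{1/2}/\ln 2$.

The nested one-component model (`a2 = 0`) describes free-fluorophore
controls, which recover fully and fast; fitting it to a control should give
recovery near 100% and immobile fraction near zero, and this is one of the
package's acceptance checks.

## Normalization

Each cell is normalized by the mean of its **last 10** pre-bleach
intensities (frames closest to the bleach), so slow drift early in the
pre-bleach block does not contaminate the denominator. Times are rebased so
the first post-bleach frame is `t = 0`; the 60 ms bleach pulse is treated
as an unobserved gap, excluded from the fit domain. No background
subtraction is applied by default (none is part of the protocol this
package models); a constant-offset option exists and announces itself when
nonzero. Whether the original time origin was the bleach midpoint or the
first post frame is not knowable from the protocol description; the first
post frame is used consistently here, which shifts all half-times by at
most one frame interval.

## Fitting

Unweighted least squares by bounded Levenberg-Marquardt (`minpack.lm`),
with three deterministic starts bracketing the plausible time scales
(fast/slow half-time pairs 1/15 s, 0.5/5 s, 3/40 s); the lowest-RSS start
wins and components are reordered so `t_half_fast < t_half_slow`. Bounds
are physical-plausibility limits on a 60 s window — amplitudes in [0, 1.5],
`f0` in [0, 0.95], fast half-time in [0.05, 30] s, slow in [0.5, 300] s —
loose enough not to bind at realistic values. Convergence tolerance is
1e-8 on parameters and cost, at most 2000 evaluations per start.

**Identifiability flagging.** With additive noise of SD 0.02 on the
normalized scale, a small fraction of cells produce fits whose slow
component is not resolved on a 60 s window: the half-time runs to a box
bound or carries an enormous standard error, while the immobile fraction
compensates. Such estimates are meaningless individually and, being
heavy-right-tailed, bias cohort means. A fit is therefore flagged
`converged = FALSE` when a half-time with non-negligible amplitude
(> 0.01) sits at a bound or has a relative standard error above 50% — the
standard %RSE cutoff used in kinetic modeling for "parameter not
determined". Flagged cells stay in the parameter table with a reason and
are excluded from downstream statistics; exclusion counts are reported. At
the reference noise level this typically removes 0–20% of cells depending
on where the truth sits (high immobile fractions leave small amplitudes
and are harder), which mirrors practice: FRAP studies report the cells
that yielded usable fits.

A flat post-bleach curve fits with both amplitudes near zero and immobile
fraction near 1, and is handled without error.

## The synthetic-data generator

The generator emulates the acquisition protocol: 25 pre-bleach frames at
expected value 1, a 60 ms timestamp gap, then 60 s at 4 frames/s following
the model curve, with additive Gaussian noise (default SD 0.02) and an
optional per-frame multiplicative acquisition-bleaching drift (off by
default). Populations are two-cluster mixtures: each cell draws a cluster
by the preset weights, then its parameters from per-cluster truncated
normals (resampled until the kinetic invariants hold, erroring after 1000
tries so impossible presets fail loudly). Built-in presets encode the
state-level mean ± SD kinetics for healthy, preserved and osteoarthritic
chondrocyte cohorts. Because only state-level moments are published, the
cluster structure is a modeling choice, fixed once:

* cluster immobile-fraction means at the state mean ± 1 state SD
  (cluster 1 higher), within-cluster SD half the state SD — this keeps the
  state-level marginal SD near the reported value while giving the two
  clusters a 2-SD separation;
* other kinetic parameters share the state mean across clusters with the
  reported SDs (the immobile fraction is the variable that defines the
  subpopulations);
* weights 0.6/0.4 for healthy, 0.4/0.6 for preserved and OA, reflecting
  the consistently lower share of high-binding cells in diseased joints
  (exact published ratios are figure-level, so weights are configurable
  rather than asserted);
* bleach floor `f0 ~ N(0.3, 0.05)` truncated to [0, 1), a typical confocal
  spot-bleach depth — `f0` is not a reported quantity, so it is a free,
  documented preset field.

Seeds are explicit everywhere. A cohort call consumes one master seed that
drives cluster assignment and truth sampling and then draws one trace seed
per cell; the same master seed is bit-identical on rerun.

**What the generator does not emulate:** spatial structure (no bleach-spot
geometry, no diffusion PDE — consistent with the diffusion-uncoupled
interpretation), photophysics (blinking, reversible photobleaching),
acquisition bleaching by default, correlated noise, and any within-donor
versus between-donor variance decomposition (published SDs are treated as
pure between-cell variability). Passing parameter-recovery tests therefore
shows the estimator is unbiased and well-calibrated *under the stated noise
model*, not that real traces meet that model.

## Clustering and the adaptive tree cut

Cells are clustered on their fitted parameters under Euclidean distance
with average linkage (complete and Ward available); variables are z-scored
in the default multivariate mode (immobile fraction, ratio, both
half-times). A single-variable mode (`vars = "if-only"`) clusters on the
immobile fraction alone, the variable that defines the subpopulations;
because the two modes agree only when separation lives in the immobile
fraction, the if-only mode is what the package's two-cluster benchmarks
use, and the multivariate default is best when treatments may move other
parameters too.

Choosing the number of clusters from the dendrogram needs care: merge-height
gaps alone cannot distinguish one diffuse group from two separated ones —
for average linkage on a single 1-D Gaussian blob, the top merge-height gap
is routinely 20–45% of total tree height, overlapping what genuinely
separated groups produce, so no fixed height-gap fraction works. The
package instead selects K by the **gap statistic** (uniform reference
distribution, 50 seeded reference draws, `firstSEmax` rule), which
explicitly supports K = 1 and is deterministic given its seed. Candidate
partitions come from `cutree` on the single prebuilt tree; reference
datasets are re-clustered from scratch. Clusters below the minimum size
(default 5) are merged into the nearest centroid; with fewer than twice the
minimum size, one cluster is returned with a warning. This is an
approximation to published dynamic tree cutting, not a reimplementation of
the full hybrid algorithm.

Clustering runs per donor per condition; same-numbered clusters are then
comparable across donors within a health state because labels follow a
fixed convention: clusters are renumbered by decreasing mean immobile
fraction, so cluster 1 is always the high-binding subpopulation. Ties are
broken by cluster size, then input order, with a message. The
cluster-1:cluster-2 count ratio summarizes composition; it is flagged
undefined when cluster 2 is absent.

Because the built-in presets separate clusters by only 2 state SD, cluster
*membership* near the boundary is genuinely ambiguous even when K = 2 is
correctly detected; recovered weights on fitted (noisy) parameters blur
toward 50:50. The package's weight-recovery checks therefore run on
generator truth values, which isolates the clustering question from fit
noise.

## Statistics

Group comparisons use the Mann-Whitney U test, the appropriate choice for
the skewed, non-Gaussian per-cell parameter distributions. U counts
x-beats-y pairs (ties half). With both samples of size ≤ 8 the p-value is
exact, by enumeration of all C(n+m, n) equally likely assignments of the
pooled values, which handles ties without approximation; larger samples use
the normal approximation with tie correction and a 0.5 continuity
correction. Star annotations follow the conventional strict thresholds
(p < 0.05/0.01/0.001). No multiple-testing correction is applied by default
— effects are reported per comparison — but Benjamini-Hochberg is available
and recorded in the output when used. Summary tables report mean, sample SD
(n − 1) and n per group over converged cells only.

## Relative expression

The comparative Ct module implements the Livak 2^−ΔΔCt method: target Ct
normalized to a reference gene within each group, then to the untreated
control. Replicates are aggregated by mean Ct before differencing. Perfect
doubling per cycle is assumed (no efficiency correction — that would be the
Pfaffl method, out of scope); mean Ct above 35 is flagged as near the
detection limit. Two identities pin the arithmetic down and are tested:
fold(A→B)·fold(B→A) = 1, and invariance to adding any constant to every Ct.

## Problem sizes and reproducibility

The test suite and acceptance script run cohorts of 200 cells per health
state at the reference noise level, the scale at which cohort means
stabilize well inside the tolerances of interest, plus large generator-only
draws (5000–10000 cells on a shortened grid) for law-of-large-numbers
checks. The pipeline stamps every run with its seed, a config echo and its
MD5 hash, and the package version; stage outputs are pure functions of
(inputs, config, master seed).

## Known limitations

* The two-component model cannot distinguish many short binding events
  from slowed diffusion; that ambiguity is intrinsic to the
  diffusion-uncoupled interpretation.
* Slow half-times approaching the 60 s window are structurally hard to
  estimate; the identifiability filter removes them rather than pretending
  otherwise, which slightly censors the high-immobile tail of a cohort.
* The adaptive cut assumes roughly convex, comparably sized clusters (it
  inherits this from the gap statistic with a uniform reference).
* Preset cluster weights and separations are modeling choices anchored to
  state-level summaries, not fitted to any single-cell dataset.
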