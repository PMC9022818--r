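---
title: "Methods: sliding-window network dynamics in block-design task fMRI"
author: "dynfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

# The model

`dynfc` treats a task fMRI run as a multivariate time series
$x_{t r}$ ($t = 1 \dots T$ volumes, $r = 1 \dots R$ regions) and asks how
the topology of the inter-regional correlation network evolves over the
run, and in particular whether it is *more stable* during the
task-stimulation-related period than over the whole scan.

The analysis chain is:

1. **Band-limiting.** BOLD fluctuations informative about task-driven
   coupling live well below the sampling rate; windowed correlations over
   short windows are noisy, so the series is band-limited first. Two
   mechanisms are offered. *Frequency-domain masking* zeroes discrete
   Fourier coefficients outside the passband and inverts the transform —
   zero-phase by construction and free of filter-order or ripple
   parameters, at the cost of a hard spectral edge. Cutoffs are specified
   as **periods in seconds** (the inverse of the cutoff frequency), e.g. a
   high-pass at 75 s passes fluctuations faster than 1/75 Hz. *MODWT
   level selection* decomposes each series with the maximal overlap
   discrete wavelet transform and reconstructs it from chosen detail
   levels; level $j$ occupies the nominal band
   $[f_s/2^{j+1},\, f_s/2^{j}]$, so at TR = 1 s keeping levels 3–5 retains
   roughly 1/64–1/8 Hz. The MODWT is shift-invariant, which matters here:
   a critically-sampled transform would make the windowed correlations
   depend on the alignment of the window grid with the decimation grid.

2. **Sliding-window correlation.** A window of $N$ TRs advanced by $s$
   TRs yields $W = \lfloor (T-N)/s \rfloor + 1$ positions; window $w$
   covers the volumes ending at TR $N + (w-1)s$ and produces the matrix
   of pairwise Pearson correlations, optionally under Gaussian weights
   centered at the window midpoint. Uniform weights reduce exactly to the
   ordinary Pearson estimate, which is the property the weighted
   implementation is tested against. Trailing volumes that do not fill a
   final window are dropped; no partial windows are formed.

3. **Temporal inclusive mask.** Windows are marked task-related by two
   per-time-point criteria combined with logical AND (either can be used
   alone): the *estimated activation* — the design boxcar convolved with
   the canonical double-gamma hemodynamic response, thresholded at 0.8 —
   and the *condition coverage* — at least 80% of the window-length
   neighborhood of the time point under the task condition.

4. **Binarization and graph metrics.** Each windowed matrix is binarized
   and summarized by the standard global and nodal binary-graph
   properties (efficiencies, clustering, path length, degree,
   transitivity, assortativity, modularity, betweenness), with clustering
   and path length optionally normalized by the means of 20 random
   graphs with the same node and edge counts; the small-world coefficient
   is the ratio of the two normalized quantities.

5. **Stability.** The dynamics of a property $A$ is its sample variance
   $V = \frac{1}{N-1}\sum_i (A_i - \mu)^2$ over selected windows.
   Task-masked and full-duration variances are compared per subject and
   tested with a paired two-sided t-test across subjects.

# The mask alignment convention

The two mask components are defined per *time point*; a window must read
them at one representative time point, and several conventions are
defensible (a window can be indexed by its first, central, or last
volume, and "the window associated with a time point" can equally be read
as the span centered on it). These choices move block-edge windows in and
out of the mask and therefore change the masked-window count. The package
fixes the convention **once, by calibration against the worked example it
ships with** (5 × 30 s task / 5 × 30 s rest at TR = 1 s, window 17, step
1, activation 0.8, coverage 80%, which must select exactly 79 of 284
windows):

* the activation curve is computed by convolving the boxcar with the
  canonical HRF on a fine grid (TR/16), sampling at the end of each TR,
  and dividing by the curve's global maximum;
* the per-TR activation mask is `curve > 0.8`; the per-TR coverage mask
  is the task fraction of the window-length span *centered* on the time
  point, with out-of-range TRs counting against coverage, at `>= 80%`;
* window $w$ (covering TRs $[w, w+N-1]$ at step 1) reads the combined
  mask at its **first** TR.

Under this convention the example yields 18 selected windows per interior
task block and 7 in the final block (truncated by the window count), 79
in total. The calibration is *robust*: the counts are unchanged for
convolution grids from TR/8 to TR/32 and for strict vs non-strict
thresholding, and the activation values adjacent to the threshold sit at
0.73 and 0.84, comfortably away from 0.8. Last- and center-TR indexing
and the within-window coverage reading remain available (`at =`,
`neighborhood =`), but they produce 97/82-window masks on the reference
design and are not the default.

Two activation normalizations are implemented because "maximum estimated
response" is ambiguous between a sustained block and a single stimulus:
`"global"` (default) scales the curve by its own maximum, so 1 means the
strongest response actually attained in this design; `"single-event"`
scales by the peak response to a one-TR stimulus, so sustained blocks
exceed 1. The default is the one fixed by the calibration above.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| window size | 17 | TR | ≥ 15 TRs for a stable correlation estimate, shorter than one 30 s block |
| step size | 1 | TR | densest trajectory; any divisor of the design works |
| Gaussian taper σ | window/6 | TR | ±3σ spans the window; rectangular is the default taper |
| wavelet levels / kept | 5 / 3–5 | — | keeps ≈ 0.015–0.125 Hz at TR = 1 s |
| activation threshold | 0.8 | fraction of max response | excludes transition periods around block edges |
| coverage threshold | 80 | % of window TRs | window must be dominated by one condition |
| binarization sweep | 0.5–0.85 by 0.01 | r | absolute thresholding; 36 densities per window |
| ensemble size | 20 | graphs | fixed-(n, m) uniform reference for γ, λ, σ |

# Numerical choices

* **Unreachable pairs.** Inverse distances of unreachable pairs
  contribute 0 to efficiencies; the characteristic path length averages
  over *reachable* ordered pairs only. At sparse thresholds this choice
  changes L materially, which is why it is stated here rather than left
  implicit. A graph with no reachable pair has no defined L and raises an
  error instead of returning a sentinel.
* **Strictness and ties.** Absolute and proportional rules keep an edge
  on `value > threshold` (strict); cost thresholding keeps the top
  `round(cost · n(n−1)/2)` coefficients with ties broken by descending
  value then ascending node-pair order, so results are deterministic.
* **Missing edges.** A region that is constant within a window has an
  undefined correlation; those entries are flagged missing (not set to 0,
  which is a meaningful correlation) and are never kept by any
  binarization rule.
* **Modularity.** Q is maximized exactly by exhaustive partition search
  for networks of up to 8 nodes and by deterministic greedy agglomeration
  (best merge first, earliest pair on ties, best partition along the
  merge path) above that; the greedy result is never below the
  single-module Q of 0.
* **Random ensembles.** Reference graphs are uniform over simple graphs
  with exactly (n, m) — matching the definition of the normalization —
  with degree-preserving rewiring available as an option. Ensembles are
  seeded and restore the session RNG state on exit, as does the data
  simulator, so library calls never perturb user-level reproducibility.
* **MODWT.** The LA8 (least-asymmetric, length-8) scaling filter is
  hard-coded; boundaries are handled by reflection (the series is
  mirrored to twice its length, transformed circularly, and truncated).
  Reconstruction from all levels plus the smooth is exact to ~1e-12 and is
  tested to 1e-8. The approximation band is *dropped* by default when
  reconstructing from selected levels, since level selection is meant to
  band-limit; `keepSmooth = TRUE` retains it.
* **Degenerate statistics.** Assortativity of a regular graph is NaN (a
  flag, not an error); transitivity of a triple-free graph is 0 with a
  warning; a paired test on identical variance vectors returns t = 0,
  p = 1, and on constant non-zero differences returns ±Inf with a
  degeneracy flag.

# The synthetic generator

`simulateROITimeSeries()` draws a latent standard-normal signal $z_t$ and
sets $x_{rt} = w_t z_t + \epsilon_{rt}$ with
$\epsilon_{rt} \sim N(0, \sigma^2)$ i.i.d. The mixing weight
$w = \sigma\sqrt{\rho/(1-\rho)}$ makes the population correlation between
any two channels exactly $\rho$ *including* the noise, so the target
couplings (`rhoTask = 0.6`, `rhoRest = 0.2` by default, `noiseSD = 1`)
are interpretable without correction. The default design is the 5 × 30 s
task / 5 × 30 s rest paradigm at TR = 1 s (300 volumes). With
`hrfSmoothing = TRUE` (default) the coupling switch follows the
normalized canonical response rather than the boxcar, so transitions have
a realistic hemodynamic lag.

What the generator does *not* emulate: physiological drift and motion
spikes, spatial autocorrelation between voxels, region-specific
hemodynamics, negative coupling structure, or non-stationarity within a
condition. Passing tests on this generator therefore demonstrates the
correctness of the pipeline's arithmetic and its qualitative behavior
under condition-dependent coupling — not robustness to realistic fMRI
artifacts, which preprocessing upstream of this package is responsible
for.

Problem sizes used in the shipped tests are chosen to make each property
checkable in seconds: graphs of 4–8 nodes against exhaustive oracles
(200 draws), 40–100 nodes against independent formula evaluations and
igraph cross-checks, 10-ROI 300-volume subjects for pipeline-level
checks, and 20 subjects for the group-level stability comparison.

# Known limitations

* Only block designs are supported for mask generation; event-related
  designs with jittered onsets, parametric modulators, and HRF
  derivative regressors are out of scope.
* Graph metrics are for undirected binary graphs; weighted and directed
  variants, rich-club coefficients, and state-clustering approaches to
  dynamic connectivity are not implemented.
* Atlas and data grids must agree exactly (same shape, affine within
  1e-4); no resampling or registration is performed.
* The variance-based stability measure is computed per threshold; the
  summary averages variances over the threshold sweep, which weights all
  densities equally.
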