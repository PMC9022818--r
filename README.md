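# dynfc — task-related dynamics of functional brain network topology

Functional connectivity (FC) between brain regions is not constant during a
cognitive task: windowed estimates of inter-regional correlation, and the
graph-theoretical properties of the networks built from them, fluctuate as
the brain moves between rest and task states. `dynfc` is a scriptable R
toolbox for quantifying these dynamics in **block-design task fMRI**. It is
aimed at researchers who already have preprocessed, atlas-aligned 4D data
(or extracted ROI time series) and want a reproducible, file-based pipeline
from time series to group-level statements about the *stability* of network
topology during task performance.

## What it computes

1. **ROI time series** — mean BOLD signal per region from a 4D NIfTI volume
   and a label atlas, binary masks, or spherical ROIs; or directly from a
   TSV/CSV matrix (rows = time points, columns = ROIs).
2. **Band-limiting** — zero-phase frequency-domain filtering (cutoffs given
   as periods in seconds), or MODWT wavelet-level selection: the series is
   decomposed with the maximal overlap discrete wavelet transform and
   reconstructed from selected detail levels, level *j* occupying the
   nominal band [f_s/2^(j+1), f_s/2^j].
3. **Sliding-window FC** — for a window of *N* TRs advanced by a step of
   *s* TRs over *T* volumes, `⌊(T−N)/s⌋ + 1` matrices of pairwise Pearson
   correlations (rectangular or Gaussian-tapered weights). Setting
   *N* = *T* gives the static network.
4. **Temporal inclusive mask** — windows are marked task-related by
   thresholding the estimated activation (design boxcar convolved with the
   canonical double-gamma HRF, threshold 0.8 by default) AND the condition
   coverage of the window (≥ 80% task TRs by default).
5. **Graph metrics** — each windowed matrix is binarized (absolute,
   proportional, or wiring-cost thresholding; optionally on |r|) and
   summarized by global efficiency

   E_glob(G) = 1/(n(n−1)) Σ_{i≠j} 1/d_ij,

   local efficiency, clustering coefficient C, average degree,
   characteristic path length L, transitivity, assortativity, modularity Q,
   and the normalized quantities γ = C/C_rand, λ = L/L_rand and the
   small-world coefficient σ = γ/λ against 20 random networks with the same
   number of nodes and edges; plus nodal efficiency, nodal clustering,
   degree, and betweenness centrality B(i) = 1/((n−1)(n−2)) Σ_{j≠k}
   p(i|j,k)/P(j,k).
6. **Topological stability** — the dynamics of each property is the sample
   variance V = 1/(N−1) Σ (A_i − μ)² over the masked windows; per-subject
   task-masked variances are compared against full-duration variances with
   a paired two-sided t-test, and group trajectories are reported as mean ±
   SEM.

A synthetic-data module generates block-design multivariate series (and 4D
volumes) with condition-dependent inter-ROI coupling, so the entire
pipeline is testable without any imaging data.

## Worked example

Ten-ROI subjects with coupling 0.6 during task and 0.2 during rest
(5 × 30 s task blocks interleaved with 5 × 30 s rest blocks, TR = 1 s):

```r
library(dynfc)

design <- taskDesign("0 1 0 1 0 1 0 1 0 1", 30, tr = 1)
ts  <- simulateROITimeSeries(nROIs = 10, design = design,
                             rhoTask = 0.6, rhoRest = 0.2, seed = 1)
fc  <- slidingWindowFC(ts, windowSize = 17, stepSize = 1)
fc
#> FCSeries: 284 windows of 10 x 10, window 17 TR / step 1 TR (rectangular taper)

mask <- taskMask(design, fc)   # activation 0.8 AND 80% task coverage
mask
#> TemporalMask (both): 79 of 284 windows selected

tab <- metricsOverSeries(fc, metrics = "Eglob")  # absolute 0.5–0.85 by 0.01
head(varianceSummary(tab, mask), 1)
#>   metric threshold      Vtask       Vall    muTask     muAll Ntask Nall
#> 1  Eglob       0.5 0.03843824 0.04313377 0.6543601 0.5710493    79  284
```

The 300-volume run yields 284 windowed matrices, of which 79 are marked
task-related by the default mask. Global efficiency is higher (0.65 vs
0.57 at threshold 0.5) and *less variable* inside the task-related period
than over the full scan — the coupled regime is both stronger and more
stable. Across 20 simulated subjects (seeds 1–20) the task-masked variance
of global efficiency, averaged over the default threshold sweep, is lower
than the full-duration variance in 18/20 subjects (paired t = 5.50,
p = 2.6e-05):

```r
res <- runPipeline(subjects, config = list(metrics = "Eglob"))
res$group
#>  metric    t        p  meanVtask meanVall nSubjects
#>   Eglob 5.50  2.6e-05      0.031    0.048        20
```

A thin command-line wrapper is provided at `inst/cli/dynfc.R`
(`simulate` and `run` subcommands, YAML config; see
`defaultConfig()`).

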