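---
title: "Dynamic functional network metrics: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional network metrics: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis in one paragraph

`dynfc` treats a resting-state scan as a multi-layer temporal graph. A
subject's ROI time series (volumes × regions) is cut into overlapping
rectangular windows; within each window the pairwise Pearson correlation
matrix is the corresponding network layer. Three families of spatio-temporal
metrics summarize how that layered network reorganizes over time —
temporal variability (how much each node's connectivity profile changes
between windows), the temporal correlation coefficient (how consistently
each node keeps its neighbors between consecutive windows), and temporal
path length (how quickly any node can reach any other along time-respecting
paths). Group differences in these metrics are then tested with ANCOVA
models that adjust for age, sex, education, head motion (mean framewise
displacement) and acquisition site, with Benjamini–Hochberg FDR control,
and metric–symptom associations are assessed with partial Spearman
correlations.

## Windowing

A window of `window_s` seconds advanced in steps of `step_s` seconds is
converted to volumes through the repetition time. The conversion must be
exact: 100 s at TR = 2 s is 50 volumes, but 100 s at TR = 3 s is rejected
rather than rounded, because a fractional window has no defined sample set
and silent rounding would change the effective window length across sites
with different TRs. The number of windows is
`floor((n_volumes - window_vols) / step_vols) + 1`; with 230 usable volumes,
TR 2 s, a 100 s window and a 6 s step this gives 61 windows. Defaults are
100 s / 6 s; the sensitivity analyses re-run the pipeline over
windows of 40–100 s and steps of 4–8 s.

Windows are rectangular (no tapering). Correlation layers have their
diagonal fixed at 0 — a node's self-correlation is not an edge — and a node
whose series is constant inside any window raises an error naming the node
and window: on preprocessed BOLD data this indicates a broken extraction,
and a silently imputed correlation would contaminate every downstream
metric.

## Binarization at a sparsity threshold

Temporal clustering and temporal efficiency are defined on binary networks,
so each layer is thresholded to keep a fixed proportion (the *sparsity*) of
its strongest connections: `k = round(sparsity * E)` edges of the
`E = N(N-1)/2` undirected pairs, with round-half-away-from-zero. Ranking
uses the raw signed correlations, so strong positive edges win — the
standard convention in sparsity-thresholded connectome analysis — with
`rank_by = "absolute"` available when magnitude is the quantity of
interest. Ties at the cutoff are broken by ascending `(i, j)` pair order,
which makes the output deterministic; because a fixed count of top-ranked
edges is kept, the edge set is invariant under any strictly increasing
transform of the weights, and edge sets are nested across sparsities
(everything kept at 10% is still kept at 30%). No Fisher z-transform is
applied before thresholding; rank-based selection makes it irrelevant.
The default grid is 10%–50% in 1% increments (41 levels), and
sparsity-dependent metrics are also reported averaged over the grid.

## The three metric families

**Temporal variability** (weighted layers). For node $k$ with per-layer
connectivity profile $p_k(t)$ (its correlation-matrix row, self entry
removed),
$$V_k = 1 - \frac{2}{T(T-1)} \sum_{t<t'} \mathrm{corr}\left(p_k(t),\, p_k(t')\right),$$
which ranges from 0 (profile frozen) to 2 (profiles perfectly
anticorrelated between windows). The global value is the unweighted mean of
the nodal values; the alternative "whole-matrix" definition (one minus the
mean correlation of vectorized upper triangles across window pairs) is
available via `global_temporal_variability(method = "whole_matrix")`. A
node whose profile is constant within a layer makes the correlation
undefined and is reported as an error rather than dropped.

**Temporal correlation coefficient** (binary layers). For adjacency
$a_{ij}(t)$,
$$C_i = \frac{1}{T-1} \sum_{t=1}^{T-1}
  \frac{\sum_j a_{ij}(t)\,a_{ij}(t+1)}
       {\sqrt{\sum_j a_{ij}(t)\,\sum_j a_{ij}(t+1)}},$$
the mean normalized overlap of consecutive neighbor sets, in $[0, 1]$. A
step on which the node is isolated on either side has an undefined ratio;
that term contributes 0 rather than being skipped, which keeps the global
mean anchored to all $N$ nodes and the value inside $[0, 1]$.

**Temporal path length** (binary layers). The temporal distance
$d(i, j)$ is the earliest layer by which $j$ is reachable from $i$ along a
time-respecting path: successive edges occupy strictly increasing layer
indices (one edge traversal per layer) and waiting at a node is free. It is
computed by layer-sequential frontier expansion — the reached set of each
source persists across layers, and at layer $t$ all layer-$t$ neighbors of
the reached set are added with arrival time $t$ — which is equivalent to
exhaustive path enumeration (checked against one in the tests). The
convention matters: if unlimited hops were allowed within a layer
("non-decreasing" paths), any connected layer would make every distance 1
and the metric would degenerate at connectome densities of 10–50%; the
strictly-increasing rule preserves the 1-to-infinity range the metric is
meant to have. Distances are direction-dependent (reversing a path would
need decreasing layers), so the latency matrix is asymmetric even though
each layer is undirected. The nodal temporal path length averages the
*outgoing* finite distances $d(i, \cdot)$ — how quickly information
starting at $i$ spreads — and the characteristic temporal path length
averages over all ordered pairs with finite distance. Unreachable pairs are
excluded from the mean rather than imputed with a pseudo-distance, and
their fraction is carried through to the outputs so that pathological
subjects are visible to the statistics stage instead of silently shifting
the estimate. One consequence worth noting: waiting means a node with any
late-layer edge is still reachable — e.g. with layers
$\{(1,2)\}, \{(2,3)\}$, node 3 reaches node 2 at layer 2 by waiting through
layer 1.

## Group statistics

The group effect on each metric is the partial (extra-sum-of-squares) F
test of the group term in
`y ~ group + age + sex + education + mean_fd + site`, with site entering as
fixed-effect dummies (the simplest identifiable choice; random-site and
harmonization models are out of scope). Every site must contain both
groups, otherwise the group effect is confounded with site and the fit is
refused (subgroup contrasts instead drop offending sites with a warning,
since subgroup labels are not balanced by design). Collinear designs are
rejected naming the offending columns. For metrics computed on the
sparsity grid, the between-subject group main effect of the
repeated-measures design with sparsity as a complete within-subject factor
is exactly the ANCOVA on each subject's sparsity mean, which is how it is
computed; sphericity corrections concern within-subject terms and are moot
for this effect. Per-sparsity ANCOVAs are reported alongside to show
consistency across the grid, and the group-by-sparsity interaction is
deliberately not part of the interface.

Partial Spearman correlations rank-transform both variables (average ranks
on ties), residualize the ranks on the covariate design (age, sex, site) by
least squares, and correlate the residuals; the p-value uses the t
approximation with $n - 2 - q$ degrees of freedom. Missing clinical scores
are handled by listwise deletion per correlation. FDR families mirror the
reporting structure: the three global metrics for the primary comparison,
regions within a metric for nodal tests, and metrics × contrasts for the
subgroup family.

## What the synthetic cohorts emulate — and what they do not

The generator is a hidden-Markov covariance-switching model: each subject
moves through a small set of connectivity "states" (block-structured
correlation matrices; each state permutes the node-to-block assignment)
as a first-order Markov chain with geometric dwell times, and volumes are
i.i.d. multivariate-normal draws from the current state plus isotropic
observation noise. The group manipulation targets *switching rate only* —
default mean dwell 50 volumes (100 s) for patients versus 200 volumes
(400 s) for controls — so the injected effect is specifically dynamic
rather than a difference in connectivity strength, which is what the
temporal metrics claim to detect. A HAMD-like severity score is linear in
each patient's realized switching rate plus noise (slope 500 per unit
transition rate, intercept 8, SD 4), so the generator also plants a
recoverable positive variability–severity association. Covariates (age,
sex, education, mean FD, site) are drawn from distributions resembling an
adult clinical cohort and have no effect on the time series by default
(`fd_noise_gain` can couple motion to noise level); they exist so the
adjustment machinery is exercised, not to simulate confounding.

The dwell-time defaults deserve a note, because the interplay with the
window is not obvious. Sliding-window variability responds to switching
non-monotonically: when state epochs are much shorter than the 50-volume
window, every window averages over many states, all windows look alike, and
faster switching *lowers* variability; only when epochs are on the order of
the window length or longer do different windows capture different states.
Defaults were therefore chosen so that control epochs (≈2 per scan) are
long relative to the window while patient epochs (≈100 s) sit at the window
scale — the regime in which a faster-switching group genuinely shows higher
temporal variability, lower temporal clustering and shorter temporal paths
through the claimed mechanism.

What the generator does not emulate: hemodynamic smoothing and temporal
autocorrelation of BOLD (volumes are independent given the state), scanner
noise spectra, motion artifacts, site-specific effects on the signal, and
realistic anatomical covariance. Passing the recovery tests therefore shows
that the pipeline detects genuine switching-rate differences under the
model's assumptions; it does not certify behavior under autocorrelated
noise or site confounding on real data.

## Numerical choices and degenerate inputs

* Seconds-to-volumes conversions must be exact (tolerance $10^{-9}$);
  anything else is an error.
* Zero-variance detection in windows uses a relative tolerance of
  $10^{-12}$ on the second moment to guard against floating-point
  cancellation on constant columns.
* `k = round(sparsity * E)` uses round-half-away-from-zero; `k = 0` is an
  error rather than an empty layer.
* Constant outcomes in the ANCOVA (zero extra and residual sums of squares)
  return F = 0, p = 1 instead of 0/0.
* All-unreachable latency matrices are an error for the characteristic path
  length; individual unreachable nodes report `Inf` with a count attribute.
* Per-subject RNG substreams are derived from the cohort seed by an affine
  counter scheme, so any subject is reproducible independent of generation
  order, and a fixed seed makes cohorts, metrics CSVs and manifests
  reproduce exactly.

## Problem sizes used by the checks

The simulation-based checks run at a deliberately reduced scale chosen to
exercise every stage while keeping the full suite fast: cohorts of 40 + 40
subjects, 20 regions, 230 volumes at TR 2 s, a five-level sparsity grid
(10%–50% in 10% steps) for cohort-level simulations, 100 cohorts for the
direction-recovery and null-calibration checks, and exhaustive-enumeration
cross-checks on 500 random networks of up to 6 nodes and 4 layers. The
robustness checks use a single large cohort (100 + 100 subjects): the
window/step sensitivity sweep runs on the reduced sparsity grid, while the
split-half analysis uses the full 41-level grid, whose averaging stabilizes
the path-length estimate — the path-length group contrast carries the most
between-subject variance of the three metrics, because it inherits the
randomness of each subject's realized switching sequence. The
window-arithmetic, metric-limit and statistics oracles are exact and run at
full precision. Effect statistics from real multi-site clinical samples
(specific F and rho values) require access to such data and are not
reproduced here.

## Known limitations

* Only rectangular windows; no tapering.
* Weighted generalizations of temporal clustering and efficiency are not
  implemented (the metrics are defined on binary networks), and no
  FC-state clustering (k-means state analysis is a different approach).
* Fixed-effect site adjustment only; no ComBat-style harmonization or
  mixed models.
* The temporal-path convention (strictly increasing layers, waiting
  allowed) is one reasoned convention among several in the temporal-graph
  literature; comparisons with toolboxes using per-layer multi-hop paths
  will differ by construction.
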