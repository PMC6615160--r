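---
title: "Methods: distance-correlation connectivity and local efficiency of visual networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-correlation connectivity and local efficiency of visual networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`vicnet` implements a two-group resting-state fMRI connectivity analysis of
the visual intrinsic connectivity networks (ICNs). Nineteen regions of
interest spanning three ICNs — the higher visual network (HVN, 4 nodes), the
primary visual network (PVN, 2 nodes) and the visuospatial network (VSN, 13
nodes) — define a fixed node set. For each subject the pipeline produces a
19×19 matrix of Fisher-transformed multivariate distance correlations
between ROI voxel patches, summarizes it into intra-/inter-network block
means and sparsity-swept nodal local efficiency, and compares a patient
group (amblyopes in the motivating design) against controls with a
split-plot ANOVA, pooled t-tests and Storey q-values.

The package analyses either real pre-extracted ROI voxel×time matrices (TSV)
or 4D NIfTI volumes through the atlas masks, but ships with a synthetic
cohort generator so the entire analysis is exercisable and testable without
access to human imaging data.

## Connectivity: U-centered distance correlation

Let an ROI be a $v \times t$ matrix (voxels × frames). After z-scoring each
voxel's time course, the $t \times t$ matrix of Euclidean distances between
time-point voxel patterns is formed,
$d_{t_1 t_2} = \lVert x_{\cdot t_1} - x_{\cdot t_2} \rVert_2$, and
U-centered: off the diagonal,

$$D_{t_1 t_2} = d_{t_1 t_2}
  - \frac{1}{t-2}\sum_{p} d_{t_1 p}
  - \frac{1}{t-2}\sum_{q} d_{q t_2}
  + \frac{1}{(t-1)(t-2)}\sum_{p,q} d_{q p},$$

with $D_{tt}=0$. Every row and column of $D$ then sums to zero, and

$$\mathrm{dCov}(A,B) = \frac{1}{t(t-3)} \sum_{t_1,t_2} D_{A}D_{B}, \qquad
  \mathrm{dVar}(A) = \frac{1}{t(t-3)} \sum D_A^2$$

is the *unbiased* (signed) U-statistic estimator of distance covariance.
The distance correlation is
$\mathrm{dCor} = \sqrt{\mathrm{dCov}/\sqrt{\mathrm{dVar}_A\,\mathrm{dVar}_B}}$
when $\mathrm{dCov} > 0$ and $0$ otherwise, so edges live in $[0,1]$. Edges
are Fisher-transformed, $z = \tfrac12\log\frac{1+r}{1-r}$.

Numerical choices:

* the clamp of negative dCov to zero is applied *after* the signed
  U-statistic is computed, so the unbiased value remains available
  internally (`dcov_u`) for diagnostics;
* $t \ge 4$ is enforced (the $t-3$ denominators require it);
* a degenerate ROI with zero distance variance yields dCor 0 with a warning
  rather than an error, so one bad region cannot kill a cohort run;
* dCor values at or above $1-10^{-7}$ are clamped before the Fisher
  transform ($z(1)$ is infinite); the diagonal is excluded anyway.

Because every voxel is standardized first, the statistic is exactly
invariant to affine rescaling of either ROI and to voxel order; both are
asserted in the test suite against an independently written naive
implementation of the defining sums.

## Temporal preprocessing

Per subject, in order: polynomial detrending (default order 3), framewise
displacement censoring, zero-phase band-pass, motion-confound regression.

* **FD** is Power-style: per frame, the sum of absolute backward differences
  of the three translations plus 50 mm times the sum of absolute rotation
  increments; frames with FD > 0.2 mm are deleted. The censoring decision is
  made once from the acquisition motion trace; a scan carrying its censor
  mask is not re-censored, making the stage idempotent (FD across a deletion
  junction is not a within-frame motion artifact).
* **Band-pass** is a 4th-order Butterworth, 0.01–0.10 Hz at TR = 2 s,
  applied forward and backward so connectivity sees no phase distortion. At
  mid-band the gain is within 1% of unity; one octave outside the edges it
  is below 0.01. Filtering is applied to the concatenated kept frames:
  band-passing gappy series is ill-posed, so censoring precedes filtering
  (a `filter_before_censor` flag provides the alternative order).
* **Confound regression** projects out an intercept, the six motion
  parameters and their backward-difference derivatives; the confounds are
  censored and filtered exactly like the data first. Constant columns are
  dropped; any residual rank deficiency is an error naming the columns.

Deleted (not interpolated) censored frames and the motion-only confound set
reflect the narrowest reading of the preprocessing description this package
emulates; both are configurable at the function level.

## Graph metrics: local efficiency over a sparsity sweep

Each subject's z-matrix is thresholded at sparsities 0.20–0.80 in steps of
0.05 (13 points), retaining the `round(s·171)` strongest edges with their
weights (ties broken deterministically by node index, which makes edge sets
nested across the grid). For node $i$, the neighbor subgraph $G_i$ contains
the nodes directly connected to $i$, excluding $i$ itself; the local
efficiency is

$$E_{local}(i) = \frac{1}{N_{G_i}(N_{G_i}-1)} \sum_{j \ne k \in G_i} \frac{1}{l_{jk}},$$

where $l_{jk}$ is the shortest path length between $j$ and $k$ *within*
$G_i$. Stronger edges must mean shorter paths, so edge length is the
reciprocal of the weight after rescaling all weights by the matrix maximum;
lengths are then ≥ 1 and $E_{local} \in [0,1]$. The literal
"sum of weights along the path" reading is available behind
`lengths = "raw"`. Nodes with fewer than two neighbors score 0, as do
disconnected neighbor pairs — degenerate nodes must still enter the group
t-tests. The per-node area under the LE-versus-sparsity curve (aLE) is a
trapezoidal integral over the grid: a threshold-free nodal summary.

Whether the motivating analysis binarized graphs before LE is not stated in
its description; weighted retained-weight graphs (the common toolbox
default) are used here, and the trapezoid (not a Riemann sum) is the AUC
rule. Both choices are flagged as assumptions.

## Group statistics

Per subject, intra-network connectivity is the mean upper-triangle z within
each ICN (for the two-node PVN, the single lV1–rV1 edge) and inter-network
connectivity the mean over cross-network pairs. Group comparisons:

* **Split-plot ANOVA** with group as the between-subject factor and
  condition (3 networks, 3 network pairs, or 19 nodes) as the within-subject
  factor. The group effect is tested against subjects-within-groups; the
  condition and interaction effects against the within-subject residual.
  With 18 + 18 subjects and 3 conditions the dfs are (1, 34) and (2, 68);
  with 19 nodes, (18, 612). No sphericity correction is applied (none is
  reported in the motivating design); the implementation is verified against
  a textbook sums-of-squares oracle.
* **Pooled-variance t-tests** (df = $n_1+n_2-2$ = 34 at the design size;
  pooled rather than Welch because that df pattern is the reported one).
* **Storey q-values** with fixed $\lambda = 0.5$:
  $\hat\pi_0 = \min(1, \#\{p > \lambda\}/((1-\lambda)m))$ and
  $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. The finite-sample
  pFDR factor $1/(1-(1-p)^m)$ sits behind a `pfdr` flag. Families are
  corrected separately: 3 intra tests, 3 inter tests, 19 node tests.
  *Caveat*: with very small families the plug-in $\hat\pi_0$ can be 0 (for
  $m=3$ this happens with probability 1/8 under the complete null), which
  declares every test significant. The estimator is kept as defined; its
  FDR control is verified on the 19-test family, where it is well behaved.
* **Acuity correlations**: Pearson r of each block measure against the
  patients' amblyopic-eye logMAR.

## The synthetic cohort generator

The generator is the package's study stand-in, not a fixture. Each subject's
node signal is a mixture of one global factor, one factor per network and an
idiosyncratic factor — all built by forward–backward band-pass filtering
white noise to 0.01–0.10 Hz (zero phase, so no group-differential phase
artifacts) and standardizing:

$$s_i(t) = a\, f_{net(i)}(t) + b\, g(t) + \sqrt{1-a^2-b^2}\; e_i(t),$$

with white voxel noise (SD 1) added to every voxel of the 33-voxel patch
(the size of a 6 mm sphere on the 3 mm grid). The subject's coupling $a$ is
drawn once per network around the group mean (between-subject SD 0.10), and
$b = 0.3$ globally; the variance budget $a^2+b^2<1$ is validated. Motion is
a slow random walk (0.02 mm/frame translations, 4×10⁻⁴ rad/frame rotations,
which contributes comparably to FD at a 50 mm head radius) plus Bernoulli
(rate 0.02) persistent step spikes of 0.5 mm — persistent, so each spike
censors exactly one frame at the 0.2 mm threshold. Acuities are truncated
normal draws per eye and group (patient amblyopic eye 0.59 ± 0.23 logMAR,
fellow 0.01 ± 0.06; controls near 0). All randomness flows from one root
seed via deterministic per-subject seeds.

**Coupling defaults.** Controls couple at 0.50 in every network. The patient
group's deficit — HVN 0.31, VSN 0.38, PVN 0.50 (no deficit) — was calibrated
once, by a pilot measurement of the realized downstream Cohen's d of the
intra-network block means at the analysis problem size used throughout the
replicate checks (18 + 18 subjects, 96 frames, 6 voxels per ROI), and then
frozen. The target was d ≈ 0.9, the effect size implied by a t of −2.64 with
34 df at this design size. HVN needs a larger coupling gap than VSN because
its block mean averages only 6 edges against VSN's 78, so edge-estimation
noise dilutes the programmed effect more. Note that the realized d grows
with frames and voxels (at 180 frames × 33 voxels the same gaps give
d ≈ 1.3) because estimation noise shrinks while the coupling gap is fixed;
d ≈ 0.9 is a property of the cohorts at the stated analysis size.

**What the generator does not emulate**: physiological (cardiac/respiratory)
noise, spatial autocorrelation beyond the shared ROI signal, scanner drift
beyond an optional linear+quadratic trend, non-stationarity, and real
parcellation geometry (spherical masks stand in for parcel volumes; the
atlas distributes only the 19 node centers). Passing tests therefore
demonstrate correctness of the estimators and recoverability of programmed
effects under this model — not robustness to everything real rs-fMRI
contains.

## Problem sizes used in the checks

The replicate-based checks simulate cohorts of 18 + 18 subjects at 96 frames
and 6 voxels per ROI (200 replicates for effect-direction recovery and PVN
null calibration), the FDR-control check uses 500 null cohorts at the
summary level (36 subjects × 19 node summaries — under the complete null the
pipeline's subject summaries are exchangeable iid values, so the q-value
machinery sees the same uniform p-values), and oracle-equivalence checks use
50 random instances each. The acceptance script runs one full cohort at
120 frames × 8 voxels plus 60 replicate cohorts at the reduced size.

## Known limitations

* The group-level numbers of any real study cannot be reproduced from
  synthetic cohorts; the package verifies estimator correctness, calibration
  and programmed-effect recovery instead.
* Spherical masks around node centers are a stand-in for volumetric
  parcellations; real parcel shapes change voxel counts per node.
* The U-centering denominators require t ≥ 4 after censoring; heavily
  censored scans fail with a clear error (`min_kept_frames`, default 50,
  guards the realistic range).
* Storey's $\hat\pi_0$ degeneracy for tiny families (above).
* Spatial preprocessing (registration, slice timing, smoothing,
  normalization) is out of scope; inputs are assumed already on a common
  grid.
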