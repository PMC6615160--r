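# vicnet

Resting-state functional-connectivity analysis of the visual intrinsic
connectivity networks (ICNs), for researchers studying how developmental
visual disorders such as amblyopia reshape the brain's visual networks.
`vicnet` compares a patient group against controls on a fixed 19-node visual
atlas — 13 visuospatial (VSN), 4 higher-visual (HVN) and 2 primary-visual
(PVN) nodes — using multivariate distance-correlation connectivity and
graph-theoretical local efficiency.

## What it computes

For each subject, every ROI is a voxels × time matrix. Connectivity between
ROIs *A* and *B* is the **U-centered distance correlation**: Euclidean
distances between time-point voxel patterns are U-centered so all row and
column sums vanish, giving the unbiased estimator

    dCov(A,B) = 1/(t(t-3)) Σ D_A D_B,
    dCor(A,B) = sqrt( dCov / sqrt(dVar(A) dVar(B)) )   (0 if dCov ≤ 0)

and edges are Fisher-transformed, z = ½ log((1+dCor)/(1−dCor)), yielding a
19×19 matrix per subject. Upstream, scans pass through framewise-displacement
censoring (0.2 mm), order-3 polynomial detrending, zero-phase 0.01–0.10 Hz
band-pass and motion-confound regression. Downstream, each matrix is
thresholded at sparsities 0.20–0.80 (step 0.05); the **nodal local
efficiency** — the mean inverse shortest-path length among a node's
immediate neighbors, within the neighbor subgraph — is integrated over the
sweep into a per-node AUC (aLE). Group statistics are split-plot
repeated-measures ANOVAs, pooled two-sample t-tests, Storey q-values
(families: 3 intra-network, 3 inter-network, 19 nodes, corrected
separately) and Pearson correlations with visual acuity.

A seeded synthetic cohort generator produces band-limited two-group cohorts
with a programmed extra-striate (HVN/VSN) coupling deficit and an unaffected
PVN, realistic motion traces with censorable spikes, and logMAR acuities —
so the whole pipeline is testable without human data. See the methods
vignette (`vignettes/vicnet-methods.Rmd`) for the model and every numerical
choice.

## Worked example

```r
library(vicnet)

cfg <- pipeline_config(
  cohort = cohort_config(n_per_group = 4, t_frames = 120,
                         voxels_per_roi = 8, seed = 7))
res <- cmd_run_all(cfg)
#> simulated 8 subjects (4 per group, 120 frames)
#> connectivity: 8 matrices of 19x19; kept frames 115-119
#> group tests: 3 intra, 3 inter, 19 node
print(res$report)
#> Group report: 4 patients vs 4 controls
#> Intra-network ANOVA: group F(1,6)=1.54 p=0.261; condition F(2,12)=1.04
#>   p=0.384; interaction F(2,12)=3.51 p=0.0631
#>   unit mean_patient mean_control      t df     p q
#> 1  HVN        0.239        0.372 -2.613  6 0.040 0
#> 2  PVN        0.328        0.262  0.884  6 0.411 0
#> 3  VSN        0.320        0.373 -1.882  6 0.109 0
#> ...
```

Even at this toy size the programmed deficit shows: patients' mean HVN and
VSN Fisher-z connectivity (0.24, 0.32) sit below controls (0.37, 0.37) with
negative t statistics, while the unaffected PVN does not. At the study
design size (18 per group) the deficit reaches significance in a solid
majority of simulated cohorts. The per-subject matrices (`res$matrices`),
local-efficiency profiles (`res$profiles`) and all test tables
(`res$report`) are returned; with an `outdir`, everything is written as
labelled TSV/JSON plus a run log and manifest, and `cmd_report()` renders
heatmaps, the thresholded graph (node size ∝ aLE) and block bar charts.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/vicnet.R run-all --outdir out --seed 1 --n-per-group 18
```

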