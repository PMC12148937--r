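---
title: "Methods: models, parameters and design choices in enskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in enskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enskit)
```

enskit re-implements, as one tested toolkit, the computational procedures
used to characterize mouse submucosal enteric neurons and their functional
interactions: droplet-level quality control and iterative contaminant
exclusion for scRNA-seq, graph-based clustering and marker annotation,
cross-dataset label transfer, ligand–receptor communication scoring,
calcium-trace response classification under a mechanical-stimulation
protocol, and 3D varicosity-to-cell distance quantification. Every stage
has a synthetic-data generator that plants a known ground truth, so each
claim the package makes about recovery can be checked quantitatively.

This vignette explains the models and the choices behind them. It states
no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Synthetic data generators

`gen_counts()` draws a genes × cells negative-binomial matrix,
parameterized by (mean, dispersion) with per-cell log-normal library
sizes — the simplest standard model sufficient for recovery testing.
Planted structure:

* **Classes and markers.** Each singlet belongs to one of `n_classes`
  classes; each class elevates its `markers_per_class` marker genes by
  `2^marker_log2fc` (class profiles are renormalized, so the realized
  in/out marker ratio is very slightly below the nominal fold).
* **Doublets** are the summed raw counts of two random singlet parents,
  binomially thinned to 0.8× the summed library: doublets in droplets have
  elevated but not doubled depth, which is exactly the signal the pANN
  detector relies on.
* **Contaminants** come from an unrelated (permuted) expression profile
  carrying their own marker set, emulating epithelial/myocyte/immune
  droplets that co-sort with neurons.
* **Mitochondrial fraction** is imposed by rescaling the `mt-` genes to a
  drawn per-cell fraction, because QC thresholds act on that fraction
  directly.
* **Sex genes**: females draw Xist ~ Poisson(5) and zero Y-linked counts;
  males the reverse (four Y genes at Poisson(1.5) each), leaving a small,
  realistic rate of zero-evidence cells.

The generator does **not** model transcriptome-wide covariance, ambient
RNA, or batch chemistry; passing recovery tests therefore demonstrates
correctness of the algorithms at the stated effect sizes, not performance
on arbitrary real data.

`gen_traces()` emulates GCaMP6f recordings at 50 frames/s: baseline
fluorescence 100 with Gaussian noise, transients with instantaneous rise
and exponential decay (default amplitude 5σ, τ = 1 s — a fast indicator's
shape). The default protocol is 24 epochs at 45 s period with first onset
at 20 s and a 40 s tail: 1140 s, i.e. the 19-minute session of the
emulated experiment. Quiescent cells respond once per epoch at a planted
latency; spontaneous cells fire as a homogeneous Poisson process through
the whole recording (and, by default, also respond to stimuli, as such
cells did in the recordings this emulates).

`gen_scene()` places non-overlapping ellipsoidal cell bodies in a box and,
for each cell, one varicosity offset from a random surface point along the
outward normal by exactly the planted distance — for a convex body that
surface point remains the true nearest point at any positive offset, so
the construction is analytically exact. Background varicosities are
rejection-sampled to stay farther than every planted distance (0.5 µm
guard).

## Quality control

`global_filter()` applies, in order: the gene pre-filter (expressed in
< 3 cells), the cell pre-filter (< 200 UMIs), then the global thresholds —
mitochondrial fraction (0.2 for juvenile-style data, 0.1 for postnatal),
detected genes within [500, 6500] (bounds inclusive: "within the range" is
read inclusively), and ≤ 40,000 UMIs. Per-cell statistics are computed once
after the gene pre-filter; each removed cell is tagged with the first
criterion it violates so reports itemize removals per criterion.

`cluster_percentile_trim()` removes, within each cluster independently,
cells strictly below the 1st or strictly above the 99th percentile of the
cluster's UMI distribution. The percentile convention is linear
interpolation between order statistics (`quantile(type = 7)`, the common
statistical default); the original procedure does not state its
convention, so this one is fixed here and exercised against a brute-force
oracle in the tests. Clusters with fewer than 3 cells are left untrimmed —
percentiles of two points are meaningless.

`doublet_scores()` is a pANN scorer: artificial doublets (25 % of the
merged dataset, i.e. `pN/(1−pN)` × n real cells) are summed pairs of real
cells; after log-CPM normalization, HVG selection and PCA, each real
cell's score is the fraction of its k = 30 nearest neighbors that are
artificial. The original tool's pK sweep is deliberately not reproduced:
pANN is the algorithmic core, and no parameter values were reported for
it. The "auto" threshold is the (1 − expected rate) score quantile.

`iterative_refine()` alternates clustering (at the configured resolutions)
with signature-driven exclusion and optional percentile trimming. A
cluster is excluded when the mean over its cells of the **cell-level**
z-scored signature expression exceeds 2. Scoring across cells rather than
z-scoring cluster means across clusters is a deliberate choice: with K
clusters the largest attainable across-cluster z is √K·(K−1)/K, which is
below 2 whenever K ≤ 5, so a contaminant cluster among a handful of real
ones could never be flagged at the default threshold under that scheme.
The cell-level score has no such ceiling and reduces to the same ordering
when many clusters exist.

## Normalization, clustering and annotation

Two normalizations are provided. `log_cpm` is `log1p(1e4·x/libsize)`.
`pearson_residual` is the analytic Pearson residual of a negative binomial
with fixed dispersion θ = 100 and mean proportional to library size,
clipped at ±√n_cells — a closed-form variance stabilization in the spirit
of regularized NB regression, without re-fitting per-gene GLMs. HVGs are
the top genes by normalized variance after removing the exclusion list
(sex-linked genes by default, optionally immediate-early genes); excluded
genes stay in the matrix for downstream analysis, they are only barred
from driving the embedding.

`snn_louvain()` builds a Euclidean kNN graph in PC space (k = 20 default),
re-weights edges by the Jaccard overlap of neighbor sets (sets include the
cell itself), prunes below 1/15 — common defaults where the original
analysis states none — and runs Louvain at the configured resolution with
a seed-fixed traversal. Labels are canonicalized as 0..C−1 by decreasing
community size, so partitions are comparable across runs.

`de_markers()` tests each gene cluster-vs-rest with a two-sided Wilcoxon
rank-sum (normal approximation, tie-corrected, no continuity correction,
which makes the implementation exactly equal to the closed-form oracle the
tests carry). BH adjustment is within cluster; genes are ranked by
adjusted p, ties broken by decreasing signed logFC so that p-saturated
ties resolve toward overexpressed genes — the direction a marker table is
for. logFC is the normalized-scale mean difference divided by log 2.

`annotate_classes()` scores each cluster against each signature as the
mean z-scaled expression of the signature genes over the cluster's cells
and assigns the argmax only when it leads the runner-up by a margin
(default 0.1 z units); otherwise the cluster is `unassigned`, which also
covers exact ties.

## Sex inference and label transfer

`infer_sex()` is purely rule-based: Xist⁺/Y⁻ → F, Xist⁻/Y⁺ → M, both
zero → NA (no evidence), both positive → ambiguous. Only this rule is
contractual; no trained classifier is involved.

`joint_embed()` merges per-dataset HVG lists, restricts to shared genes,
and fits one PCA on the concatenation. Batch alignment is per-dataset
centroid matching in PC space, iterated to convergence (≤ 10 passes): the
minimal defined computation realizing "integration" when the class
structure is shared. It corrects global shifts only — class-specific batch
distortions are out of scope, which is why the tests use an additive batch
effect.

`transfer_labels()` removes masked reference labels *before* the neighbor
search (so masked labels are structurally unpredictable, not just
down-weighted), then classifies each query cell by Gaussian
distance-weighted kNN voting (k = 30, bandwidth = the cell's median
neighbor distance). Scores form a probability vector per cell; prediction
is the argmax.

## Ligand–receptor scoring

For each record and ordered (sender, receiver) pair:

* L = geometric mean over ligand genes of per-tail truncated means
  (trim 0.20 for neuron–neuron, 0.10 for neuron–epithelium, where small
  heterogeneous epithelial clusters would otherwise lose true signal) of
  sender expression; R likewise for receptor subunits in the receiver.
* probability = L·R / (kh + L·R), with kh = 0.5 on the normalized
  expression scale.

The Hill form with geometric-mean subunit aggregation mirrors the
published communication-probability model this stands in for; since no
formula is printed in the original methods, the formula is fixed here and
every constant is exposed in `lr_params()`. Cofactor modulation is
carried in the database schema but not scored. The permutation null
reshuffles group labels and uses the add-one estimator
p = (1 + #{null ≥ obs}) / (1 + B), so p is never zero and under an
exchangeable null P(p ≤ 0.05) is exactly 0.05 for B = 199; BH runs within
each sender→receiver pair. Note that a calibration estimate over 200
interactions carries binomial noise (sd ≈ 0.015 at the 5 % level).

## Calcium epoch analysis

ΔF/F uses a running 10th-percentile baseline (30 s window, knots every
second, linearly interpolated), which tracks slow drift while ignoring
transients. Spike detection is defined here because the original
"custom notebook" specifies none:

1. noise σ is estimated robustly from first differences
   (`mad(diff(dff))/√2`), insensitive to the transients themselves;
2. a causal 0.3 s boxcar average of ΔF/F must exceed `z_threshold`·σ
   (default 3.5). Thresholding raw samples cannot work at 50 frames/s — a
   3.5σ white-noise upcrossing occurs roughly every 1.5 minutes, far above
   any tolerable false-positive budget — so smoothing is part of the
   detector's definition, and against the smoothed noise the effective
   threshold is ≈ 13.5σ while a 5σ fast transient still averages ≈ 4.3σ
   over the window;
3. each detection is backtracked over the smoothing window to the first
   raw sample above threshold, recovering the true onset sample for
   fast-rising transients (so latencies are not biased by the smoothing
   delay);
4. onsets closer than 0.5 s merge (earliest kept).

Epoch windows: stimulus [0, 25) s from onset (the *first* electrode-down;
latency is measured "from the start of the mechanical stimulus"), post
[25, 45), baseline [−20, 0). Latency classes are half-open exactly as
stated: immediate [0, 0.5) — "< 0.5 s" is taken literally, so a spike at
exactly 0.5 s is delayed — delayed [0.5, 25), poststimulus [25, 45),
otherwise none.

Because the epoch period is 45 s, each baseline coincides exactly with the
previous epoch's post-stimulus window. Classifying any baseline spike as
"ongoing activity" would therefore label every post-stimulus responder
spontaneous; `classify_cell()` instead counts only *pure-baseline* spikes
(baseline time belonging to no stimulus/post window — in the default
protocol, the stretches before the first epoch and after the last post
window). Spontaneous cells' stimulus-locked activity is recorded but, as
in the emulated analysis, spontaneous cells are excluded from epoch-level
comparison by default. `compare_groups()` reports both the two-tailed
Student's t and the Mann–Whitney U on per-cell metric reductions and flags
one as primary.

## 3D proximity

Point-to-ellipsoid distance solves the Lagrange condition
Σ (aᵢqᵢ)²/(t+aᵢ²)² = 1 with a safeguarded Newton iteration (bracketed,
tolerance 1e−12 on the residual, ≤ 100 iterations); interior points return
0. Triangulated meshes take the minimum over per-triangle distances
(region-decomposed closed form), so both a parametric and a mesh path
exist — the upstream surface representation is proprietary, and scenes may
carry either. Varicosities are treated as points (their centers), matching
how "varicosity-to-cell distance" is quantified; distances are
center-to-surface, an assumption noted because surface-to-surface is the
plausible alternative. Summaries per cell-type × fiber-class report
median, IQR and a Gaussian KDE with Silverman's rule-of-thumb bandwidth;
comparisons use the two-sided Mann–Whitney U.

## Orchestration and reproducibility

`run_pipeline()` executes the configured stage blocks in canonical order,
chaining outputs on disk and writing a JSON manifest (package and R
versions, stage seeds, cell counts). All randomness derives from the
single global seed through a fixed integer map, so a run is reproducible
from its config alone; unknown configuration keys are rejected by name.
Counts are genes × cells internally (MTX convention); exported tables are
cells-as-rows; coordinates are µm and times seconds throughout.

## Problem sizes and limitations

The test suite and acceptance script run on deliberately compact problems
chosen to estimate each quantity stably: 150–1500 cells and 300–2000 genes
for expression stages (recovery checks use 1500 cells, 3 classes,
log2FC = 2, 10 % doublets, 15 % contaminants over 5 seeds), 199
permutations × 200 interactions for calibration, 19-minute traces at
50 frames/s, and scenes of ~10 cells and ≤ 200 varicosities. These sizes
are the package's own verification conditions; the implementations
themselves are size-generic, with dense distance matrices being the main
scaling bound (kNN search is O(n²) memory, comfortable to ~10⁴ cells).

Known limitations: no ambient-RNA correction; Pearson residuals use a
fixed θ rather than learned regularization; centroid alignment does not
correct nonlinear batch effects; LR scoring omits cofactor modulation;
spike detection assumes fast-rising transients and Gaussian noise; 3D
analysis does not segment surfaces from images. These mirror the stated
scope of the procedures being re-implemented.
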