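---
title: "Methods: spatial analysis of glomerular crescent formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of glomerular crescent formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

glomscape analyses segmented-cell spatial transcriptomics of crescentic
glomerulonephritis (rapidly progressive GN): kidney tissue in which
parietal epithelial cells (PECs) proliferate into crescents inside
glomeruli, driven early by PDGF and later by TGF-β signalling, ending in
glomerulosclerosis. The package takes a per-cell coordinate table plus a
sparse cell-by-gene count matrix over a targeted panel (hundreds of genes,
a few tens of transcripts per cell) and produces:

1. cell types (regularized multinomial classifier transferred from a
   labelled reference),
2. spatial compartments — glomerular, periglomerular (a 100 µm ring) and
   tubulointerstitial — with individual glomeruli instanced as ROIs,
3. an ROI-level *crescent trajectory*: PC1 of normalized pseudo-bulk
   profiles, K-means stages, diffusion pseudotime, Jenks quadrants,
   correlation of patient-median PC1 with clinical covariates, and
   covariate-adjusted differential expression,
4. per-cell pathway scores (PDGF, TGF-β, fibrosis) and their quadratic
   trends along the trajectory,
5. a distance-truncated ligand–receptor communication model with a
   permutation null,
6. protein-image integration by in-polygon pixel summation (e.g. Ki-67
   positivity along the trajectory), and
7. pathway-coverage drug prioritization.

Because patient data cannot be shipped, a synthetic cohort generator with
complete ground truth is a first-class module; every downstream method is
validated by parameter recovery against that truth.

# The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the features of the real
tissue that the analysis relies on, and nothing more:

* **Geometry.** Glomeruli are non-overlapping discs (radius 90 ± 15 µm)
  in a square field (800 µm); the periglomerular niche is the exact
  100 µm annulus; everything else is tubulointerstitial. Discs make the
  100-µm compartment rule exactly checkable; real glomeruli are
  irregular, so boundary-shape effects are *not* probed by these tests.
* **Compositions.** Expected cell-type fractions per condition
  (control, SLE, ANCA-GN, anti-GBM) and compartment are anchored at the
  published medians for the anchored entries (glomerular podocyte
  30/25.9/25/23.8 %, PEC 6/8/15/15 %, mesangial 17.9/10.2/7.1/4.3 %,
  fibrotic-mesangial 1.6/2/6.4/8.8 %, macrophage 0.4/2/2/7.8 %;
  periglomerular T cells 1.1/2.5/4.8/7.4 %; tubulointerstitial T cells
  1.13/2.28/3.82/4.4 %); the remaining entries are plausible kidney
  compositions completing each simplex.
* **Latent severity.** Each glomerulus draws a severity s ∈ [0, 1] from a
  condition-specific Beta (control (1.2, 10), SLE (2, 5), ANCA-GN (4, 3),
  anti-GBM (6, 2)). Compositions shift linearly in the *deviation* of s
  from the condition median (PEC, macrophage and fibrotic-mesangial gain;
  podocyte, endothelial and mesangial loss; T-cell infiltration outside
  the tuft), so the condition-level medians stay at their configured
  values while severity drives within-condition heterogeneity. A
  Dirichlet jitter (concentration 600) adds between-ROI variance; the
  paper-scale datasets report only medians, so this concentration is a
  free realism parameter, not a fitted one.
* **Expression.** Negative-binomial counts (size 2) over a synthetic
  480-gene panel: four disjoint markers per type at mean 5.5 counts,
  background 0.025, giving ≈ 34 median transcripts/cell — the sparsity
  regime of real in-situ panels. Severity acts multiplicatively: a
  quadratic PDGF-response hump in PECs peaking at s = 0.5 (amplitude 3),
  a saturating TGF-β response (amplitude 3.5, half-point 0.3), a linear
  fibrosis programme in PECs (base 0.7, slope 5), a constitutive
  fibrosis programme in fibrotic-mesangial cells, and severity-scaled
  ligand production in sender types. Effect sizes were chosen once so the
  programmes are detectable at this depth; they are config-exposed.
* **Protein.** A Ki-67-like channel: PECs are positive with probability
  0.05 + 0.7·4s(1−s) (bright mode ≈ 3, background ≈ 0.5); cells are
  rendered as regular hexagons so in-polygon pixel sums have exact
  oracles.

What passing recovery tests **does not** show: robustness to segmentation
errors, transcript spillover between neighbouring cells, irregular niche
shapes, optical artifacts, or batch effects — the generator deliberately
omits all of these.

# Cell typing

Counts are normalized per cell to 1,000 and log(1+x)-transformed
(`normalize_log1p()`); pseudo-bulk ROI profiles use a 10,000 target. The
classifier is ridge-penalized multinomial logistic regression
(`glmnet::cv.glmnet`, 5-fold CV over a log-spaced penalty grid
10⁻²…10²), deterministic given the seed. The reference atlas carries 12
classes and **no** fibrotic-mesangial class: that state is defined
*downstream* by relabeling mesangial-labelled cells inside glomerular
domains whose fibrosis score exceeds the 90th percentile of control
glomerular mesangial cells (strict `>`; percentile configurable, and an
explicit threshold can be supplied for disease-only cohorts). Clusters
with median annotation confidence < 0.6 can be dropped with
`filter_low_confidence_clusters()` (strict `<`).

# Niche annotation

`annotate_spatial_domains()` follows the neighbourhood-PCA recipe: per
sample, a k = 15 spatial kNN graph, mean aggregation of each cell's own
plus neighbours' normalized expression, PCA to 20 components, and Leiden
modularity clustering (resolution 0.5) on a 15-NN graph in PC space.
Two numerical choices deserve comment:

* **Which clusters are glomerular.** Cluster-level podocyte-marker scores
  (PODXL/NPHS2/PTPRQ) are split into two classes by an exact 1-D
  natural-breaks cut (the Jenks engine with k = 2, equivalent to Otsu),
  with a goodness-of-variance guard (≥ 0.5). A mean-plus-one-SD rule is
  available as `rule = "mean_sd"`, but it degenerates whenever there are
  few clusters (with two clusters the threshold always exceeds the
  maximum), so the breaks rule is the default.
* **Boundary erosion.** Neighbourhood aggregation blurs the domain
  boundary outward by roughly one cell ring, which systematically
  contaminates the glomerular niche with periglomerular (tubule-rich)
  cells and biases its composition. The mask is therefore eroded by
  `boundary_erosion_um` (default 18 µm ≈ 0.7 × the aggregation radius at
  the default density; calibrated on synthetic tissue with known disc
  boundaries). Erosion is purely geometric — it removes a boundary shell
  whose type mix equals the local niche mix — so recovered compositions
  are unbiased, at the cost of slightly smaller instances.

Instancing is single-linkage clustering of masked cells (30 µm link,
≥ 15 cells, ids by decreasing size); compartments follow the
nearest-glomerular-cell rule with the 100 µm perimeter, ties to the lower
glomerulus id, never across samples or slides. Distances are between cell
centroids (polygons are optional inputs). The periglomerular distance is
measured from the detected glomerular *cell set*, not a fitted boundary
polygon — the source recipes leave this choice open, and the cell-set rule
needs no shape model.

# Trajectory

Raw counts of each ROI (glomerulus + ring) are summed, normalized to
10,000, log-transformed and decomposed by centered PCA. PC1's sign is
fixed so control ROIs sit low. K for K-means is the elbow (maximum
second difference of the *log* within-cluster sum of squares over
k = 2…10; the log scale keeps the large k = 1→2 drop from masking the true
elbow); clusters whose control fraction exceeds 0.6 are merged
("predominantly control" quantified), and clusters are renamed C1…Cn by
ascending median PC1. The final number of clusters is data-driven.

Diffusion pseudotime uses a 10-NN graph in 10-PC space with an adaptive
Gaussian kernel (bandwidth = distance to the 7th neighbour), the
symmetric normalized transition operator, and the standard
eigen-weighted diffusion distance from a root ROI, rescaled to [0, 1].
The root is a random *control* ROI; because a control ROI can
occasionally be mid-trajectory (severity is a distribution, not a
constant), the random draw is restricted to the half of control ROIs on
the control-typical pole of the first informative diffusion component —
without this guard the pseudotime folds around an atypical root.
Disconnected graph components are bridged through their closest node
pair with a negligible weight before the eigendecomposition.

Pseudotime quadrants are exact Jenks natural breaks (dynamic programming,
verified against exhaustive enumeration for n ≤ 25; affine-invariant).
Patient-median PC1 is correlated with eGFR, albuminuria, age and the
ordinal ANCA risk score (low/medium/high → 1/2/3) by Spearman's rho with
the two-sided t-approximation. Differential expression between C1 and
the remaining clusters is a per-gene linear model with slide indicators
as covariates (dropped with a warning when confounded), ordinary
two-sided t-tests and Benjamini–Hochberg adjustment; zero-variance genes
are flagged and excluded from the adjustment.

# Pathway scores and trends

`score_gene_set()` is the mean over present set genes of gene-wise
z-scored normalized expression; constant genes contribute zero. With a
targeted panel of a few hundred genes, expression-matched background
pools are too small for bin-matched scoring, so the z-mean is the
default (`method = "binned"` exists as the deviation knob). The fibrosis
set defaults to COL1A1/COL4A1/FN1/LUM/TIMP1 and is overridable, since no
canonical fibrosis set is fixed by the underlying analyses.
`trend_along_trajectory()` fits OLS of per-cell scores on
(1, PC1, PC1²) with an analytic pointwise 95 % band and reports the peak
−b/(2c) when curvature is negative.

# Spatial communication model

The communication module is an explicitly simplified, fully specified
stand-in for diffusion-based interaction tools: for each interaction and
ordered type pair, ligand and receptor summaries are 0.1-trimmed means
of log-normalized expression over the sender and receiver cells
(geometric mean across multi-subunit genes), spatial proximity is the
fraction of cell pairs within a hard range (250 µm secreted, 10 µm
contact), computed per slide and pooled by pair count, and the
probability is h(L)·h(R)·π with the Hill response h(u) = u/(0.5+u).
Hard truncation replaces diffusion weighting and the half-saturation 0.5
replaces a fitted response; both constants are config-exposed. Type
pairs with fewer than 10 cells score zero (stability guard). Slides are
laid out left-to-right with x-offsets of 10 × the interaction range so
cross-slide pairs can never interact. Significance is a within-slide
label permutation with the add-one estimator
p = (1 + #{perm ≥ obs})/(1 + B); differential networks difference the
aggregated significant weights (α = 0.05), and the incoming-signal table
lists significant edges into a target type (e.g. PEC) by probability.

# Protein integration

Pixels belong to a cell when their centers fall inside or on the
boundary of its polygon (even-odd ray casting with an explicit
on-boundary test); overlapping polygons count shared pixels for each
cell. Registration is assumed done; an optional affine transform is
accepted but never estimated. Positivity defaults to an Otsu split of
the target type's per-cell mean intensities — when the intensity
distribution has an empty gap between modes any threshold in the gap is
optimal, and the implementation returns one such maximizer — with a
fixed-quantile alternative, since no positivity criterion is canonical.
Per-ROI positive fractions are then fitted against PC1 with the
quadratic trend above.

# Drug prioritization

For drug d with targets T_d and pathway set G_p:
S_b = |T_d ∩ G_p| / |G_p| (coverage),
S_a = Σ_{g ∈ T_d ∩ G_p} w(a_{d,g}) with w = 1 for inhibitor/antagonist
actions and w = 0.5 for binder/activator/agonist (case-insensitive
substring match, overridable weight map; unlisted actions weigh 0 but
still count toward coverage), and
S_f = S_b × (1 + S_a / max(1, |T_d ∩ G_p|)).
Drugs with S_f below 0.1 are dropped; the rest are ranked by S_f with
ties broken by drug id. Duplicate (drug, gene) rows keep the
highest-weight action. The shipped drug table is a small synthetic
DrugBank-style fixture; the PDGF gene set includes the PDGF ligands and
both receptors.

# Problem sizes, determinism, degenerate inputs

The test suite and the acceptance script run cohorts of 10–40 samples
with ~4,600 cells per sample (40 ROIs per condition for composition
recovery, 80 ROIs for trajectory recovery) — large enough that median
compositions are stable to well under a percentage point while a full
run stays in the minutes range on one core. All randomness flows from a
single seed through a counter-based per-stage derivation
(`derive_seed()`), so adding a stage never perturbs earlier stages.
Degenerate inputs fail loudly with classed errors: all-zero pseudo-bulk
variance, fewer than four distinct pseudotime values, empty gene-set
overlap, no control root, impossible disc packings, and perimeter or
trim parameters outside their domains.

# Known limitations

* Disc-shaped glomeruli and exact annuli understate boundary complexity;
  the erosion calibration is tied to the default density and k.
* The communication model's hard range truncation and Hill response are
  simplifications; its probabilities are comparable within a run, not
  across tools.
* The classifier assumes the reference and target share the panel scale;
  no batch correction is attempted.
* Per-cell pathway scores at ~34 transcripts/cell are noisy; trends are
  reliable at the ROI level, not per cell.
* The drug fixture is synthetic; real DrugBank exports must be supplied
  by the user as CSV.
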