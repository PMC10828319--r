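---
title: "Methods: distribution shapes, networks and markers in senescence single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distribution shapes, networks and markers in senescence single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senkit)
```

`senkit` re-implements, as a tested pipeline, the bespoke computations of a
single-cell study of replicative senescence: hESC-derived mesenchymal stem
cell cultures sampled at three timepoints (T0/T1/T2, three biological
replicates each), profiled by droplet scRNA-seq and by high-content imaging
of nuclear senescence markers. This vignette explains each method, its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Quality control

**Cell calling.** Barcodes are ordered by library size; the reference level
is the `upper_quantile` (default 0.99, type-7 interpolation) of the top
`expected_cells` library sizes, and a barcode is called a cell when its
total exceeds `fraction` (default 0.10) of that reference. The quantile
convention is fixed to type 7 — the most common default — so worked
examples are exact; the inequality is strict. The caller assumes a
separable knee: real cells at depths well above the ambient tail.

**Gene filtering.** Genes detected (count > 0) in strictly less than
`min_cell_fraction` (default 10%) of all cells are removed; genes never
detected are always removed. Filtering is idempotent, and a report records
matrix dimensions before and after.

## Count-distribution shapes

The central idea is distribution-centric: rather than asking whether a
gene's mean shifts, each gene at each timepoint is assigned one of four
count families — Poisson (P), zero-inflated Poisson (ZIP), negative
binomial (NB, mean $\mu$ and size $\theta$ with variance
$\mu + \mu^2/\theta$) and zero-inflated negative binomial (ZINB) — and
genes are tracked for family *switches* across timepoints.

**Model.** Every family uses a log link on the mean with biological
replicate as a categorical covariate, i.e. a free mean per replicate
group; the zero-inflation $\pi$ (ZIP/ZINB) sits on the zero atom only and
is shared across replicates. Parameter counts are
$k = 1 + (R - 1)$ for P ($R$ replicates), plus one for $\theta$ or
$\pi$, plus two for ZINB, and $\mathrm{BIC} = k\ln n - 2\ln L$.

**Estimation.** For P and NB the group-mean MLE is the group sample mean
(the NB score in $\mu$ is a weighted sum of $y - \mu$), so only $\theta$
needs numerical work: a 1-D profile search over $\log\theta \in [-7, 12]$.
ZIP and ZINB use coordinate ascent: an EM step for the group means (and
$\theta$) given the posterior zero-atom memberships, then an exact 1-D
maximisation of the observed likelihood in $\pi$. Because the $\pi$ step
is exact and the EM steps are monotone, the inflated families can never
score below their non-inflated submodels (the package tests assert
$\ln L_{\mathrm{ZINB}} \ge \ln L_{\mathrm{NB}} - 10^{-4}$ and likewise for
ZIP vs P). Convergence is declared when $|\Delta \ln L| < 10^{-6}$ or
after 200 iterations. Likelihood evaluations run over tabulated
(value, multiplicity) pairs per replicate group, which keeps the
bootstrap affordable.

**Degeneracies.** All-zero genes cannot identify a finite log-mean (nor a
$\pi < 1$) and are flagged non-converged in every family. If the fitted
$\pi$ falls below $10^{-4}$ the inflated fit is collapsed onto the
non-inflated family (flagged `collapsed`); under BIC the non-inflated
family then wins the tie, which is the intended selection behaviour. A
fitted $\theta > 10^4$ sets a `poisson_limit` flag but keeps the family
label.

**Goodness of fit.** The KS statistic is
$D = \sup_t |\hat F_n(t) - F_{\hat\vartheta}(t)|$ where the fitted CDF is
pooled over the observed replicate mix. Because parameters are estimated,
the null distribution of $D$ is obtained by parametric bootstrap: `n_boot`
(default 100) datasets are simulated from the fitted model over the same
replicate design, refit (warm-started at the fitted parameters), and the
add-one p-value $(1 + \#\{D_b \ge D\})/(n_{\mathrm{boot}} + 1)$ is
returned. `n_boot < 19` is rejected: the p-value could not resolve the
default screening level. The screen is applied per (gene, timepoint,
family) without multiplicity correction; `alpha` is configurable
(default 0.05).

**Selection.** All four families are fitted; fits failing the KS screen or
non-converged are discarded, and the minimum-BIC survivor is selected,
with ties broken toward fewer parameters (P < ZIP = NB < ZINB). The
implementation screens candidates in ascending BIC order and stops at the
first survivor — mathematically the same rule, but only as many bootstrap
screens run as needed. If nothing survives the gene is `NONE` at that
timepoint.

**Switch categories.** A gene's (T0, T1, T2) family triple is classified
as `stable`, `single_transition` (exactly one consecutive change),
`reverting` (A→B→A), `distinct_triple` (all three differ), or
`unassigned` (any `NONE`). "Differentially distributed" genes — those
changing at *both* consecutive transitions — are the union of `reverting`
and `distinct_triple`; single transitions are reported separately. This
operationalisation was chosen because every reference census pattern
changes at both transitions and no single-transition pattern appears
there. The family census supports two percentage denominators (the
per-timepoint assigned count, or a fixed study-wide total) because
reference tables are printed against a fixed total; both are exposed and
the census never reconciles rounding in its inputs.

## PPI-constrained co-expression networks

Edges are Spearman correlations (average ranks for ties) computed across
cells for gene pairs *present in a reference PPI network*; pairs with
$|\rho|$ strictly above `rho_min` (default 0.5) are kept with their sign.
Constant genes have undefined correlations; their pairs are skipped with a
warning. P-values for $\rho$ are deliberately not computed — the
threshold is on magnitude alone. Cluster-specific networks pass the
cluster's marker genes as `gene_subset`; by default all genes present in
the PPI are in scope.

**MCODE.** Dense modules are found with a re-implementation of the MCODE
algorithm. The weight of a vertex is $k \times$ density of the highest
$k$-core of its closed neighbourhood. Expansion seeds at the
highest-weight unvisited vertex and includes neighbours whose weight is at
least $(1 - \mathrm{vwp})$ of the seed weight (defaults: vwp = 0.2,
haircut on, fluff off, 2-core filter — the documented defaults of the
original app). The haircut removes members with within-module degree < 2
in a single pass; modules lacking a 2-core are discarded; modules are
disjoint by visitation and ranked by density. Two numerical details are
fixed deliberately: seed and ranking ties break lexicographically by gene
id, and the weight-cutoff comparison uses a $10^{-9}$ tolerance so that
exact boundary weights are not lost to floating-point rounding. Edge
signs are ignored during detection (modules live on the thresholded
topology); signed counts are reported separately by the edge census.
The implementation is verified against an independent brute-force k-core
enumeration (exhaustive subset search) on hundreds of small random graphs.

**Degree distribution.** The power-law fit replicates the log–log
least-squares convention of network visualisation tools —
$\log_{10}(\mathrm{freq})$ on $\log_{10}(\mathrm{degree})$ over nonzero
bins, reporting $\gamma$ (negated slope) and $R^2$ — rather than a
maximum-likelihood tail fit, because that is the convention the reported
exponents come from. At least 3 distinct positive degrees are required.

## Imaging marker statistics

The pipeline order is fixed and enforced by convention: (1) IQR outlier
removal per marker **within each timepoint** — points outside
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ (type-7 quartiles)
are dropped; (2) max-scaling, dividing each marker by its maximum **across
all timepoints** (computed after outlier removal — scaling before removal
would let a single outlier set the denominator); (3) two-sided Wilcoxon
rank-sum tests between timepoints, exact for groups of ≤ 50 cells and a
tie-corrected normal approximation above that. Per-timepoint outlier
grouping was chosen over pooling because pooling would delete genuine
senescence shifts as "outliers". Positivity fractions (e.g. the share of
SA-β-gal–positive cells) use a user-supplied threshold, defaulting to the
99th percentile of T0 — a conservative "almost no positive cells at
baseline" convention. DNA-content subpopulations are exported as a
histogram only; no mixture model is fitted.

## Cells: normalization, markers, phases, lineage

**Normalization** is depth-relative log-normalization,
$\ln(1 + 10^4 \, c_{gj} / d_j)$. It stands in for the variance-stabilising
regression normalization used upstream in the original workflow, which is
out of scope here; it preserves the zero pattern and is scale-free in
depth.

**Marker ranking** is a one-vs-rest Wilcoxon rank-sum per gene with
$\mathrm{logFC} = \ln\frac{\mathrm{mean}(e^{x_{in}} - 1) + 1}
{\mathrm{mean}(e^{x_{out}} - 1) + 1}$ (natural log, pseudocount 1 on
de-logged means — the convention under which the 0.25 threshold is
quoted), Bonferroni correction over all genes tested, and retention at
$|\mathrm{logFC}| > 0.25$ and adjusted $p < 0.001$. The p-value uses a
tie-corrected normal approximation with continuity correction. The
one-vs-rest background defaults to *all* other cells (configurable by
subsetting the input), since the reference analysis does not state a
narrower background.

**Cell-cycle scores** follow the expression-matched control scheme: genes
are binned by average expression (24 bins), each phase-set gene draws
`n_ctrl` = 100 controls from its bin, and a cell's score is the mean of
the set genes minus the mean of the controls. Controls are drawn from
genes outside *both* phase sets, so one set never serves as background
for the other — with transcriptome-sized gene universes this is
immaterial, but it is the correct reading of "control genes". Phase is G1
when both scores are ≤ 0, otherwise the larger score wins. Gene sets are
user-supplied; nothing is hard-coded.

**PCA** is centred, unscaled, with 20 components by default (the depth
used upstream in the original workflow); component signs are fixed by
making each loading's largest-magnitude entry positive so embeddings are
reproducible across platforms.

**Lineage.** The trajectory is deliberately the *first stage* of
MST-based lineage inference: a Euclidean minimum spanning tree over
cluster centroids in PC space, rooted at a stated root cluster, with
lineages read as root-to-leaf paths. The principal-curve smoothing
iteration of full trajectory methods is intentionally omitted — the
topology-level claims (which cluster precedes which, where the
bifurcation sits) only require the MST stage. Per-cell pseudotime is the
arc length from the root centroid to the cell's orthogonal projection
onto the nearest tree segment incident to its cluster (projections clamp
to segment ends), so the root centroid sits at pseudotime 0 and centroid
pseudotimes increase along every lineage.

## The synthetic-data generator

Every pipeline input can be generated with a ground-truth record, making
the whole pipeline testable without external data. Design choices:

* **Counts** are drawn per gene from a planted family with multiplicative
  replicate effects on the mean (a log-link covariate, matching the
  fitting model). RNG is namespaced per gene, so adding genes never
  perturbs earlier genes' draws, and every generator is a pure function
  of (parameters, seed).
* **Droplets**: real and ambient barcodes draw Poisson totals around
  `real_depth` (default 1000) and `ambient_depth` (default 10) — a
  two-order-of-magnitude separation that yields a clean knee, matching
  the study design of ~10,000 targeted cells over an ambient tail.
* **Co-expression**: module genes share a latent Gaussian factor with
  loading 0.8 (within-module Spearman ≈ 0.62, comfortably above the 0.5
  edge threshold at n = 500 cells); the PPI is preferential-attachment
  (scale-free) over all genes plus every within-module pair.
* **Markers** are log-normal with per-timepoint location shifts; the
  default log-scale spread is 0.25, chosen so the 1.5×IQR rule's
  false-positive rate on clean log-normal data is ≈ 1.8% (< 2%, the rate
  the generator contract promises). Injected outliers sit above 10× the
  marker's 99th percentile and are flagged in the truth record.
* **Lineage**: cells are Gaussian-perturbed cluster centroids in
  log-mean space, exponentiated and Poisson-sampled, so downstream
  log-normalization approximately recovers the geometry. The test
  fixture's bifurcation has centroid separation roughly 12× the Gaussian
  noise (scale 1 vs `noise_sd` 0.08).

What the generator does **not** emulate: transcriptome-wide gene–gene
covariance, ambient-RNA chemistry, doublets, batch structure beyond a
multiplicative replicate effect, or variance-stabilised residual
structure. Passing tests therefore demonstrate correctness of the
*computations* under the stated models, not robustness to every artefact
of real droplet data.

## Problem sizes and tolerances

The test suite and the acceptance script use sizes chosen to give the
statistics room to separate while remaining quick on a laptop: family
identification uses 100 genes per family at n = 2000 cells (parameter
recovery at n = 5000); the MCODE oracle enumerates 500 random graphs of
up to 8 nodes (where exhaustive subset search is exact); droplet calling
uses 100 real + 1000 ambient barcodes; lineage recovery uses 100 seeds of
a 4-cluster bifurcation with 60 cells per cluster; the null
marker-ranking control uses 100 runs of 500 genes × 400 cells. Bootstrap
KS uses 100 replicates (p-resolution ≈ 0.01).

## Known limitations

* ZIP/ZINB assume a shared $\pi$ across replicates; replicate-specific
  inflation is not modelled.
* The KS screen is unadjusted for multiplicity across genes, families and
  timepoints (by design, matching the reference workflow's silence on
  correction); censuses should be read accordingly.
* The MST lineage has no uncertainty measure and no within-cluster
  ordering beyond segment projection.
* The log–log least-squares power-law fit is known to be biased relative
  to maximum-likelihood tail estimation; it is kept because comparability
  with the reported exponents matters more here than estimator
  efficiency.
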