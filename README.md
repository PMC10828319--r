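# senkit

Analyses for single-cell studies of **replicative senescence** in
mesenchymal stem cell (MSC) cultures sampled across a time course
(T0/T1/T2, three biological replicates), combining droplet scRNA-seq with
high-content imaging of nuclear senescence markers (p16, p21, BrdU,
SA-β-gal, DNA content). The package is aimed at computational biologists
who want the study's bespoke computations as tested, reusable functions —
with a synthetic-data module that generates every input with ground truth,
so the whole pipeline runs and is verifiable without any external data.

## What it computes

* **Distribution-shape model selection.** Each gene at each timepoint is
  fitted with four count families — Poisson (P), zero-inflated Poisson
  (ZIP), negative binomial (NB; mean μ, size θ, variance μ + μ²/θ) and
  zero-inflated negative binomial (ZINB) — as GLMs with a log link and
  biological replicate as a categorical covariate. Fits are screened by a
  parametric-bootstrap Kolmogorov–Smirnov test
  (p = (1 + #{D_b ≥ D}) / (n_boot + 1)) and the minimum-BIC survivor
  (BIC = k·ln n − 2·lnL) is selected. Genes are then classified by their
  (T0, T1, T2) family triple — stable, single transition, reverting
  (A→B→A), or distinct triple — and censused; "differentially
  distributed" genes change family at both consecutive transitions.
* **QC.** Droplet cell calling (a barcode is a cell when its library size
  exceeds 10% of the 0.99 quantile of the top expected barcodes) and gene
  filtering (genes detected in < 10% of cells are removed).
* **PPI-constrained co-expression networks.** Spearman ρ across cells for
  gene pairs present in a reference protein–protein interaction network;
  edges kept at |ρ| > 0.5 with their sign; dense modules via a
  re-implemented MCODE (k-core vertex weighting, seeded expansion, haircut,
  2-core filter), verified against brute-force k-core enumeration;
  log–log least-squares power-law degree fits; signed edge censuses and
  top-10 hub genes.
* **Imaging marker statistics.** 1.5×IQR outlier removal per marker per
  timepoint, max-scaling across timepoints, two-sided Wilcoxon rank-sum
  shift tests, positivity fractions and pairwise Spearman correlations.
* **Cells.** Depth-relative log-normalization, one-vs-rest Wilcoxon
  marker-gene ranking (|logFC| > 0.25, Bonferroni p < 0.001), cell-cycle
  phase scoring with expression-matched control genes, centred PCA, and a
  minimum-spanning-tree lineage over cluster centroids with per-cell
  pseudotime.

See `vignettes/senescence-pipeline.Rmd` for the models, assumptions,
parameter defaults and numerical choices.

## Worked example

A gene planted to switch family across the time course (P at T0, NB at
T1, ZINB at T2; 700 cells per timepoint × replicate):

```r
library(senkit)

sp  <- shape_spec("CDKN1A-like", c("P", "NB", "ZINB"),
                  mu = c(3, 6, 8), theta = c(NA, 0.6, 2),
                  pi = c(NA, NA, 0.4), cells_per_group = 700)
sim  <- gen_shape_counts(list(sp), seed = 1)
meta <- sim$matrix$cell_data

fams <- sapply(c("T0", "T1", "T2"), function(tp) {
  idx <- meta$timepoint == tp
  assign_shape(as.integer(sim$matrix$counts[1, idx]),
               meta$replicate[idx], seed = 1)$family
})
fams
#>     T0     T1     T2
#>    "P"   "NB" "ZINB"
classify_switch(fams[1], fams[2], fams[3])
#> [1] "distinct_triple"

fit_family(as.integer(sim$matrix$counts[1, meta$timepoint == "T2"]),
           meta$replicate[meta$timepoint == "T2"], "ZINB")
#> ShapeFit [ZINB]: logLik -5093.6790, k = 5, BIC 10225.6113
```

All three planted families are recovered, the triple is classified as a
distinct-triple switch (a "differentially distributed" gene), and the T2
fit returns π̂ = 0.395, μ̂ ≈ (8.42, 7.40, 7.98) across replicates and
θ̂ = 1.93 — close to the planted π = 0.4, μ = 8, θ = 2.

The numbered scripts under `analysis/` run the full workflow on simulated
data (`01_simulate.R` → `06_lineage.R`), writing tables under `results/`:
QC reports, shape and switch censuses, network modules and hubs, marker
shift tests and positive fractions, and the recovered lineage tree with
pseudotime.

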