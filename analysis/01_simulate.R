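#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# ground-truth records. All outputs land under results/simdata/.

suppressPackageStartupMessages(library(senkit))

seed <- 20230614
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## A panel of genes whose count family may switch across the three
## timepoints: stable Poisson/NB backbones plus planted reverting and
## distinct-triple switchers, all with mild replicate effects.
specs <- c(
  lapply(sprintf("stableP_%02d", 1:10), function(g) {
    shape_spec(g, c("P", "P", "P"), mu = c(2, 3, 2.5),
               rep_effect = c(1, 1.15, 0.9), cells_per_group = 300)
  }),
  lapply(sprintf("stableNB_%02d", 1:10), function(g) {
    shape_spec(g, c("NB", "NB", "NB"), mu = 5, theta = 0.6,
               rep_effect = c(1, 1.1, 0.95), cells_per_group = 300)
  }),
  lapply(sprintf("revert_%02d", 1:5), function(g) {
    shape_spec(g, c("P", "NB", "P"), mu = c(3, 5, 3),
               theta = c(NA, 0.5, NA), cells_per_group = 300)
  }),
  lapply(sprintf("triple_%02d", 1:5), function(g) {
    shape_spec(g, c("P", "NB", "ZINB"), mu = c(3, 6, 8),
               theta = c(NA, 0.6, 2), pi = c(NA, NA, 0.4),
               cells_per_group = 300)
  }))
shapes_sim <- gen_shape_counts(specs, seed = seed)
write_count_matrix(shapes_sim$matrix, file.path(out, "shape_counts"))
write_sim_truth(list(kind = "shape_counts", seed = seed,
                     genes = vapply(shapes_sim$truth$specs,
                                    function(s) s$gene, character(1))),
                file.path(out, "shape_truth.json"))
message("shape panel: ", nrow(shapes_sim$matrix$counts), " genes x ",
        ncol(shapes_sim$matrix$counts), " cells")

## Droplet profile: 100 real cells over an ambient tail.
drop <- gen_droplet_profile(100, 1000, real_depth = 1000,
                            ambient_depth = 10, seed = seed)
write.table(data.frame(barcode = names(drop$profile),
                       total_umi = drop$profile,
                       is_real = drop$truth$is_real),
            file.path(out, "droplet_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## PPI-constrained co-expression fixture with one planted 10-gene module.
ppx <- gen_ppi_expression(80, list(c(10, 0.8)), n_cells = 500,
                          seed = seed)
write.table(round(ppx$expr, 5), file.path(out, "ppi_expression.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write_ppi(ppx$ppi, file.path(out, "ppi_edges.tsv"))
write_sim_truth(list(kind = "ppi", seed = seed,
                     module_genes = names(ppx$truth$membership)[
                       !is.na(ppx$truth$membership)]),
                file.path(out, "ppi_truth.json"))

## Imaging marker intensities with senescence-like shifts and 2% outliers.
mk <- gen_marker_table(500, outlier_frac = 0.02, seed = seed)
write_marker_table(mk$table, file.path(out, "marker_intensities.csv"))
write_sim_truth(list(kind = "markers", seed = seed,
                     n_outliers = sum(mk$truth$outlier)),
                file.path(out, "marker_truth.json"))

## Lineage: a bifurcating 4-cluster trajectory (root A -> B -> {C, D}).
pos <- rbind(A = c(0, 0), B = c(1.2, 0), C = c(2.4, 1.8),
             D = c(2.4, -1.8))
dirs <- local({
  set.seed(99)
  d1 <- rnorm(50); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- rnorm(50); d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  list(d1 = d1, d2 = d2)
})
cen <- t(apply(pos, 1, function(p) 1.5 + p[1] * dirs$d1 + p[2] * dirs$d2))
tree <- list(centroids = cen,
             edges = data.frame(parent = c("A", "B", "B"),
                                child = c("B", "C", "D")),
             root = "A")
lin <- gen_lineage_counts(tree, 60, 0.08, seed = seed)
write_count_matrix(lin$matrix, file.path(out, "lineage_counts"))
write_sim_truth(lin$truth, file.path(out, "lineage_truth.json"))

message("simulated inputs written to ", out)
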