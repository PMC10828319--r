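#!/usr/bin/env Rscript
# Imaging marker statistics: IQR outlier removal per marker within each
# timepoint, max-scaling, Wilcoxon shift tests, SA-beta-gal positive
# fractions and pairwise marker correlations.

suppressPackageStartupMessages(library(senkit))

out <- "results/markers"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_marker_table("results/simdata/marker_intensities.csv")

keep <- rep(TRUE, nrow(tab))
for (mk in unique(tab$marker)) {
  for (tp in unique(tab$timepoint)) {
    idx <- which(tab$marker == mk & tab$timepoint == tp)
    keep[idx] <- !iqr_filter(tab$intensity[idx])$outlier
  }
}
message(sprintf("IQR filter removed %d of %d points", sum(!keep), length(keep)))
scaled <- max_scale(tab[keep, ])

tests <- do.call(rbind, lapply(unique(scaled$marker), function(mk) {
  do.call(rbind, lapply(list(c("T0", "T1"), c("T1", "T2"), c("T0", "T2")),
                        function(pair) {
    r <- marker_shift_test(scaled, mk, pair[1], pair[2])
    data.frame(marker = mk, from = pair[1], to = pair[2],
               W = r$statistic, p = r$p_value)
  }))
}))
write.table(tests, file.path(out, "shift_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d marker shifts significant at p < 0.05",
                sum(tests$p < 0.05), nrow(tests)))

# positivity threshold: 99th percentile of T0 values per marker
sab <- scaled[scaled$marker == "SAbGal", ]
thr <- quantile(sab$intensity[sab$timepoint == "T0"], 0.99, names = FALSE)
pos <- vapply(c("T0", "T1", "T2"), function(tp) {
  positive_fraction(sab$intensity[sab$timepoint == tp], thr)
}, numeric(1))
write.table(data.frame(timepoint = names(pos), positive_pct = pos),
            file.path(out, "sabgal_positive.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("SA-b-gal positive fractions: T0 %.1f%%, T1 %.1f%%, T2 %.1f%%",
                pos[1], pos[2], pos[3]))

for (tp in c("T0", "T2")) {
  rho <- suppressWarnings(marker_correlations(scaled, tp))
  write.table(round(rho, 3),
              file.path(out, sprintf("marker_correlations_%s.tsv", tp)),
              sep = "\t", quote = FALSE, col.names = NA)
}
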