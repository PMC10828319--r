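Package: senkit
Title: Distribution-Shape, Network and Marker Analyses for Replicative
    Senescence Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used
    to characterise replicative senescence in hESC-derived mesenchymal
    stem cells at single-cell resolution: droplet barcode calling and gene
    filtering, per-gene count-distribution model selection among Poisson,
    zero-inflated Poisson, negative binomial and zero-inflated negative
    binomial families with a parametric-bootstrap Kolmogorov-Smirnov
    screen and cross-timepoint switching censuses, PPI-constrained signed
    Spearman co-expression networks with MCODE dense-module detection and
    power-law degree fits, single-cell imaging marker-intensity statistics
    (IQR outlier removal, max-scaling, Wilcoxon shift tests), Wilcoxon
    marker-gene ranking, cell-cycle phase scoring, and a minimum-spanning
    tree cluster lineage with per-cell pseudotime. A synthetic-data module
    generates every input with ground-truth records so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
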