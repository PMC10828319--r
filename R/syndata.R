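#' Specify a gene's per-timepoint count distribution
#'
#' A `ShapeSpec` plants, for one gene, the count family and parameters at
#' each timepoint. Families follow the four options used throughout the
#' package: Poisson (`P`), zero-inflated Poisson (`ZIP`), negative binomial
#' (`NB`, mean/size parameterisation with variance `mu + mu^2/theta`) and
#' zero-inflated negative binomial (`ZINB`). Zero inflation `pi` puts extra
#' mass on the zero atom only.
#'
#' @param gene gene id.
#' @param family character vector, one family per timepoint.
#' @param mu per-timepoint mean of the count component (counts, >= 0).
#' @param theta per-timepoint NB size (> 0); `NA` for P/ZIP.
#' @param pi per-timepoint zero-inflation in `[0, 1)`; `NA` for P/NB.
#' @param rep_effect multiplicative replicate effects on `mu` (one per
#'   replicate; acts like a log-link categorical covariate).
#' @param cells_per_group cells per timepoint x replicate combination.
#' @return a `ShapeSpec` list.
#' @export
shape_spec <- function(gene, family, mu, theta = NA_real_, pi = NA_real_,
                       rep_effect = 1, cells_per_group = 100) {
  n_tp <- length(family)
  mu <- rep_len(mu, n_tp)
  theta <- rep_len(theta, n_tp)
  pi <- rep_len(pi, n_tp)
  if (!all(family %in% c("P", "ZIP", "NB", "ZINB"))) {
    stop("family must be one of P, ZIP, NB, ZINB")
  }
  if (any(mu < 0)) stop("mu must be >= 0")
  needs_theta <- family %in% c("NB", "ZINB")
  needs_pi <- family %in% c("ZIP", "ZINB")
  if (any(!is.na(theta) & !needs_theta)) stop("theta given for P/ZIP family")
  if (any(!is.na(pi) & !needs_pi)) stop("pi given for P/NB family")
  if (any(needs_theta & (is.na(theta) | theta <= 0))) {
    stop("NB/ZINB require theta > 0")
  }
  if (any(needs_pi & (is.na(pi) | pi < 0 | pi >= 1))) {
    stop("ZIP/ZINB require pi in [0, 1)")
  }
  if (any(rep_effect <= 0)) stop("rep_effect must be positive")
  structure(list(gene = as.character(gene), family = family, mu = mu,
                 theta = theta, pi = pi, rep_effect = rep_effect,
                 cells_per_group = as.integer(cells_per_group)),
            class = "ShapeSpec")
}

# One draw of n counts from a (possibly zero-inflated) count family.
r_family <- function(n, family, mu, theta = NA, pi = NA) {
  y <- switch(family,
    P    = rpois(n, mu),
    NB   = rnbinom(n, size = theta, mu = mu),
    ZIP  = rpois(n, mu),
    ZINB = rnbinom(n, size = theta, mu = mu),
    stop("invalid family name: ", family)
  )
  if (family %in% c("ZIP", "ZINB")) {
    y[rbinom(n, 1L, pi) == 1L] <- 0L
  }
  as.integer(y)
}

#' Generate per-gene counts from planted count families
#'
#' Draws each gene's counts from its planted family with replicate-specific
#' means (multiplicative replicate effects, emulating a log-link categorical
#' covariate), across `T0..T(k-1)` timepoints and `R1..Rk` replicates. RNG
#' is namespaced per gene, so adding genes never perturbs earlier genes'
#' draws.
#'
#' @param specs list of [shape_spec()] objects (>= 1).
#' @param seed integer seed.
#' @param timepoints,replicates label vectors; lengths set the design.
#' @return list with `matrix` (a [CountMatrix]) and `truth` (planted specs
#'   and the seed).
#' @export
gen_shape_counts <- function(specs, seed,
                             timepoints = c("T0", "T1", "T2"),
                             replicates = c("R1", "R2", "R3")) {
  if (inherits(specs, "ShapeSpec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  n_tp <- length(timepoints)
  n_rep <- length(replicates)
  recycle <- function(x, n, what) {
    if (length(x) == n) return(x)
    if (length(x) == 1) return(rep(x, n))
    stop("spec/", what, " length mismatch")
  }
  specs <- lapply(specs, function(s) {
    s$family <- recycle(s$family, n_tp, "timepoint")
    s$mu <- recycle(s$mu, n_tp, "timepoint")
    s$theta <- recycle(s$theta, n_tp, "timepoint")
    s$pi <- recycle(s$pi, n_tp, "timepoint")
    s$rep_effect <- recycle(s$rep_effect, n_rep, "replicate")
    if (s$cells_per_group < 1) stop("cells per timepoint x replicate >= 1")
    s
  })
  n_per <- vapply(specs, function(s) s$cells_per_group, integer(1))
  if (length(unique(n_per)) != 1) {
    stop("all specs must share cells_per_group")
  }
  nc <- n_per[1] * n_tp * n_rep
  tp_lab <- rep(timepoints, each = n_per[1] * n_rep)
  rep_lab <- rep(rep(replicates, each = n_per[1]), times = n_tp)
  counts <- matrix(0L, nrow = length(specs), ncol = nc)
  for (g in seq_along(specs)) {
    s <- specs[[g]]
    counts[g, ] <- with_seed(sub_seed(seed, g), {
      unlist(lapply(seq_len(n_tp), function(t) {
        unlist(lapply(seq_len(n_rep), function(r) {
          r_family(n_per[1], s$family[t], s$mu[t] * s$rep_effect[r],
                   s$theta[t], s$pi[t])
        }))
      }))
    })
  }
  rownames(counts) <- vapply(specs, function(s) s$gene, character(1))
  colnames(counts) <- sprintf("cell_%05d", seq_len(nc))
  cm <- CountMatrix(counts,
                    data.frame(barcode = colnames(counts),
                               timepoint = tp_lab, replicate = rep_lab,
                               stringsAsFactors = FALSE))
  list(matrix = cm,
       truth = list(kind = "shape_counts", specs = specs, seed = seed))
}

#' Generate a droplet barcode profile with an ambient tail
#'
#' Real barcodes draw library sizes around `real_depth`, ambient droplets
#' around `ambient_depth` (Poisson totals). Depths must be well separated
#' for the downstream caller to find a knee.
#'
#' @param n_real,n_ambient numbers of real / ambient barcodes.
#' @param real_depth,ambient_depth positive mean total UMI per barcode.
#' @param seed integer seed.
#' @return list with `profile` (named integer vector of total UMI per
#'   barcode) and `truth` (logical `is_real` per barcode, and the seed).
#' @export
gen_droplet_profile <- function(n_real, n_ambient, real_depth = 1000,
                                ambient_depth = 10, seed = 1) {
  if (real_depth <= 0 || ambient_depth <= 0) stop("depths must be positive")
  stopifnot(n_real >= 1, n_ambient >= 0)
  with_seed(seed, {
    totals <- c(rpois(n_real, real_depth), rpois(n_ambient, ambient_depth))
    is_real <- c(rep(TRUE, n_real), rep(FALSE, n_ambient))
    bases <- c("A", "C", "G", "T")
    bc <- vapply(seq_along(totals), function(i) {
      paste(sample(bases, 12, replace = TRUE), collapse = "")
    }, character(1))
    bc <- make.unique(bc, sep = "-")
    names(totals) <- bc
    list(profile = totals,
         truth = list(kind = "droplets", is_real = setNames(is_real, bc),
                      seed = seed))
  })
}

#' Generate expression with planted co-expression modules and a PPI
#'
#' Genes in a planted module share a latent Gaussian factor (loading
#' `a`, residual sd `sqrt(1 - a^2)`), so within-module pairs are strongly
#' rank-correlated; background genes are independent N(0,1). The PPI is a
#' preferential-attachment (scale-free) graph over all genes, augmented
#' with every within-module pair.
#'
#' @param n_genes total genes.
#' @param planted_modules list of `c(size, loading)` pairs; sizes must sum
#'   to at most `n_genes` and each be >= 2.
#' @param n_cells cells (columns).
#' @param seed integer seed.
#' @param pa_m edges added per vertex in the preferential-attachment graph.
#' @return list with `expr` (genes x cells matrix), `ppi` (edge
#'   `data.frame`), `truth` (module membership per gene, seed).
#' @export
gen_ppi_expression <- function(n_genes, planted_modules, n_cells, seed,
                               pa_m = 2) {
  sizes <- vapply(planted_modules, function(m) as.integer(m[1]), integer(1))
  loadings <- vapply(planted_modules, function(m) as.numeric(m[2]), numeric(1))
  if (any(sizes < 2)) stop("module size must be >= 2")
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    expr <- matrix(rnorm(n_genes * n_cells), nrow = n_genes,
                   dimnames = list(genes, sprintf("cell_%04d", seq_len(n_cells))))
    membership <- rep(NA_integer_, n_genes)
    offset <- 0L
    for (m in seq_along(sizes)) {
      idx <- offset + seq_len(sizes[m])
      membership[idx] <- m
      f <- rnorm(n_cells)
      a <- loadings[m]
      expr[idx, ] <- a * matrix(f, nrow = sizes[m], ncol = n_cells,
                                byrow = TRUE) +
        sqrt(1 - a^2) * matrix(rnorm(sizes[m] * n_cells), nrow = sizes[m])
      offset <- offset + sizes[m]
    }
    g <- igraph::sample_pa(n_genes, m = pa_m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    ppi <- data.frame(gene_a = genes[el[, 1]], gene_b = genes[el[, 2]],
                      stringsAsFactors = FALSE)
    for (m in seq_along(sizes)) {
      idx <- which(membership == m)
      pairs <- t(utils::combn(genes[idx], 2))
      ppi <- rbind(ppi, data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                                   stringsAsFactors = FALSE))
    }
    key <- ifelse(ppi$gene_a < ppi$gene_b,
                  paste(ppi$gene_a, ppi$gene_b),
                  paste(ppi$gene_b, ppi$gene_a))
    ppi <- ppi[!duplicated(key) & ppi$gene_a != ppi$gene_b, ]
    rownames(ppi) <- NULL
    list(expr = expr, ppi = ppi,
         truth = list(kind = "ppi_expression",
                      membership = setNames(membership, genes), seed = seed))
  })
}

#' Generate a per-cell imaging marker intensity table
#'
#' Intensities are log-normal per marker per timepoint, with planted
#' location shifts (on the log scale) and optional injected outliers at
#' more than 10x the marker's 99th percentile.
#'
#' @param n_cells_per_timepoint cells imaged per timepoint.
#' @param marker_shifts named list: marker -> numeric vector of per-
#'   timepoint log-scale locations (>= 0).
#' @param outlier_frac fraction of points per marker replaced by outliers,
#'   in `[0, 0.2]`.
#' @param seed integer seed.
#' @param sdlog log-scale spread of the clean intensities.
#' @param timepoints timepoint labels.
#' @return list with `table` (long `data.frame`: cell_id, timepoint,
#'   marker, intensity) and `truth` (outlier flags per row, shifts, seed).
#' @export
gen_marker_table <- function(n_cells_per_timepoint,
                             marker_shifts = list(
                               p16 = c(0, 0.5, 1.2),
                               p21 = c(0, 1.0, 1.0),
                               BrdU = c(1.0, 0.5, 0.1),
                               SAbGal = c(0, 1.0, 2.0),
                               DNA = c(1.0, 1.0, 1.1)),
                             outlier_frac = 0, seed = 1, sdlog = 0.25,
                             timepoints = c("T0", "T1", "T2")) {
  if (outlier_frac < 0 || outlier_frac > 0.2) {
    stop("outlier_frac must be in [0, 0.2]")
  }
  if (any(unlist(marker_shifts) < 0)) stop("shift locations must be >= 0")
  n_tp <- length(timepoints)
  with_seed(seed, {
    rows <- list()
    flags <- list()
    for (mk in names(marker_shifts)) {
      loc <- rep_len(marker_shifts[[mk]], n_tp)
      vals <- unlist(lapply(seq_len(n_tp), function(t) {
        rlnorm(n_cells_per_timepoint, meanlog = loc[t], sdlog = sdlog)
      }))
      out_flag <- rep(FALSE, length(vals))
      if (outlier_frac > 0) {
        n_out <- round(outlier_frac * length(vals))
        if (n_out > 0) {
          idx <- sample.int(length(vals), n_out)
          q99 <- quantile(vals, 0.99, type = 7, names = FALSE)
          vals[idx] <- 10 * q99 * runif(n_out, 1.05, 2)
          out_flag[idx] <- TRUE
        }
      }
      rows[[mk]] <- data.frame(
        cell_id = sprintf("cell_%s_%04d", rep(timepoints, each = n_cells_per_timepoint),
                          rep(seq_len(n_cells_per_timepoint), n_tp)),
        timepoint = rep(timepoints, each = n_cells_per_timepoint),
        marker = mk, intensity = vals, stringsAsFactors = FALSE)
      flags[[mk]] <- out_flag
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(kind = "markers", outlier = unlist(flags, use.names = FALSE),
                      shifts = marker_shifts, seed = seed))
  })
}

#' Generate counts for cells arranged along a cluster tree
#'
#' Each cell is its cluster centroid (log-scale coordinates) plus Gaussian
#' noise; coordinates are exponentiated and Poisson-sampled into counts, so
#' downstream log-normalization approximately recovers the geometry.
#'
#' @param cluster_tree list with `centroids` (clusters x genes numeric
#'   matrix with cluster rownames; log-mean expression), `edges`
#'   (`data.frame` with `parent`, `child` cluster ids) and `root`.
#' @param cells_per_cluster cells per cluster.
#' @param noise_sd Gaussian sd around the centroid (log scale).
#' @param seed integer seed.
#' @return list with `matrix` (a [CountMatrix] with cluster labels) and
#'   `truth` (topology, root, seed).
#' @export
gen_lineage_counts <- function(cluster_tree, cells_per_cluster, noise_sd,
                               seed) {
  cen <- cluster_tree$centroids
  if (nrow(cen) < 2) stop("need >= 2 clusters")
  if (anyDuplicated(apply(cen, 1, paste, collapse = ","))) {
    stop("duplicate centroids")
  }
  clusters <- rownames(cen)
  n_genes <- ncol(cen)
  genes <- if (!is.null(colnames(cen))) colnames(cen) else
    sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    mats <- lapply(seq_len(nrow(cen)), function(k) {
      z <- matrix(rnorm(cells_per_cluster * n_genes, sd = noise_sd),
                  nrow = cells_per_cluster)
      lam <- exp(sweep(z, 2, cen[k, ], "+"))
      matrix(rpois(length(lam), lam), nrow = cells_per_cluster)
    })
    counts <- t(do.call(rbind, mats))
    rownames(counts) <- genes
    colnames(counts) <- sprintf("cell_%05d", seq_len(ncol(counts)))
    meta <- data.frame(barcode = colnames(counts),
                       cluster = rep(clusters, each = cells_per_cluster),
                       stringsAsFactors = FALSE)
    cm <- CountMatrix(counts, meta)
    list(matrix = cm,
         truth = list(kind = "lineage", edges = cluster_tree$edges,
                      root = cluster_tree$root, seed = seed))
  })
}

#' Write a SimTruth record as JSON
#'
#' @param truth a truth list as returned by the generators.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
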