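#' Depth-relative log-normalization
#'
#' `value = ln(1 + count * scale / depth)` with `depth` the cell's total
#' UMI count. Zero counts map to zero; doubling every count in a cell
#' leaves its values unchanged.
#'
#' @param counts a [CountMatrix].
#' @param scale size factor target (default 1e4).
#' @return genes x cells dense numeric matrix, with the cell annotations
#'   attached as attribute `cell_data`.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  stopifnot(inherits(counts, "CountMatrix"))
  depth <- Matrix::colSums(counts$counts)
  if (any(depth == 0)) stop("zero-depth cell")
  norm <- log1p(as.matrix(counts$counts) %*%
                  Matrix::Diagonal(x = scale / depth))
  norm <- as.matrix(norm)
  dimnames(norm) <- dimnames(counts$counts)
  attr(norm, "cell_data") <- counts$cell_data
  norm
}

# Vectorised two-sided rank-sum p-values, normal approximation with tie
# correction and continuity correction, one gene per row.
ranksum_rows <- function(norm, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  apply(norm, 1, function(x) {
    r <- rank(x)
    u <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u - n1 * n2 / 2)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  })
}

#' Rank marker genes for a group by Wilcoxon one-vs-rest
#'
#' For each gene, a two-sided Wilcoxon rank-sum test of the group's cells
#' against all other cells, with
#' `logFC = ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`
#' (natural log, pseudocount 1 on de-logged means). P-values are
#' Bonferroni-adjusted over all genes tested; records are kept when
#' `|logFC| > logfc_min` and adjusted p < `padj_max`, sorted by `|logFC|`.
#'
#' @param norm normalized matrix from [lognormalize()].
#' @param labels group label per cell.
#' @param group the group to contrast against the rest.
#' @param logfc_min log fold-change threshold (default 0.25).
#' @param padj_max Bonferroni-adjusted p threshold (default 0.001).
#' @return `data.frame` with `gene`, `group`, `avg_logFC`, `p`, `p_adj`,
#'   `direction`; attribute `n_up` / `n_down` record the up/down split.
#' @export
rank_markers <- function(norm, labels, group, logfc_min = 0.25,
                         padj_max = 0.001) {
  labels <- as.character(labels)
  if (!group %in% labels) stop("group not present in labels")
  in_group <- labels == group
  if (sum(in_group) < 3 || sum(!in_group) < 3) {
    stop("need >= 3 cells per side")
  }
  mean_in <- rowMeans(expm1(norm[, in_group, drop = FALSE]))
  mean_out <- rowMeans(expm1(norm[, !in_group, drop = FALSE]))
  logfc <- log((mean_in + 1) / (mean_out + 1))
  p <- ranksum_rows(norm, in_group)
  p_adj <- pmin(1, p * nrow(norm))
  keep <- abs(logfc) > logfc_min & p_adj < padj_max
  out <- data.frame(gene = rownames(norm)[keep],
                    group = rep(group, sum(keep)),
                    avg_logFC = logfc[keep], p = p[keep],
                    p_adj = p_adj[keep],
                    direction = ifelse(logfc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$avg_logFC)), ]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  out
}

#' Cell-cycle phase scores from expression-matched control genes
#'
#' Genes are binned by average expression into `n_bins` bins; for each
#' gene of a phase set, `n_ctrl` control genes are drawn from its bin. The
#' phase score of a cell is the mean expression of the set genes minus the
#' mean over the drawn control genes. A cell is `G1` when both the S and
#' G2M scores are <= 0, otherwise the phase with the larger score.
#'
#' @param norm normalized matrix from [lognormalize()].
#' @param s_genes,g2m_genes character vectors of phase marker genes.
#' @param n_bins expression bins (default 24, capped at the gene count).
#' @param n_ctrl control genes per set gene (default 100).
#' @param seed integer seed for the control draws.
#' @return `data.frame` with `cell`, `s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_scores <- function(norm, s_genes, g2m_genes, n_bins = 24,
                              n_ctrl = 100, seed = 1) {
  if (!length(s_genes) || !length(g2m_genes)) stop("empty gene list")
  s_genes <- intersect(s_genes, rownames(norm))
  g2m_genes <- intersect(g2m_genes, rownames(norm))
  if (!length(s_genes) || !length(g2m_genes)) {
    stop("gene list has no overlap with the matrix")
  }
  avg <- rowMeans(norm)
  n_bins <- min(n_bins, nrow(norm))
  bin <- as.integer(cut(rank(avg, ties.method = "first"), breaks = n_bins))
  names(bin) <- rownames(norm)
  # controls come from genes outside both phase sets, so one set never
  # serves as "background" for the other
  excl <- union(s_genes, g2m_genes)
  score_set <- function(set, sub_seed_offset) {
    ctrl <- with_seed(sub_seed(seed, sub_seed_offset), {
      unlist(lapply(set, function(g) {
        pool <- setdiff(names(bin)[bin == bin[g]], excl)
        if (!length(pool)) pool <- setdiff(names(bin), excl)
        sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
      }))
    })
    colMeans(norm[set, , drop = FALSE]) -
      colMeans(norm[ctrl, , drop = FALSE])
  }
  s_score <- score_set(s_genes, 1L)
  g2m_score <- score_set(g2m_genes, 2L)
  phase <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                  ifelse(s_score > g2m_score, "S", "G2M"))
  data.frame(cell = colnames(norm), s_score = unname(s_score),
             g2m_score = unname(g2m_score), phase = unname(phase),
             stringsAsFactors = FALSE)
}

#' Centred PCA embedding of cells
#'
#' Principal components of the cells x genes matrix (centred, unscaled).
#' Component signs are fixed by making each loading vector's
#' largest-magnitude entry positive, so embeddings are reproducible.
#'
#' @param norm normalized matrix from [lognormalize()] (genes x cells).
#' @param n_pcs components to keep (default 20); must not exceed the
#'   numerical rank of the centred matrix.
#' @return list with `embedding` (cells x n_pcs scores), `loadings`,
#'   `sdev` (all components) and `var_explained` (fraction per kept PC).
#' @export
pca_embed <- function(norm, n_pcs = 20) {
  x <- t(as.matrix(norm))
  if (n_pcs > min(dim(x))) stop("n_pcs exceeds min(genes, cells)")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-8)
  if (n_pcs > rank) stop("n_pcs exceeds the rank of the data")
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- pr$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  emb <- sweep(pr$x[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pr$rotation[, seq_len(n_pcs), drop = FALSE], 2, flip,
                    "*")
  list(embedding = emb, loadings = loadings, sdev = pr$sdev,
       var_explained = pr$sdev[seq_len(n_pcs)]^2 / sum(pr$sdev^2))
}

#' Minimum-spanning-tree cluster lineage with per-cell pseudotime
#'
#' Builds the Euclidean MST over cluster centroids in the embedding,
#' roots it at `root`, and reads lineages as root-to-leaf paths. A cell's
#' pseudotime is the arc length from the root centroid to the cell's
#' orthogonal projection onto the nearest tree segment incident to its
#' cluster (projections clamp to the segment ends), so the root centroid
#' sits at pseudotime 0 and centroid pseudotimes increase along every
#' lineage.
#'
#' @param embedding cells x dims matrix (e.g. from [pca_embed()]).
#' @param labels cluster label per cell.
#' @param root the root cluster id.
#' @return a `LineageTree`: list with `centroids`, `edges` (`from`, `to`,
#'   `length`; `from` is the parent), `root`, `lineages` (list of cluster
#'   paths), `cluster_pseudotime`, `pseudotime` (per cell, input order).
#' @export
mst_lineage <- function(embedding, labels, root) {
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  if (!root %in% clusters) stop("unknown root: ", root)
  if (nrow(embedding) < 2) stop("singleton embedding")
  cen <- do.call(rbind, lapply(clusters, function(k) {
    colMeans(embedding[labels == k, , drop = FALSE])
  }))
  rownames(cen) <- clusters
  d <- as.matrix(dist(cen))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  el <- igraph::as_edgelist(tree)
  # Root the tree by BFS.
  adj <- lapply(setNames(clusters, clusters), function(k) {
    c(el[el[, 1] == k, 2], el[el[, 2] == k, 1])
  })
  parent <- setNames(rep(NA_character_, length(clusters)), clusters)
  node_pt <- setNames(rep(NA_real_, length(clusters)), clusters)
  node_pt[root] <- 0
  queue <- root
  order_visited <- character(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order_visited <- c(order_visited, v)
    for (u in adj[[v]]) {
      if (!is.na(node_pt[u]) || u == root) next
      parent[u] <- v
      node_pt[u] <- node_pt[v] + d[v, u]
      queue <- c(queue, u)
    }
  }
  edges <- data.frame(from = parent[!is.na(parent)],
                      to = names(parent)[!is.na(parent)],
                      stringsAsFactors = FALSE, row.names = NULL)
  edges$length <- d[cbind(edges$from, edges$to)]
  leaves <- setdiff(clusters[vapply(adj, length, numeric(1)) == 1], root)
  lineages <- lapply(leaves, function(lf) {
    path <- lf
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  })
  # Per-cell pseudotime: project onto the incident segment that the cell
  # is closest to.
  pt <- numeric(nrow(embedding))
  for (i in seq_len(nrow(embedding))) {
    k <- labels[i]
    segs <- rbind(edges[edges$from == k, c("from", "to")],
                  edges[edges$to == k, c("from", "to")])
    best_d <- Inf
    best_pt <- node_pt[k]
    for (s in seq_len(nrow(segs))) {
      a <- segs$from[s]  # parent end: closer to the root
      b <- segs$to[s]
      va <- cen[a, ]
      u <- cen[b, ] - va
      len <- sqrt(sum(u^2))
      tproj <- min(max(sum((embedding[i, ] - va) * u) / len, 0), len)
      proj <- va + u * tproj / len
      dd <- sqrt(sum((embedding[i, ] - proj)^2))
      if (dd < best_d) {
        best_d <- dd
        best_pt <- node_pt[a] + tproj
      }
    }
    pt[i] <- best_pt
  }
  structure(list(centroids = cen, edges = edges, root = root,
                 lineages = lineages, cluster_pseudotime = node_pt,
                 pseudotime = pt), class = "LineageTree")
}

#' Write a LineageTree as JSON
#'
#' @param tree a `LineageTree`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(tree, path) {
  jsonlite::write_json(
    list(root = tree$root, edges = tree$edges,
         lineages = lapply(tree$lineages, identity),
         cluster_pseudotime = as.list(tree$cluster_pseudotime),
         pseudotime = tree$pseudotime),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
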