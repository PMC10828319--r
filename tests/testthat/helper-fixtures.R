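# Shared fixtures and independent brute-force oracles.

# Embed low-dimensional cluster positions into gene space along two fixed
# orthonormal directions, on top of a constant baseline log-mean.
make_trajectory_centroids <- function(pos, n_genes = 50, base = 1.5,
                                      scale = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(99)
  d1 <- rnorm(n_genes)
  d1 <- d1 / sqrt(sum(d1^2))
  d2 <- rnorm(n_genes)
  d2 <- d2 - sum(d2 * d1) * d1
  d2 <- d2 / sqrt(sum(d2^2))
  t(apply(pos, 1, function(p) base + scale * (p[1] * d1 + p[2] * d2)))
}

chain_tree <- function() {
  pos <- rbind(A = c(0, 0), B = c(1, 0), C = c(2, 0))
  list(centroids = make_trajectory_centroids(pos),
       edges = data.frame(parent = c("A", "B"), child = c("B", "C")),
       root = "A")
}

bifurcation_tree <- function() {
  pos <- rbind(A = c(0, 0), B = c(1.2, 0), C = c(2.4, 1.8),
               D = c(2.4, -1.8))
  list(centroids = make_trajectory_centroids(pos),
       edges = data.frame(parent = c("A", "B", "B"),
                          child = c("B", "C", "D")),
       root = "A")
}

# Canonical undirected edge key of a tree, for topology comparison.
tree_key <- function(edges) {
  paste(sort(paste(pmin(edges$from, edges$to),
                   pmax(edges$from, edges$to))), collapse = ";")
}

recover_bifurcation <- function(seed, cells_per_cluster = 60,
                                noise_sd = 0.08) {
  tr <- bifurcation_tree()
  g <- gen_lineage_counts(tr, cells_per_cluster, noise_sd, seed = seed)
  emb <- pca_embed(lognormalize(g$matrix), 3)
  lt <- mst_lineage(emb$embedding, g$matrix$cell_data$cluster, tr$root)
  list(tree = lt,
       recovered = tree_key(lt$edges) == "A B;B C;B D")
}

# --- brute-force graph oracles (independent of the implementation) ------

# All edges of a SignedGraph as a two-column character matrix.
graph_edge_mat <- function(graph) {
  cbind(graph$edges$gene_a, graph$edges$gene_b)
}

# Highest k-core of the induced subgraph on `nodes`, found by exhaustive
# subset enumeration: for each k (descending) check every vertex subset
# for minimum induced degree >= k. Only viable for small graphs.
brute_highest_core <- function(em, nodes) {
  n <- length(nodes)
  if (n == 0) return(list(k = 0L, members = character(0)))
  best <- list(k = 0L, members = nodes)
  for (k in seq_len(n - 1)) {
    found <- NULL
    for (mask in seq_len(2^n - 1)) {
      sub <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      if (length(sub) < k + 1) next
      degs <- vapply(sub, function(v) {
        sum((em[, 1] == v & em[, 2] %in% sub) |
              (em[, 2] == v & em[, 1] %in% sub))
      }, numeric(1))
      if (all(degs >= k)) {
        if (is.null(found) || length(sub) > length(found)) found <- sub
      }
    }
    if (is.null(found)) break
    best <- list(k = k, members = found)
  }
  best
}

# Brute-force MCODE vertex weights via the subset-enumeration core finder.
brute_vertex_weights <- function(graph) {
  em <- graph_edge_mat(graph)
  w <- setNames(numeric(length(graph$nodes)), graph$nodes)
  for (v in graph$nodes) {
    nbr <- unique(c(em[em[, 1] == v, 2], em[em[, 2] == v, 1]))
    if (!length(nbr)) next
    core <- brute_highest_core(em, c(v, nbr))
    if (core$k == 0) next
    m <- core$members
    n_e <- sum(em[, 1] %in% m & em[, 2] %in% m)
    w[v] <- core$k * n_e / (length(m) * (length(m) - 1) / 2)
  }
  w
}

# Independent re-statement of the MCODE expansion, written over edge
# matrices and recursion instead of adjacency lists and queues.
brute_mcode_modules <- function(graph, vwp = 0.2) {
  em <- graph_edge_mat(graph)
  w <- brute_vertex_weights(graph)
  visited <- character(0)
  modules <- list()
  neighbours <- function(v) unique(c(em[em[, 1] == v, 2],
                                     em[em[, 2] == v, 1]))
  for (seed in names(w)[order(-w, names(w))]) {
    if (seed %in% visited) next
    cutoff <- (1 - vwp) * w[seed]
    members <- seed
    visited <- c(visited, seed)
    frontier <- seed
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in setdiff(neighbours(v), visited)) {
          if (w[u] >= cutoff - 1e-9) {
            members <- c(members, u)
            visited <- c(visited, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    deg_in <- vapply(members, function(v) {
      sum(neighbours(v) %in% members)
    }, numeric(1))
    members <- members[deg_in >= 2]
    if (length(members) < 3) next
    core <- brute_highest_core(em, members)
    if (core$k < 2) next
    n_e <- sum(em[, 1] %in% members & em[, 2] %in% members)
    modules[[length(modules) + 1]] <- list(
      nodes = sort(members),
      score = n_e / (length(members) * (length(members) - 1) / 2))
  }
  modules
}

# Erdos-Renyi-ish random small SignedGraph with random edge signs.
random_small_graph <- function(seed, max_nodes = 8) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  nodes <- letters[seq_len(n)]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < runif(1, 0.2, 0.8)
  edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      rho = runif(sum(keep), -1, 1), stringsAsFactors = FALSE)
  edges <- edges[abs(edges$rho) > 1e-9, ]
  signed_graph(nodes, edges)
}

# Table 6 per-pattern gene counts (T0, T1, T2 family triples).
table6_patterns <- function() {
  data.frame(
    t0 = c("P", "P", "P", "NB", "NB", "NB", "ZIP", "ZIP",
           "P", "P", "NB", "NB", "NB", "ZIP", "ZINB"),
    t1 = c("NB", "ZIP", "ZINB", "P", "ZIP", "ZINB", "P", "NB",
           "NB", "ZIP", "P", "ZIP", "ZINB", "P", "NB"),
    t2 = c("ZIP", "NB", "NB", "ZIP", "P", "ZIP", "NB", "P",
           "P", "P", "NB", "NB", "NB", "ZIP", "ZINB"),
    count = c(14, 22, 1, 22, 14, 2, 27, 15,
              138, 30, 212, 69, 15, 1, 3),
    stringsAsFactors = FALSE)
}

# Expand the pattern table into one record per gene.
table6_records <- function() {
  pat <- table6_patterns()
  idx <- rep(seq_len(nrow(pat)), pat$count)
  data.frame(gene = sprintf("gene_%03d", seq_along(idx)),
             t0 = pat$t0[idx], t1 = pat$t1[idx], t2 = pat$t2[idx],
             stringsAsFactors = FALSE)
}

# Table 5 per-family counts per timepoint.
table5_counts <- function() {
  data.frame(
    timepoint = rep(c("T0", "T1", "T2"), each = 4),
    family = rep(c("P", "NB", "ZIP", "ZINB"), 3),
    count = c(1568, 1833, 135, 26,
              1742, 1647, 150, 23,
              1556, 1881, 106, 19),
    stringsAsFactors = FALSE)
}

# Expand Table 5 counts into a per-gene assignment data.frame.
table5_assignments <- function() {
  tab <- table5_counts()
  do.call(rbind, lapply(split(tab, tab$timepoint), function(s) {
    idx <- rep(seq_len(nrow(s)), s$count)
    data.frame(gene = sprintf("g%04d", seq_along(idx)),
               timepoint = s$timepoint[1], family = s$family[idx],
               stringsAsFactors = FALSE)
  }))
}
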