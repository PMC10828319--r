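#' Construct a signed graph from an edge table
#'
#' @param nodes character vector of gene ids.
#' @param edges `data.frame` with columns `gene_a`, `gene_b`, `rho`
#'   (optional `sign`, derived from `rho` when absent).
#' @param label provenance label (timepoint or cluster).
#' @return a `SignedGraph`: list with `nodes`, `edges` (gene_a, gene_b,
#'   rho, sign), `label`.
#' @export
signed_graph <- function(nodes, edges, label = NA_character_) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (is.null(edges$sign)) edges$sign <- ifelse(edges$rho >= 0, "+", "-")
    if (any(edges$gene_a == edges$gene_b)) stop("self-loops not allowed")
    key <- ifelse(edges$gene_a < edges$gene_b,
                  paste(edges$gene_a, edges$gene_b),
                  paste(edges$gene_b, edges$gene_a))
    if (anyDuplicated(key)) stop("duplicate edges")
    if (!all(c(edges$gene_a, edges$gene_b) %in% nodes)) {
      stop("edge endpoint not in node set")
    }
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        rho = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, label = label),
            class = "SignedGraph")
}

#' @method print SignedGraph
#' @export
print.SignedGraph <- function(x, ...) {
  cat(sprintf("SignedGraph%s: %d nodes, %d edges (%d +, %d -)\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == "+"),
              sum(x$edges$sign == "-")))
  invisible(x)
}

# Adjacency list of a SignedGraph (signs ignored).
graph_adj <- function(graph) {
  adj <- setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$gene_a[i]
    b <- graph$edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' PPI-constrained signed Spearman co-expression graph
#'
#' For each PPI pair with both genes in the expression matrix (and in
#' `gene_subset` when given), computes Spearman's rho across cells
#' (average ranks for ties) and keeps edges with `|rho| > rho_min`,
#' recording the sign. Pairs involving a constant gene have undefined rho
#' and are skipped with a warning.
#'
#' @param expr genes x cells numeric matrix with gene rownames.
#' @param ppi_edges `data.frame` with columns `gene_a`, `gene_b`.
#' @param rho_min absolute-correlation threshold (strict; default 0.5).
#' @param gene_subset optional gene ids restricting the node universe
#'   (e.g. a cluster's marker genes).
#' @param label provenance label for the graph.
#' @return a `SignedGraph` over the in-scope genes.
#' @export
correlation_graph <- function(expr, ppi_edges, rho_min = 0.5,
                              gene_subset = NULL, label = NA_character_) {
  if (ncol(expr) < 3) stop("need >= 3 cells")
  genes <- rownames(expr)
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  pp <- ppi_edges[ppi_edges$gene_a %in% genes & ppi_edges$gene_b %in% genes, ]
  used <- unique(c(pp$gene_a, pp$gene_b))
  ranks <- t(apply(expr[used, , drop = FALSE], 1, rank))
  sds <- apply(ranks, 1, stats::sd)
  const <- rownames(ranks)[sds == 0]
  if (length(const)) {
    warning("skipping pairs with constant genes: ",
            paste(head(const, 5), collapse = ", "),
            if (length(const) > 5) ", ..." else "")
  }
  keep <- !(pp$gene_a %in% const) & !(pp$gene_b %in% const)
  pp <- pp[keep, , drop = FALSE]
  rho <- vapply(seq_len(nrow(pp)), function(i) {
    cor(ranks[pp$gene_a[i], ], ranks[pp$gene_b[i], ])
  }, numeric(1))
  sel <- abs(rho) > rho_min
  signed_graph(genes,
               data.frame(gene_a = pp$gene_a[sel], gene_b = pp$gene_b[sel],
                          rho = rho[sel], stringsAsFactors = FALSE),
               label = label)
}

# Peel an adjacency list restricted to `keep`, returning the vertices of
# the highest k-core and its k. Signs are irrelevant here.
highest_core <- function(adj, keep) {
  best_k <- 0L
  best_members <- keep
  k <- 1L
  members <- keep
  repeat {
    repeat {
      deg <- vapply(members, function(v) {
        sum(adj[[v]] %in% members)
      }, numeric(1))
      drop <- members[deg < k]
      if (!length(drop)) break
      members <- setdiff(members, drop)
      if (!length(members)) break
    }
    if (!length(members)) break
    best_k <- k
    best_members <- members
    k <- k + 1L
  }
  list(k = best_k, members = best_members)
}

edge_count_within <- function(graph, members) {
  sum(graph$edges$gene_a %in% members & graph$edges$gene_b %in% members)
}

graph_density <- function(n_edges, n_nodes) {
  if (n_nodes < 2) return(0)
  n_edges / (n_nodes * (n_nodes - 1) / 2)
}

#' MCODE vertex weighting
#'
#' The weight of a vertex is `k * density` of the highest k-core of the
#' induced subgraph on its closed neighbourhood (density = edges /
#' (n(n-1)/2)); isolated vertices weigh 0. Edge signs are ignored.
#'
#' @param graph a `SignedGraph`.
#' @return named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(graph) {
  adj <- graph_adj(graph)
  w <- setNames(numeric(length(graph$nodes)), graph$nodes)
  for (v in graph$nodes) {
    nbr <- adj[[v]]
    if (is.null(nbr) || !length(nbr)) next
    closed <- c(v, nbr)
    core <- highest_core(adj, closed)
    if (core$k == 0L) next
    dens <- graph_density(edge_count_within(graph, core$members),
                          length(core$members))
    w[v] <- core$k * dens
  }
  w
}

#' MCODE dense-module detection
#'
#' Seeds at the highest-weight unvisited vertex and grows the module
#' breadth-first over unvisited neighbours whose weight is at least
#' `(1 - vwp)` times the seed weight. Post-processing: `haircut` removes
#' (in a single pass) members with within-module degree < 2; modules
#' without a `min_core`-core are discarded. Module score is the density of
#' the final module subgraph; modules are disjoint by visitation and
#' ranked by score.
#'
#' @param graph a `SignedGraph` (signs ignored for detection).
#' @param vwp vertex weight percentage cutoff in `[0, 1]` (default 0.2).
#' @param haircut drop degree-<2 members after expansion (default TRUE).
#' @param fluff unsupported MCODE option, kept for interface parity; must
#'   be FALSE.
#' @param min_core minimum k such that the module must contain a k-core
#'   (default 2).
#' @return list of `GraphModule`s: each a list with `nodes`, `score`,
#'   `rank`.
#' @export
mcode_modules <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                          min_core = 2) {
  if (vwp < 0 || vwp > 1) stop("vwp must be in [0, 1]")
  if (isTRUE(fluff)) stop("fluff post-processing is not implemented")
  adj <- graph_adj(graph)
  w <- mcode_vertex_weights(graph)
  order_v <- names(w)[order(-w, names(w))]  # ties: lexicographic
  visited <- character(0)
  modules <- list()
  for (seed in order_v) {
    if (seed %in% visited) next
    cutoff <- (1 - vwp) * w[seed]
    members <- seed
    visited <- c(visited, seed)
    queue <- seed
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (u %in% visited) next
        # small tolerance so exact boundary weights are not lost to
        # floating-point rounding
        if (w[u] >= cutoff - 1e-9) {
          members <- c(members, u)
          visited <- c(visited, u)
          queue <- c(queue, u)
        }
      }
    }
    if (haircut) {
      deg <- vapply(members, function(v) sum(adj[[v]] %in% members),
                    numeric(1))
      members <- members[deg >= 2]
    }
    if (length(members) < 3) next
    core <- highest_core(adj, members)
    if (core$k < min_core) next
    score <- graph_density(edge_count_within(graph, members),
                           length(members))
    modules[[length(modules) + 1]] <- list(nodes = sort(members),
                                           score = score)
  }
  if (length(modules)) {
    ord <- order(-vapply(modules, function(m) m$score, numeric(1)))
    modules <- modules[ord]
    for (i in seq_along(modules)) modules[[i]]$rank <- i
  }
  modules
}

#' Power-law fit to the degree distribution
#'
#' Least squares of `log10(frequency)` on `log10(degree)` over nonzero
#' degree bins, as network visualisation tools report it. Returns the
#' exponent `gamma` (negated slope) and the `R^2` of the line.
#'
#' @param graph a `SignedGraph`.
#' @return list with `gamma`, `r_squared`, `n_bins`.
#' @export
degree_powerlaw <- function(graph) {
  degs <- table(c(graph$edges$gene_a, graph$edges$gene_b))
  freq <- table(as.numeric(degs))
  d <- as.numeric(names(freq))
  f <- as.numeric(freq)
  keep <- d > 0
  d <- d[keep]
  f <- f[keep]
  if (length(d) < 3) stop("need >= 3 distinct positive degrees")
  fit <- lm(log10(f) ~ log10(d))
  # an exactly linear histogram is a legitimate input; summary.lm warns
  # about the perfect fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(gamma = -unname(coef(fit)[2]),
       r_squared = r2,
       n_bins = length(d))
}

#' Signed edge census across graphs (and modules)
#'
#' Per graph label (and per module when `module_map` is given): counts of
#' positive and negative edges and the number of non-isolated nodes, plus
#' deltas of each label's counts against the first label.
#'
#' @param graphs named list of `SignedGraph`s.
#' @param module_map optional named vector: node -> module id. All mapped
#'   nodes must exist in the shared node universe.
#' @return list with `census` (`data.frame`: label, module, positive,
#'   negative, nodes) and `deltas` (per label vs the first).
#' @export
edge_census <- function(graphs, module_map = NULL) {
  if (is.null(names(graphs))) names(graphs) <- seq_along(graphs)
  universe <- unique(unlist(lapply(graphs, function(g) g$nodes)))
  if (!is.null(module_map) && !all(names(module_map) %in% universe)) {
    stop("module_map references unknown nodes")
  }
  count_block <- function(g, members = NULL) {
    e <- g$edges
    if (!is.null(members)) {
      e <- e[e$gene_a %in% members & e$gene_b %in% members, ]
    }
    c(positive = sum(e$sign == "+"), negative = sum(e$sign == "-"),
      nodes = length(unique(c(e$gene_a, e$gene_b))))
  }
  rows <- list()
  for (lab in names(graphs)) {
    g <- graphs[[lab]]
    tot <- count_block(g)
    rows[[length(rows) + 1]] <- data.frame(
      label = lab, module = "all", positive = tot["positive"],
      negative = tot["negative"], nodes = tot["nodes"],
      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(module_map)) {
      for (m in sort(unique(module_map))) {
        blk <- count_block(g, names(module_map)[module_map == m])
        rows[[length(rows) + 1]] <- data.frame(
          label = lab, module = as.character(m),
          positive = blk["positive"], negative = blk["negative"],
          nodes = blk["nodes"], stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  census <- do.call(rbind, rows)
  rownames(census) <- NULL
  base <- census[census$label == names(graphs)[1] & census$module == "all", ]
  deltas <- do.call(rbind, lapply(names(graphs), function(lab) {
    cur <- census[census$label == lab & census$module == "all", ]
    data.frame(label = lab,
               d_positive = cur$positive - base$positive,
               d_negative = cur$negative - base$negative,
               stringsAsFactors = FALSE)
  }))
  rownames(deltas) <- NULL
  list(census = census, deltas = deltas)
}

#' Top-k hub genes by degree
#'
#' @param graph a `SignedGraph` with at least one node.
#' @param k number of hubs (>= 1); when larger than the node count, all
#'   nodes are returned. Ties are broken lexicographically by gene id.
#' @return character vector of gene ids, highest degree first.
#' @export
hub_genes <- function(graph, k = 10) {
  if (k < 1) stop("k must be >= 1")
  if (!length(graph$nodes)) stop("empty graph")
  degs <- setNames(numeric(length(graph$nodes)), graph$nodes)
  tab <- table(c(graph$edges$gene_a, graph$edges$gene_b))
  degs[names(tab)] <- as.numeric(tab)
  ord <- names(degs)[order(-degs, names(degs))]
  head(ord, k)
}
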