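make_k4_pendant <- function() {
  cl <- t(combn(c("a", "b", "c", "d"), 2))
  signed_graph(c("a", "b", "c", "d", "u"),
               data.frame(gene_a = c(cl[, 1], "a"),
                          gene_b = c(cl[, 2], "u"), rho = 1,
                          stringsAsFactors = FALSE))
}

test_that("correlation graphs respect the PPI constraint, sign and threshold", {
  cells <- 10
  expr <- rbind(up1 = 1:10, up2 = (1:10)^2, down = 10:1,
                noise = c(5, 1, 4, 2, 6, 3, 8, 7, 10, 9))
  colnames(expr) <- paste0("c", 1:10)
  ppi <- data.frame(gene_a = c("up1", "up1"), gene_b = c("up2", "down"),
                    stringsAsFactors = FALSE)
  g <- correlation_graph(expr, ppi, rho_min = 0.5)
  expect_equal(nrow(g$edges), 2)
  e_up <- g$edges[g$edges$gene_b == "up2", ]
  expect_equal(e_up$rho, 1)
  expect_equal(e_up$sign, "+")
  e_down <- g$edges[g$edges$gene_b == "down", ]
  expect_equal(e_down$rho, -1)
  expect_equal(e_down$sign, "-")

  # perfectly correlated pair absent from the PPI yields no edge
  expect_false(any(g$edges$gene_a == "up2" & g$edges$gene_b == "down"))

  # constant gene: pair skipped with a warning
  expr2 <- rbind(expr, flat = rep(3, 10))
  ppi2 <- rbind(ppi, data.frame(gene_a = "flat", gene_b = "up1"))
  expect_warning(g2 <- correlation_graph(expr2, ppi2), "constant")
  expect_equal(nrow(g2$edges), 2)
})

test_that("raising the correlation threshold never adds edges", {
  px <- gen_ppi_expression(40, list(c(8, 0.7)), n_cells = 120, seed = 51)
  prev <- correlation_graph(px$expr, px$ppi, rho_min = 0.2)
  for (thr in c(0.4, 0.6, 0.8)) {
    cur <- correlation_graph(px$expr, px$ppi, rho_min = thr)
    key <- function(g) paste(g$edges$gene_a, g$edges$gene_b)
    expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("MCODE vertex weights match hand-enumerated k-cores", {
  g <- make_k4_pendant()
  w <- mcode_vertex_weights(g)
  expect_equal(unname(w[c("a", "b", "c", "d")]), rep(3, 4))
  expect_equal(unname(w["u"]), 1)

  edge <- signed_graph(c("x", "y"), data.frame(gene_a = "x", gene_b = "y",
                                               rho = 0.9))
  expect_equal(unname(mcode_vertex_weights(edge)), c(1, 1))

  iso <- signed_graph(c("x", "y", "z"),
                      data.frame(gene_a = "x", gene_b = "y", rho = 0.9))
  expect_equal(unname(mcode_vertex_weights(iso)["z"]), 0)
})

test_that("MCODE modules reproduce the hand-traced fixtures", {
  mods <- mcode_modules(make_k4_pendant())
  expect_length(mods, 1)
  expect_equal(mods[[1]]$nodes, c("a", "b", "c", "d"))
  expect_equal(mods[[1]]$score, 1)

  tri <- signed_graph(c("a", "b", "c"),
                      data.frame(gene_a = c("a", "b", "a"),
                                 gene_b = c("b", "c", "c"), rho = 1))
  mods_tri <- mcode_modules(tri)
  expect_length(mods_tri, 1)
  expect_equal(mods_tri[[1]]$nodes, c("a", "b", "c"))

  path4 <- signed_graph(c("a", "b", "c", "d"),
                        data.frame(gene_a = c("a", "b", "c"),
                                   gene_b = c("b", "c", "d"), rho = 1))
  expect_length(mcode_modules(path4), 0)

  expect_error(mcode_modules(make_k4_pendant(), vwp = 1.5), "vwp")
})

test_that("weights and modules agree with brute-force enumeration on random graphs", {
  for (s in 1:60) {
    g <- random_small_graph(s)
    expect_equal(mcode_vertex_weights(g), brute_vertex_weights(g),
                 info = paste("weights, seed", s))
    got <- mcode_modules(g)
    want <- brute_mcode_modules(g)
    expect_equal(lapply(got, function(m) m$nodes),
                 lapply(want, function(m) m$nodes),
                 info = paste("modules, seed", s))
    expect_equal(vapply(got, function(m) m$score, numeric(1)),
                 vapply(want, function(m) m$score, numeric(1)),
                 info = paste("scores, seed", s))
  }
})

test_that("hand-written core peeling matches igraph coreness", {
  for (s in 61:90) {
    g <- random_small_graph(s)
    if (!nrow(g$edges)) next
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = g$nodes)
    core_ig <- igraph::coreness(ig)
    adj <- senkit:::graph_adj(g)
    hc <- senkit:::highest_core(adj, g$nodes)
    expect_equal(hc$k, max(core_ig))
    expect_equal(sort(hc$members),
                 sort(names(core_ig)[core_ig == max(core_ig)]))
  }
})

test_that("every detected module is connected and survives its own haircut", {
  for (s in 101:130) {
    g <- random_small_graph(s)
    for (m in mcode_modules(g)) {
      em <- g$edges[g$edges$gene_a %in% m$nodes &
                      g$edges$gene_b %in% m$nodes, ]
      ig <- igraph::graph_from_data_frame(em[, 1:2], directed = FALSE,
                                          vertices = m$nodes)
      expect_true(igraph::is_connected(ig))
      deg <- igraph::degree(ig)
      expect_true(all(deg >= 2))
    }
  }
})

test_that("planted co-expression modules are recovered with high Jaccard", {
  px <- gen_ppi_expression(80, list(c(10, 0.8)), n_cells = 500, seed = 77)
  g <- correlation_graph(px$expr, px$ppi, rho_min = 0.5)
  mods <- mcode_modules(g)
  expect_gt(length(mods), 0)
  planted <- names(px$truth$membership)[!is.na(px$truth$membership)]
  jac <- vapply(mods, function(m) {
    length(intersect(m$nodes, planted)) / length(union(m$nodes, planted))
  }, numeric(1))
  expect_gte(max(jac), 0.8)
})

test_that("power-law fits recover exact and simulated degree spectra", {
  # freq(d) = 64 / d^2 over degrees 1,2,4,8: exact log-log line, gamma 2
  deg_seq <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
  ig <- igraph::realize_degseq(deg_seq)
  el <- igraph::as_edgelist(ig)
  nodes <- paste0("n", seq_along(deg_seq))
  g <- signed_graph(nodes, data.frame(gene_a = nodes[el[, 1]],
                                      gene_b = nodes[el[, 2]], rho = 1))
  fit <- degree_powerlaw(g)
  expect_equal(fit$gamma, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # complete graph: single degree value
  k5 <- t(combn(paste0("k", 1:5), 2))
  gk <- signed_graph(paste0("k", 1:5),
                     data.frame(gene_a = k5[, 1], gene_b = k5[, 2], rho = 1))
  expect_error(degree_powerlaw(gk), "distinct")

  # preferential-attachment fixture: exponent in the scale-free range
  px <- gen_ppi_expression(300, list(), n_cells = 5, seed = 5)
  gpa <- signed_graph(sprintf("G%04d", 1:300),
                      data.frame(gene_a = px$ppi$gene_a,
                                 gene_b = px$ppi$gene_b, rho = 1))
  fpa <- degree_powerlaw(gpa)
  expect_gte(fpa$gamma, 1.5)
  expect_lte(fpa$gamma, 3.5)
})

test_that("edge censuses count signs exactly and match a brute-force scan", {
  g <- signed_graph(letters[1:5],
                    data.frame(gene_a = c("a", "a", "b", "c"),
                               gene_b = c("b", "c", "c", "d"),
                               rho = c(0.8, 0.9, 0.7, -0.6)))
  cen <- edge_census(list(T0 = g))
  expect_equal(cen$census$positive, 3)
  expect_equal(cen$census$negative, 1)

  empty <- signed_graph(letters[1:3], data.frame())
  cen0 <- edge_census(list(T0 = empty))
  expect_equal(cen0$census$positive + cen0$census$negative, 0)

  g2 <- random_small_graph(200)
  cen2 <- edge_census(list(A = g2, B = g))
  brute_pos <- sum(g2$edges$rho > 0)
  expect_equal(cen2$census$positive[cen2$census$label == "A"], brute_pos)
  expect_equal(cen2$deltas$d_positive[cen2$deltas$label == "B"],
               3 - brute_pos)

  mm <- setNames(rep("m1", 3), c("a", "b", "c"))
  cenm <- edge_census(list(T0 = g), module_map = mm)
  expect_equal(cenm$census$positive[cenm$census$module == "m1"], 3)
  expect_error(edge_census(list(T0 = g), setNames("m1", "zz")), "unknown")
})

test_that("hub genes rank by degree with lexicographic ties", {
  star <- signed_graph(c("hub", paste0("s", 1:5)),
                       data.frame(gene_a = "hub", gene_b = paste0("s", 1:5),
                                  rho = 1))
  expect_equal(hub_genes(star, 1), "hub")
  expect_equal(hub_genes(star, 10), c("hub", paste0("s", 1:5)))

  g <- random_small_graph(300)
  degs <- setNames(numeric(length(g$nodes)), g$nodes)
  tab <- table(c(g$edges$gene_a, g$edges$gene_b))
  degs[names(tab)] <- tab
  brute <- names(degs)[order(-degs, names(degs))][1:3]
  expect_equal(hub_genes(g, 3), brute)
  expect_error(hub_genes(signed_graph(character(), data.frame()), 3),
               "empty")
})
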