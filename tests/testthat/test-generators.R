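test_that("random_graph places exactly l links and respects capacity", {
  expect_identical(random_graph(5, 10, seed = 1)$adjacency,
                   complete_graph(5)$adjacency)
  expect_equal(link_count(netgraph(random_graph(4, 0, seed = 1)$adjacency)), 0L)
  g <- random_graph(200, 995, seed = 2)
  expect_valid_netgraph(g)
  expect_equal(link_count(g), 995L)
  gd <- random_graph(50, 300, directed = TRUE, seed = 3)
  expect_true(gd$directed)
  expect_equal(link_count(gd), 300L)
  expect_error(random_graph(4, 7), "capacity")
  # same seed, same adjacency
  expect_identical(random_graph(40, 100, seed = 9)$adjacency,
                   random_graph(40, 100, seed = 9)$adjacency)
})

test_that("scale_free_graph honours the link contract and rank bias", {
  g <- scale_free_graph(300, 1200, alpha = 0.5, seed = 1)
  expect_valid_netgraph(g)
  expect_equal(link_count(g), 1200L)
  expect_error(scale_free_graph(100, 50, alpha = -0.1), "alpha")
  # stronger rank exponent concentrates degree on the top-ranked nodes
  md <- function(alpha, s)
    max(node_degrees(scale_free_graph(300, 1200, alpha, seed = s))$total)
  strong <- mean(vapply(1:5, function(s) md(0.9, s), 0))
  weak <- mean(vapply(1:5, function(s) md(0.1, 100 + s), 0))
  expect_gt(strong, weak)
})

test_that("degree-preserving rewiring conserves every degree exactly", {
  g <- scale_free_graph(100, 400, alpha = 0.6, seed = 4)
  r <- rewire_preserving_degrees(g, seed = 5)
  expect_valid_netgraph(r)
  expect_equal(node_degrees(r)$total, node_degrees(g)$total)
  expect_equal(link_count(r), link_count(g))
  gd <- random_graph(60, 500, directed = TRUE, seed = 6)
  rd <- rewire_preserving_degrees(gd, seed = 7)
  expect_true(rd$directed)
  expect_equal(node_degrees(rd)$in_degree, node_degrees(gd)$in_degree)
  expect_equal(node_degrees(rd)$out_degree, node_degrees(gd)$out_degree)
  expect_identical(rewire_preserving_degrees(g, seed = 8)$adjacency,
                   rewire_preserving_degrees(g, seed = 8)$adjacency)
})

test_that("modular_graph plants the requested block structure", {
  res <- modular_graph(256, 4, 24, 0, seed = 1)
  a <- res$graph$adjacency
  cross <- outer(as.integer(res$partition), as.integer(res$partition), "!=")
  expect_equal(sum(a[cross]), 0)                       # disconnected modules
  expect_equal(link_count(res$graph), round(256 * 24 / 2))
  res2 <- modular_graph(256, 4, 19, 5, seed = 2)
  a2 <- res2$graph$adjacency
  cross2 <- outer(as.integer(res2$partition), as.integer(res2$partition), "!=")
  expect_equal(sum(a2[cross2]) / 2, round(256 * 5 / 2))
  expect_equal(sum(a2[!cross2]) / 2, round(256 * 19 / 2))
  # two disconnected 4-cliques: q = 1 - 2 (1/2)^2 = 0.5 by hand
  cl <- modular_graph(8, 2, 3, 0, seed = 3)
  expect_equal(newman_modularity(cl$graph, cl$partition), 0.5)
  expect_error(modular_graph(10, 3, 2, 2), "divisible")
})

test_that("hierarchical generators meet their per-level link counts", {
  res <- hm_random_graph(rhm_spec(), seed = 1)
  g <- res$graph
  expect_valid_netgraph(g)
  expect_equal(link_count(g), 3072L)                  # 256 * 24 / 2
  coarse <- as.integer(res$partitions[[1]])
  fine <- as.integer(res$partitions[[2]])
  a <- g$adjacency
  lvl1 <- outer(coarse, coarse, "!=")
  lvl2 <- outer(coarse, coarse, "==") & outer(fine, fine, "!=")
  lvl3 <- outer(fine, fine, "==")
  expect_equal(sum(a[lvl1]) / 2, round(256 * 5 / 2))
  expect_equal(sum(a[lvl2]) / 2, round(256 * 6 / 2))
  expect_equal(sum(a[lvl3]) / 2, round(256 * 13 / 2))
  # fine-level mean internal degree ~ 13
  expect_equal(sum(a[lvl3]) / 256, 13, tolerance = 0.01)
  # degrees (0, 0, k): block-diagonal, 16 disconnected components
  blocky <- hm_random_graph(rhm_spec(c(0, 0, 8)), seed = 2)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    blocky$graph$adjacency, mode = "undirected"))
  expect_equal(comp$no, 16L)
})

test_that("centralised model keeps RHM link counts but concentrates degree", {
  rhm <- hm_random_graph(rhm_spec(), seed = 10)
  chm <- hm_centralised_graph(chm_spec(), seed = 10)
  expect_valid_netgraph(chm$graph)
  expect_equal(link_count(chm$graph), link_count(rhm$graph))
  coarse <- as.integer(chm$partitions[[1]])
  fine <- as.integer(chm$partitions[[2]])
  a <- chm$graph$adjacency
  expect_equal(sum(a[outer(coarse, coarse, "!=")]) / 2, 640)
  expect_equal(sum(a[outer(coarse, coarse, "==") &
                     outer(fine, fine, "!=")]) / 2, 768)
  maxd <- function(res) max(node_degrees(res$graph)$total)
  chm_max <- mean(vapply(1:5, function(s)
    maxd(hm_centralised_graph(chm_spec(), seed = s)), 0))
  rhm_max <- mean(vapply(1:5, function(s)
    maxd(hm_random_graph(rhm_spec(), seed = s)), 0))
  expect_gt(chm_max, rhm_max)
  expect_error(hierarchy_spec(c(4, 4), 16, c(5, 6, 13), c(0.9, 2)), "> 1")
  expect_error(hm_centralised_graph(rhm_spec()), "exponents")
})

test_that("Ravasz-Barabasi construction is deterministic with the printed sizes", {
  g5 <- ravasz_barabasi_graph(5, 3)
  expect_equal(n_nodes(g5), 125L)
  g6 <- ravasz_barabasi_graph(6, 3)
  expect_equal(n_nodes(g6), 216L)
  expect_equal(round(graph_density(g6), 3), 0.031)
  expect_identical(g6$adjacency, ravasz_barabasi_graph(6, 3)$adjacency)
  expect_valid_netgraph(g6)
  expect_equal(n_nodes(ravasz_barabasi_graph(4, 1)), 4L)
})

test_that("modularity-preserving randomisation conserves all block counts", {
  res <- modular_graph(128, 4, 14, 6, seed = 4)
  g <- res$graph; p <- res$partition
  r <- modularity_preserving_graph(g, p, seed = 5)
  expect_valid_netgraph(r)
  comm <- as.integer(p)
  for (i in 1:4) for (j in i:4) {
    block <- function(a) sum(a[comm == i, comm == j]) / (if (i == j) 2 else 1)
    expect_equal(block(r$adjacency), block(g$adjacency),
                 label = sprintf("block (%d,%d)", i, j))
  }
  expect_equal(newman_modularity(r, p), newman_modularity(g, p),
               tolerance = 1e-12)
  # directed inputs: per-direction arc counts preserved
  gd <- random_graph(40, 300, directed = TRUE, seed = 6)
  pd <- partition(rep(1:4, each = 10))
  rd <- modularity_preserving_graph(gd, pd, seed = 7)
  expect_true(rd$directed)
  expect_equal(link_count(rd), link_count(gd))
  cd <- as.integer(pd)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(sum(rd$adjacency[cd == i, cd == j]),
                 sum(gd$adjacency[cd == i, cd == j]))
  }
  # hub-concentrated cross links flatten under randomisation
  hub <- hm_centralised_graph(chm_spec(), seed = 8)
  flat <- modularity_preserving_graph(hub$graph, hub$partitions[[1]], seed = 9)
  expect_lte(max(node_degrees(flat)$total), max(node_degrees(hub$graph)$total))
})

test_that("pseudo-connectome fixtures satisfy the planted-structure contract", {
  res <- pseudo_connectome(256, seed = 1)
  expect_valid_netgraph(res$graph)
  expect_gt(newman_modularity(res$graph, res$partition), 0.3)
  small <- pseudo_connectome(64, seed = 2)
  expect_valid_netgraph(small$graph)
  expect_gt(newman_modularity(small$graph, small$partition), 0.3)
  expect_error(pseudo_connectome(30), "multiple of 16")
  # zero noise returns exactly the analytic mapping
  fc0 <- pseudo_empirical_fc(small$graph, 1.5, noise_sd = 0, seed = 3)
  expect_equal(fc0, estimate_fc(small$graph, 1.5), tolerance = 1e-15)
  fc <- pseudo_empirical_fc(small$graph, 1.5, noise_sd = 0.1, seed = 4)
  expect_true(all(fc >= -1 & fc <= 1))
  expect_equal(diag(fc), rep(1, 64))
  expect_equal(fc, t(fc))
})
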