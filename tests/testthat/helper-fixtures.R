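# Small graphs and hierarchy specs shared across the test files.

k2_graph <- function() netgraph(matrix(c(0, 1, 1, 0), 2))

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  netgraph(a)
}

star_graph <- function(leaves) {
  a <- matrix(0L, leaves + 1L, leaves + 1L)
  a[1, -1] <- 1L
  a[-1, 1] <- 1L
  netgraph(a)
}

cycle_graph <- function(n, directed = FALSE) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) a[i, i %% n + 1L] <- 1L
  if (!directed) a <- pmax(a, t(a))
  netgraph(a, directed = directed)
}

# connected undirected ER graph (resamples until connected)
connected_er <- function(n, l, seed) {
  for (s in seed + 0:20) {
    g <- random_graph(n, l, seed = s)
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      g$adjacency, mode = "undirected"))
    if (comp$no == 1L) return(g)
  }
  stop("could not draw a connected graph")
}

rhm_spec <- function(k = c(5, 6, 13)) hierarchy_spec(c(4, 4), 16, k)

chm_spec <- function(k = c(5, 6, 13), gam = c(1.7, 2.0))
  hierarchy_spec(c(4, 4), 16, k, level_exponents = gam)

expect_valid_netgraph <- function(g) {
  expect_s3_class(g, "netgraph")
  a <- g$adjacency
  expect_true(all(a %in% c(0L, 1L)))
  expect_identical(diag(a), rep(0L, nrow(a)))
  if (!g$directed) expect_identical(a, t(a))
}
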