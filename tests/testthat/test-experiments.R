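test_that("coupling scans reproduce the two-node closed forms", {
  sc <- coupling_scan(k2_graph(), g_grid = c(0, 0.25, 1))
  expect_equal(sc$mean_r, c(0, tanh(0.5), tanh(2)), tolerance = 1e-12)
  expect_equal(sc$complexity[1], 0)
  expect_equal(sc$lambda_max, 1)
  expect_equal(sc$g_real, sc$g / sc$lambda_max)
  expect_error(coupling_scan(k2_graph(), g_grid = c(1, 0.5)), "ascending")
  expect_error(coupling_scan(k2_graph(), g_grid = c(0, 2), method = "linear"),
               "g < 1")
})

test_that("the scan engine agrees with estimate_fc on both branches", {
  g <- connected_er(30, 120, seed = 1)
  sc <- coupling_scan(g, g_grid = c(0.8, 2.4))
  expect_equal(sc$mean_r[2], mean_correlation(estimate_fc(g, 2.4)),
               tolerance = 1e-9)
  expect_equal(sc$complexity[1],
               functional_complexity(estimate_fc(g, 0.8)), tolerance = 1e-9)
  lin <- coupling_scan(g, g_grid = c(0.3, 0.6), method = "linear")
  expect_equal(lin$mean_r[1],
               mean_correlation(estimate_fc(g, 0.3, method = "linear")),
               tolerance = 1e-9)
  gd <- cycle_graph(5, directed = TRUE)       # directed branch
  scd <- coupling_scan(gd, g_grid = c(0, 1.5))
  expect_equal(scd$mean_r[2], mean_correlation(estimate_fc(gd, 1.5)),
               tolerance = 1e-9)
  expect_equal(scd$mean_r[1], 0)
})

test_that("scan invariants hold: start at zero, rise, decay at saturation", {
  g <- connected_er(100, 1500, seed = 2)
  sc <- coupling_scan(g)
  expect_equal(sc$mean_r[1], 0)
  expect_equal(sc$complexity[1], 0)
  expect_true(all(diff(sc$mean_r) >= -1e-6))
  expect_lt(sc$complexity[length(sc$g)], 0.05)  # global-synchrony limit
})

test_that("peak localisation and threshold crossing follow the grid rules", {
  sc <- coupling_scan(k2_graph(), g_grid = c(0, 1, 2))
  sc$complexity <- c(0, 0.5, 0.3)
  pk <- peak_complexity(sc)
  expect_equal(pk$g_star, 1); expect_equal(pk$c_star, 0.5)
  sc$complexity <- c(0, 0, 0)                  # flat: tie resolves left
  expect_equal(peak_complexity(sc)$g_star, 0)
  fine <- coupling_scan(k2_graph(), g_grid = seq(0, 2, by = 0.05))
  expect_equal(synchronization_coupling(fine, 0.85), atanh(0.85) / 2,
               tolerance = 5e-3)
  low <- coupling_scan(k2_graph(), g_grid = c(0, 0.1))
  expect_error(synchronization_coupling(low, 0.85), "never reaches")
})

test_that("fit_coupling recovers exact and degenerate fits", {
  g <- pseudo_connectome(64, seed = 3)$graph
  grid <- seq(0, 5, by = 0.25)
  fc <- estimate_fc(g, 2.0)
  fit <- fit_coupling(g, fc, g_grid = grid)
  expect_equal(fit$g_best, 2.0)
  expect_equal(fit$distance, 0, tolerance = 1e-9)
  expect_equal(fit$complexity_at_best, functional_complexity(fc),
               tolerance = 1e-9)
  # independence is best fit by the weakest coupling
  fit0 <- fit_coupling(g, diag(64), g_grid = grid)
  expect_equal(fit0$g_best, 0)
  expect_error(fit_coupling(g, diag(10), g_grid = grid), "dimension")
  expect_equal(length(fit$distance_curve), length(grid))
})

test_that("lesion nulls draw only from non-rich-club links", {
  # two triangles joined by a bridge; members = first triangle (3 rich-club
  # links), eligible pool = the other 4 links. Every possible clean null
  # removes 3 of those 4, so each null complexity must equal one of the four
  # enumerated values; any leakage of rich-club links into the pool would
  # produce a value outside the set.
  a <- matrix(0L, 6, 6)
  lk <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
  a[lk] <- 1L; a <- pmax(a, t(a))
  g <- netgraph(a)
  grid <- seq(0, 3, by = 0.5)
  les <- lesion_study(g, 1:3, n_random = 25, g_grid = grid, m = 10, seed = 1)
  expect_equal(les$removed_links, 3)
  eligible <- lk[4:7, , drop = FALSE]
  enumerated <- apply(utils::combn(4, 3), 2, function(idx) {
    adj <- a
    rm <- eligible[idx, , drop = FALSE]
    adj[rm] <- 0L
    adj[rm[, 2:1]] <- 0L
    gs <- peak_complexity(coupling_scan(g, grid, m = 10))$g_star
    functional_complexity(estimate_fc(netgraph(adj), gs), m = 10)
  })
  expect_true(all(vapply(les$null_sample, function(x)
    any(abs(x - enumerated) < 1e-12), TRUE)))
  expect_gte(les$probability, 0); expect_lte(les$probability, 1)
  expect_error(lesion_study(g, integer(0)), "non-empty")
  iso <- netgraph(rbind(c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L)))
  expect_error(lesion_study(iso, c(1, 3), g_grid = grid), "no rich-club links")
})

test_that("rich-club lesion lowers complexity on the centralised fixture", {
  res <- pseudo_connectome(128, seed = 4)
  g <- res$graph
  les <- lesion_study(g, hub_nodes(g), n_random = 40,
                      g_grid = default_g_grid(0.2), seed = 5)
  expect_lt(les$c_lesion, les$c_real)
  expect_gt(les$removed_links, 0)
  expect_equal(length(les$null_sample), 40)
  expect_equal(les$probability, mean(les$null_sample < les$c_lesion))
})

test_that("surrogate drivers are reproducible with a fixed seed", {
  res <- pseudo_connectome(64, seed = 6)
  grid <- seq(0, 6, by = 0.5)
  c1 <- surrogate_comparison(res$graph, res$partition, n_realisations = 1,
                             g_grid = grid, seed = 11)
  c2 <- surrogate_comparison(res$graph, res$partition, n_realisations = 1,
                             g_grid = grid, seed = 11)
  expect_identical(c1$conditions, c2$conditions)
  l1 <- lesion_study(res$graph, hub_nodes(res$graph), n_random = 5,
                     g_grid = grid, seed = 12)
  l2 <- lesion_study(res$graph, hub_nodes(res$graph), n_random = 5,
                     g_grid = grid, seed = 12)
  expect_identical(l1$null_sample, l2$null_sample)
})

test_that("an ER graph is statistically its own surrogate", {
  g <- random_graph(64, 480, seed = 7)
  p <- partition(rep(1:4, each = 16))
  cmp <- surrogate_comparison(g, p, n_realisations = 8,
                              g_grid = seq(0, 8, by = 0.4), seed = 13)
  peaks <- vapply(cmp$conditions, `[[`, 0, "peak_mean")
  sds <- vapply(cmp$conditions, `[[`, 0, "peak_sd")
  pooled <- mean(sds, na.rm = TRUE)
  expect_true(all(abs(peaks - peaks["original"]) < 2 * pooled + 1e-12))
})
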