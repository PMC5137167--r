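# Experiment drivers: coupling scans, surrogate comparisons, rich-club lesion
# studies and empirical-FC fitting.

# Evaluate stat_fun(R) on the analytic FC at every coupling of the grid.
# Undirected graphs use a single eigendecomposition of the normalised
# adjacency: for A = V L V', the covariance is Q'Q = V exp(2 g L) V'
# (exponential) or V (1 - g L)^-2 V' (linear), so each coupling costs one
# matrix product instead of a fresh matrix exponential / inverse.
.scan_engine <- function(g, g_grid, method, stat_fun) {
  if (is.unsorted(g_grid, strictly = TRUE)) stop("g grid must be ascending")
  if (any(g_grid < 0)) stop("couplings must be >= 0")
  if (method == "linear" && max(g_grid) >= 1)
    stop("linear propagator requires g < 1 over the whole grid")
  sn <- spectral_normalize(g)
  n <- n_nodes(g)
  stats <- NULL
  if (!g$directed) {
    e <- eigen(sn$matrix, symmetric = TRUE)
    V <- e$vectors
    lam <- e$values
    for (idx in seq_along(g_grid)) {
      gc <- g_grid[idx]
      u <- if (method == "exponential") exp(2 * gc * lam)
        else (1 - gc * lam)^(-2)
      cov <- tcrossprod(V * rep(sqrt(u), each = n))
      d <- diag(cov)
      R <- cov / sqrt(outer(d, d))
      diag(R) <- 1
      s <- stat_fun(R)
      if (is.null(stats)) stats <- matrix(0, length(g_grid), length(s))
      stats[idx, ] <- s
    }
  } else {
    for (idx in seq_along(g_grid)) {
      gc <- g_grid[idx]
      prop <- if (method == "exponential")
        exponential_propagator(sn$matrix, gc)
      else linear_propagator(sn$matrix, gc)
      R <- correlation_from_covariance(covariance_from_propagator(prop))
      s <- stat_fun(R)
      if (is.null(stats)) stats <- matrix(0, length(g_grid), length(s))
      stats[idx, ] <- s
    }
  }
  list(stats = stats, lambda_max = sn$lambda_max)
}

#' Default coupling grid
#'
#' `g` from 0 to just below 10 in steps of `step`; after spectral
#' normalisation the transition to global synchrony falls inside this range
#' for most networks.
#'
#' @param step grid step (default 0.1).
#' @param gmax exclusive upper bound (default 10).
#' @return ascending numeric vector starting at 0.
#' @export
default_g_grid <- function(step = 0.1, gmax = 10) {
  seq(0, gmax - step, by = step)
}

#' Coupling scan
#'
#' Sweeps the coupling strength over a grid, computing the analytic FC at each
#' `g` and recording the mean correlation and the functional complexity: the
#' transition from independence (both 0 at `g = 0`) through the
#' complexity peak to global synchrony.
#'
#' @param g a [netgraph].
#' @param g_grid ascending coupling grid (default [default_g_grid()]).
#' @param method propagator, `"exponential"` (default) or `"linear"`.
#' @param m histogram bins for the complexity statistic.
#' @param support histogram support.
#' @return object of class `coupling_scan`: list with `g`, `g_real`
#'   (`g / lambda_max`, the pre-normalisation coupling), `mean_r`,
#'   `complexity`, `method`, `m`, `lambda_max`.
#' @export
coupling_scan <- function(g, g_grid = default_g_grid(),
                          method = c("exponential", "linear"),
                          m = 50, support = c(0, 1)) {
  method <- match.arg(method)
  res <- .scan_engine(g, g_grid, method, function(R)
    c(mean_correlation(R), functional_complexity(R, m, support)))
  structure(list(g = g_grid, g_real = g_grid / res$lambda_max,
                 mean_r = res$stats[, 1], complexity = res$stats[, 2],
                 method = method, m = m, lambda_max = res$lambda_max),
            class = "coupling_scan")
}

#' @export
as.data.frame.coupling_scan <- function(x, ...) {
  data.frame(g = x$g, g_real = x$g_real, mean_r = x$mean_r,
             complexity = x$complexity)
}

#' @export
print.coupling_scan <- function(x, ...) {
  pk <- peak_complexity(x)
  cat(sprintf(
    "coupling scan (%s propagator, %d couplings, m = %d, lambda_max = %.4g)\n",
    x$method, length(x$g), x$m, x$lambda_max))
  cat(sprintf("peak complexity C = %.4g at g = %.3g (mean r there: %.3g)\n",
              pk$c_star, pk$g_star, x$mean_r[which.max(x$complexity)]))
  invisible(x)
}

#' @export
plot.coupling_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$g, x$mean_r, type = "l", xlab = "coupling g",
                 ylab = "mean correlation", ylim = c(0, 1), ...)
  graphics::plot(x$g, x$complexity, type = "l", xlab = "coupling g",
                 ylab = "functional complexity", ...)
  invisible(x)
}

#' Peak of a coupling scan
#'
#' Grid argmax of the complexity curve; ties resolve to the smallest `g`.
#'
#' @param scan a `coupling_scan`.
#' @return list with `g_star` and `c_star`.
#' @export
peak_complexity <- function(scan) {
  stopifnot(inherits(scan, "coupling_scan"))
  i <- which.max(scan$complexity)
  list(g_star = scan$g[i], c_star = scan$complexity[i])
}

#' Coupling at which the network synchronises
#'
#' Smallest coupling at which the mean correlation reaches `threshold`,
#' located by linear interpolation between the bracketing grid points.
#'
#' @param scan a `coupling_scan`.
#' @param threshold mean-correlation level (default 0.85).
#' @return interpolated coupling `g`.
#' @export
synchronization_coupling <- function(scan, threshold = 0.85) {
  stopifnot(inherits(scan, "coupling_scan"))
  r <- scan$mean_r
  i <- which(r >= threshold)[1]
  if (is.na(i))
    stop("mean correlation never reaches ", threshold, " on this grid")
  if (i == 1L) return(scan$g[1])
  g0 <- scan$g[i - 1]; g1 <- scan$g[i]
  r0 <- r[i - 1]; r1 <- r[i]
  g0 + (threshold - r0) / (r1 - r0) * (g1 - g0)
}

# analytic FC complexity of an adjacency at one coupling, optionally with a
# frozen normaliser (for lesion studies where the original lambda_max is kept)
.complexity_at <- function(adj, directed, g_coupling, m, support,
                           lambda = NULL, method = "exponential") {
  gr <- netgraph(adj, directed = directed)
  if (is.null(lambda)) {
    R <- estimate_fc(gr, g_coupling, method = method)
  } else {
    storage.mode(adj) <- "double"
    prop <- if (method == "exponential")
      exponential_propagator(adj / lambda, g_coupling)
    else linear_propagator(adj / lambda, g_coupling)
    R <- correlation_from_covariance(covariance_from_propagator(prop))
  }
  functional_complexity(R, m, support)
}

.remove_links <- function(g, links) {
  adj <- g$adjacency
  if (nrow(links)) {
    adj[links] <- 0L
    if (!g$directed) adj[links[, 2:1, drop = FALSE]] <- 0L
  }
  netgraph(adj, directed = g$directed, labels = g$labels)
}

#' Surrogate comparison
#'
#' Compares the peak functional complexity of a network against three
#' surrogate ensembles sharing its size and link count: degree-preserving
#' rewirings (modules destroyed, hubs kept), modularity-preserving
#' randomisations (modules kept, hubs destroyed) and plain G(N, L) random
#' graphs. All scans share the grid and bin count. Both the peak of the
#' ensemble-mean curve and the mean of per-realisation peaks are reported.
#'
#' @param g a [netgraph].
#' @param p a [partition] (for the modularity-preserving condition).
#' @param n_realisations surrogates per condition (default 100).
#' @param g_grid,method,m,support as in [coupling_scan()].
#' @param seed optional integer seed; realisation `i` of each condition uses
#'   a derived seed so results are independent of execution order.
#' @return object of class `surrogate_comparison`.
#' @export
surrogate_comparison <- function(g, p, n_realisations = 100,
                                 g_grid = default_g_grid(),
                                 method = "exponential", m = 50,
                                 support = c(0, 1), seed = NULL) {
  stopifnot(inherits(g, "netgraph"))
  if (length(p) != n_nodes(g)) stop("partition does not cover all nodes")
  if (n_realisations < 1) stop("need at least one realisation per condition")
  base <- if (is.null(seed)) 0L else as.integer(seed)
  n <- n_nodes(g)
  l <- link_count(g)
  gen <- list(
    rewired = function(s) rewire_preserving_degrees(g, seed = s),
    modularity_preserving = function(s) modularity_preserving_graph(g, p, seed = s),
    random = function(s) random_graph(n, l, directed = g$directed, seed = s))
  orig <- coupling_scan(g, g_grid, method = method, m = m, support = support)
  conditions <- list(original = list(
    mean_curve = orig$complexity,
    peak_of_mean = max(orig$complexity),
    peak_mean = peak_complexity(orig)$c_star,
    peak_sd = NA_real_, n = 1L))
  for (cond in names(gen)) {
    curves <- matrix(0, n_realisations, length(g_grid))
    peaks <- numeric(n_realisations)
    for (i in seq_len(n_realisations)) {
      s <- base + 7919L * match(cond, names(gen)) + i
      sg <- gen[[cond]](s)
      sc <- coupling_scan(sg, g_grid, method = method, m = m,
                          support = support)
      curves[i, ] <- sc$complexity
      peaks[i] <- max(sc$complexity)
    }
    mc <- colMeans(curves)
    conditions[[cond]] <- list(mean_curve = mc, peak_of_mean = max(mc),
                               peak_mean = mean(peaks),
                               peak_sd = stats::sd(peaks),
                               n = n_realisations)
  }
  structure(list(conditions = conditions, g_grid = g_grid, method = method,
                 m = m, n_realisations = n_realisations, seed = seed),
            class = "surrogate_comparison")
}

#' @export
print.surrogate_comparison <- function(x, ...) {
  cat(sprintf("surrogate comparison (%d realisations per condition)\n",
              x$n_realisations))
  for (nm in names(x$conditions)) {
    cc <- x$conditions[[nm]]
    cat(sprintf("  %-22s peak(mean curve) = %.4f  mean(peaks) = %.4f%s\n",
                nm, cc$peak_of_mean, cc$peak_mean,
                if (is.na(cc$peak_sd)) "" else sprintf(" (sd %.4f)", cc$peak_sd)))
  }
  invisible(x)
}

#' @export
plot.surrogate_comparison <- function(x, ...) {
  curves <- vapply(x$conditions, `[[`, numeric(length(x$g_grid)), "mean_curve")
  graphics::matplot(x$g_grid, curves, type = "l", lty = 1:4, col = 1:4,
                    xlab = "coupling g", ylab = "functional complexity", ...)
  graphics::legend("topright", colnames(curves), lty = 1:4, col = 1:4,
                   bty = "n")
  invisible(x)
}

#' Rich-club lesion study
#'
#' Removes every link between the rich-club member nodes, evaluates the
#' functional complexity at the intact network's optimal coupling `g*` (the
#' grid peak of its complexity curve), and compares the drop against random
#' lesions that remove the same number of links drawn uniformly from the
#' non-rich-club links (rich-club links are excluded from the null draws).
#' The reported probability is the fraction of random lesions with complexity
#' strictly below the targeted lesion's.
#'
#' @param g a [netgraph].
#' @param members rich-club node indices (1-based), e.g. from
#'   [rich_club_profile()].
#' @param n_random number of random lesions (default 1000).
#' @param m,support,g_grid,method as in [coupling_scan()].
#' @param seed optional integer seed.
#' @param renormalise if `TRUE` (default) every lesioned graph is normalised
#'   by its own spectral radius before applying `g*`; if `FALSE` the intact
#'   network's `lambda_max` is frozen.
#' @return object of class `lesion_result`: `c_real`, `c_lesion`, `g_star`,
#'   `removed_links`, `null_sample`, `probability`.
#' @export
lesion_study <- function(g, members, n_random = 1000, m = 50,
                         support = c(0, 1), g_grid = default_g_grid(),
                         method = "exponential", seed = NULL,
                         renormalise = TRUE) {
  stopifnot(inherits(g, "netgraph"))
  if (!length(members)) stop("members must be non-empty")
  rc <- rich_club_links(g, members)
  if (nrow(rc) == 0L) stop("no rich-club links to remove")
  scan <- coupling_scan(g, g_grid, method = method, m = m, support = support)
  pk <- peak_complexity(scan)
  g_star <- pk$g_star
  c_real <- pk$c_star
  lam <- if (renormalise) NULL else scan$lambda_max
  lesioned <- .remove_links(g, rc)
  c_lesion <- .complexity_at(lesioned$adjacency, g$directed, g_star, m,
                             support, lambda = lam, method = method)
  # eligible pool: every link that is not a rich-club link
  a <- g$adjacency
  if (!g$directed) a[lower.tri(a)] <- 0L
  all_links <- which(a == 1L, arr.ind = TRUE)
  key <- function(mm) paste(mm[, 1], mm[, 2])
  eligible <- all_links[!(key(all_links) %in% key(rc)), , drop = FALSE]
  n_remove <- nrow(rc)
  if (nrow(eligible) < n_remove)
    stop("fewer eligible links (", nrow(eligible),
         ") than required for a null draw (", n_remove, ")")
  .seed_rng(seed)
  null_sample <- numeric(n_random)
  for (b in seq_len(n_random)) {
    sel <- eligible[sample.int(nrow(eligible), n_remove), , drop = FALSE]
    lg <- .remove_links(g, sel)
    null_sample[b] <- .complexity_at(lg$adjacency, g$directed, g_star, m,
                                     support, lambda = lam, method = method)
  }
  structure(list(c_real = c_real, c_lesion = c_lesion, g_star = g_star,
                 removed_links = n_remove, null_sample = null_sample,
                 probability = mean(null_sample < c_lesion),
                 n_random = n_random, renormalise = renormalise, seed = seed),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("rich-club lesion: %d links removed at g* = %.3g\n",
              x$removed_links, x$g_star))
  cat(sprintf("C(real) = %.4f  C(lesion) = %.4f  (%+.2f%%)\n",
              x$c_real, x$c_lesion,
              100 * (x$c_lesion - x$c_real) / x$c_real))
  cat(sprintf("P(random lesion < C(lesion)) = %.4g  (%d random lesions)\n",
              x$probability, x$n_random))
  invisible(x)
}

#' Fit the coupling of an analytic FC to an empirical FC
#'
#' Sweeps the grid and returns the coupling minimising the Euclidean distance
#' (off-diagonal entries) between the analytic and the empirical FC, together
#' with the full distance curve and the functional complexity at the best fit.
#'
#' @param g a [netgraph].
#' @param fc_empirical empirical correlation matrix, same dimension as `g`.
#' @param g_grid,method,m,support as in [coupling_scan()].
#' @return object of class `coupling_fit`: `g_best`, `distance`,
#'   `distance_curve`, `g_grid`, `complexity_at_best`.
#' @export
fit_coupling <- function(g, fc_empirical, g_grid = default_g_grid(),
                         method = c("exponential", "linear"), m = 50,
                         support = c(0, 1)) {
  method <- match.arg(method)
  stopifnot(inherits(g, "netgraph"))
  if (!all(dim(fc_empirical) == n_nodes(g)))
    stop("empirical FC dimension does not match the graph")
  res <- .scan_engine(g, g_grid, method, function(R)
    c(fc_distance(R, fc_empirical), functional_complexity(R, m, support)))
  i <- which.min(res$stats[, 1])
  structure(list(g_best = g_grid[i], distance = res$stats[i, 1],
                 distance_curve = res$stats[, 1], g_grid = g_grid,
                 complexity_at_best = res$stats[i, 2],
                 method = method, lambda_max = res$lambda_max),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf(
    "coupling fit (%s propagator): g_best = %.3g, distance = %.4g, C = %.4g\n",
    x$method, x$g_best, x$distance, x$complexity_at_best))
  invisible(x)
}

#' @export
plot.coupling_fit <- function(x, ...) {
  graphics::plot(x$g_grid, x$distance_curve, type = "l",
                 xlab = "coupling g", ylab = "distance to empirical FC", ...)
  graphics::abline(v = x$g_best, col = 2, lty = 2)
  invisible(x)
}
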