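# Descriptive graph statistics: density, reciprocity, degrees, Newman
# modularity and rich-club analysis.

#' Link density
#'
#' `L / (N (N - 1))` for directed graphs, `2L / (N (N - 1))` for undirected.
#'
#' @param g a [netgraph].
#' @return scalar in `[0, 1]`.
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  n <- n_nodes(g)
  if (n < 2L) stop("density needs at least 2 nodes")
  sum(g$adjacency) / (n * (n - 1))
}

#' Reciprocity
#'
#' Fraction of directed links whose reverse link also exists; identically 1
#' for undirected graphs.
#'
#' @param g a [netgraph].
#' @return scalar in `[0, 1]`.
#' @export
reciprocity <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  if (!g$directed) return(1)
  a <- g$adjacency
  if (sum(a) == 0) return(NaN)
  sum(a * t(a)) / sum(a)
}

#' Node degrees
#'
#' @param g a [netgraph].
#' @return list with `in_degree`, `out_degree` and `total` (their sum; for
#'   undirected graphs all three coincide with the plain degree).
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  indeg <- colSums(g$adjacency)
  outdeg <- rowSums(g$adjacency)
  list(in_degree = indeg, out_degree = outdeg,
       total = if (g$directed) indeg + outdeg else outdeg)
}

# undirected simple graph: link if either direction present
.symmetrise <- function(g) {
  if (!g$directed) return(g$adjacency)
  pmax(g$adjacency, t(g$adjacency))
}

#' Newman-Girvan modularity
#'
#' `q = sum_r (e_rr - a_r^2)` where `e_rr` is the fraction of links inside
#' community `r` and `a_r` the fraction of link endpoints attached to it.
#' Depends only on the per-block link counts `L_rs`, so it is conserved
#' exactly by [modularity_preserving_graph()]. Directed graphs are
#' symmetrised first.
#'
#' @param g a [netgraph].
#' @param p a [partition] covering all nodes.
#' @return scalar `q` (0 for the trivial one-community partition).
#' @export
newman_modularity <- function(g, p) {
  stopifnot(inherits(g, "netgraph"))
  if (length(p) != n_nodes(g)) stop("partition does not cover all nodes")
  a <- .symmetrise(g)
  comm <- as.integer(p)
  K <- max(comm)
  L <- sum(a) / 2
  if (L == 0) stop("graph has no links")
  q <- 0
  for (r in seq_len(K)) {
    ir <- comm == r
    l_rr <- sum(a[ir, ir]) / 2
    d_r <- sum(a[ir, ])
    q <- q + l_rr / L - (d_r / (2 * L))^2
  }
  q
}

#' Rich-club profile
#'
#' For each degree threshold `k`, the rich-club coefficient
#' `phi(k) = 2 E_{>k} / (n_{>k} (n_{>k} - 1))`: the density of the subgraph
#' spanned by nodes of total degree greater than `k` (on the symmetrised
#' graph; total degree is in + out on the original directed graph). Raw
#' coefficients rise mechanically with `k`, so they are normalised by the
#' mean profile of an ensemble of degree-preserving rewired graphs;
#' `phi_norm > 1` marks denser-than-chance hub interconnectivity.
#'
#' Membership rule: the rich-club members are all nodes of degree greater
#' than `k*`, the smallest threshold from which the normalised coefficient
#' exceeds 1 at every larger defined threshold (a persistence rule; the
#' ensemble size and seed are recorded in the result for auditability).
#' Thresholds with fewer than 2 qualifying nodes are undefined (`NA`), never
#' zero-filled.
#'
#' @param g a [netgraph] with maximum total degree `>= 2`.
#' @param null_ensemble_size rewired graphs in the normalising ensemble.
#' @param seed optional integer seed.
#' @param iteration_factor rewiring intensity, see
#'   [rewire_preserving_degrees()].
#' @return object of class `rich_club`: list with `degrees`, `phi`,
#'   `phi_norm`, `phi_null_mean`, `members`, `k_star`, `null_ensemble_size`,
#'   `seed`.
#' @export
rich_club_profile <- function(g, null_ensemble_size = 100, seed = NULL,
                              iteration_factor = 10) {
  stopifnot(inherits(g, "netgraph"))
  deg <- node_degrees(g)$total
  if (max(deg) < 2) stop("maximum total degree must be at least 2")
  ks <- 0:(max(deg) - 1L)
  phi_of <- function(graph) {
    d <- node_degrees(graph)$total
    s <- .symmetrise(graph)
    vapply(ks, function(k) {
      keep <- d > k
      nk <- sum(keep)
      if (nk < 2L) return(NA_real_)
      sum(s[keep, keep]) / (nk * (nk - 1))
    }, numeric(1))
  }
  phi <- phi_of(g)
  if (all(is.na(phi))) stop("degenerate profile: no threshold with 2+ nodes")
  .seed_rng(seed)
  null_sum <- numeric(length(ks))
  null_cnt <- numeric(length(ks))
  for (b in seq_len(null_ensemble_size)) {
    ph <- phi_of(rewire_preserving_degrees(g, iteration_factor))
    ok <- !is.na(ph)
    null_sum[ok] <- null_sum[ok] + ph[ok]
    null_cnt[ok] <- null_cnt[ok] + 1
  }
  null_mean <- ifelse(null_cnt > 0, null_sum / null_cnt, NA_real_)
  phi_norm <- phi / null_mean
  defined <- !is.na(phi_norm) & is.finite(phi_norm)
  k_star <- NA_integer_
  for (idx in seq_along(ks)) {
    later <- defined & seq_along(ks) >= idx
    if (any(later) && all(phi_norm[later] > 1)) {
      k_star <- ks[idx]
      break
    }
  }
  members <- if (is.na(k_star)) integer(0) else which(deg > k_star)
  structure(list(degrees = ks, phi = phi, phi_norm = phi_norm,
                 phi_null_mean = null_mean, members = members,
                 k_star = k_star,
                 null_ensemble_size = null_ensemble_size, seed = seed),
            class = "rich_club")
}

#' @export
print.rich_club <- function(x, ...) {
  cat(sprintf("rich-club profile over k = 0..%d (%d nulls)\n",
              max(x$degrees), x$null_ensemble_size))
  if (is.na(x$k_star)) {
    cat("no persistent rich-club detected\n")
  } else {
    cat(sprintf("k* = %d; %d member nodes\n", x$k_star, length(x$members)))
  }
  invisible(x)
}

#' @export
plot.rich_club <- function(x, ...) {
  graphics::plot(x$degrees, x$phi_norm, type = "b", pch = 16,
                 xlab = "degree threshold k",
                 ylab = expression(phi(k) / phi[null](k)), ...)
  graphics::abline(h = 1, lty = 2)
  if (!is.na(x$k_star)) graphics::abline(v = x$k_star, col = 2, lty = 3)
  invisible(x)
}

#' Top-degree hub nodes
#'
#' The nodes whose total degree exceeds the `1 - fraction` quantile of the
#' degree sequence: a simple hub set for lesion experiments, matching the
#' protocol of removing only the small fraction of links that interconnect
#' the highest-degree nodes.
#'
#' @param g a [netgraph].
#' @param fraction approximate fraction of nodes to keep (default 0.1, the
#'   top decile).
#' @return integer vector of node indices (1-based).
#' @export
hub_nodes <- function(g, fraction = 0.1) {
  stopifnot(inherits(g, "netgraph"))
  deg <- node_degrees(g)$total
  which(deg > stats::quantile(deg, 1 - fraction))
}

#' Links internal to a node set
#'
#' All links with both endpoints in `members` (ordered pairs for directed
#' graphs, unordered `i < j` pairs otherwise); the links removed by a
#' rich-club lesion.
#'
#' @param g a [netgraph].
#' @param members integer node indices (1-based).
#' @return two-column integer matrix of links (possibly 0 rows).
#' @export
rich_club_links <- function(g, members) {
  stopifnot(inherits(g, "netgraph"))
  members <- as.integer(members)
  if (length(members) && (min(members) < 1 || max(members) > n_nodes(g)))
    stop("members out of node range")
  a <- g$adjacency
  keep <- matrix(FALSE, n_nodes(g), n_nodes(g))
  keep[members, members] <- TRUE
  if (!g$directed) keep[lower.tri(keep)] <- FALSE
  w <- which(a == 1L & keep, arr.ind = TRUE)
  unname(w)
}
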