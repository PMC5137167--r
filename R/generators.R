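# Network generators and surrogate randomisations.
#
# All stochastic generators take an optional `seed`; when given, the global
# RNG is seeded (set.seed) so the same seed reproduces the same adjacency
# exactly. Every generator honours its link-count contract exactly and never
# emits self-loops or duplicate links. Non-integral link targets N*k/2 are
# rounded half-to-even (base round()).

.seed_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.pair_capacity <- function(n, directed) {
  if (directed) n * (n - 1) else n * (n - 1) / 2
}

#' Erdos-Renyi G(N, L) random graph
#'
#' Seeds exactly `l` links between uniformly chosen distinct node pairs of an
#' initially empty graph.
#'
#' @param n node count.
#' @param l link count (unordered pairs if undirected, arcs if directed).
#' @param directed logical.
#' @param seed optional integer seed.
#' @return a [netgraph].
#' @export
random_graph <- function(n, l, directed = FALSE, seed = NULL) {
  l <- round(l)
  if (l < 0 || l > .pair_capacity(n, directed))
    stop("requested ", l, " links but capacity is ", .pair_capacity(n, directed))
  .seed_rng(seed)
  ig <- igraph::sample_gnm(n, l, directed = directed)
  .from_igraph(ig)
}

# Batch rejection sampler: place l distinct links with endpoint probabilities
# proportional to `weight`, drawing both ends independently and discarding
# self-pairs and duplicates (the rank-based preferential attachment rule).
.weighted_gnl <- function(n, l, weight, directed) {
  adj <- matrix(FALSE, n, n)
  placed <- 0L
  p <- weight / sum(weight)
  while (placed < l) {
    b <- max(2L * (l - placed), 256L)
    i <- sample.int(n, b, replace = TRUE, prob = p)
    j <- sample.int(n, b, replace = TRUE, prob = p)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    for (k in seq_along(i)) {
      a <- i[k]; bb <- j[k]
      if (!adj[a, bb]) {
        adj[a, bb] <- TRUE
        if (!directed) adj[bb, a] <- TRUE
        placed <- placed + 1L
        if (placed == l) break
      }
    }
  }
  mode(adj) <- "integer"
  adj
}

#' Scale-free graph by rank-based preferential attachment
#'
#' Nodes ranked `i = 1..n` receive weight `i^-alpha`; link endpoints are drawn
#' independently with these weights and distinct unlinked pairs are kept until
#' `l` links are placed. For large sparse graphs the degree distribution
#' follows a power law with exponent `gamma = (1 + alpha) / alpha`; e.g.
#' `alpha = 0.5` gives `gamma = 3`. `alpha = 0` reduces to a uniform G(N, L)
#' draw.
#'
#' @inheritParams random_graph
#' @param alpha rank exponent, `>= 0` (values in `[0, 1)` give finite-mean
#'   power laws).
#' @export
scale_free_graph <- function(n, l, alpha = 0.5, directed = FALSE, seed = NULL) {
  if (alpha < 0) stop("alpha must be >= 0")
  l <- round(l)
  if (l < 0 || l > .pair_capacity(n, directed))
    stop("requested ", l, " links but capacity is ", .pair_capacity(n, directed))
  .seed_rng(seed)
  w <- seq_len(n)^(-alpha)
  netgraph(.weighted_gnl(n, l, w, directed), directed = directed)
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomises a graph by repeated link switches `(i,j),(i',j') -> (i,j'),(i',j)`
#' that exactly conserve every node's degree (in- and out-degree for directed
#' graphs). Switches that would create self-loops or duplicate links are
#' rejected. The switch step is attempted `iteration_factor * L` times, enough
#' to reach the maximally random graphs with the given degree sequence.
#' Reciprocity of directed graphs is not preserved: everything beyond the
#' degrees is deliberately destroyed.
#'
#' @param g a [netgraph] with at least 2 links.
#' @param iteration_factor switch attempts per link (default 10).
#' @param seed optional integer seed.
#' @return a rewired [netgraph] with identical degree sequences.
#' @export
rewire_preserving_degrees <- function(g, iteration_factor = 10, seed = NULL) {
  stopifnot(inherits(g, "netgraph"))
  if (link_count(g) < 2L) stop("graph must have at least 2 links to rewire")
  .seed_rng(seed)
  niter <- round(iteration_factor * link_count(g))
  ig <- igraph::rewire(.to_igraph(g),
                       with = igraph::keeping_degseq(loops = FALSE,
                                                     niter = niter))
  out <- .from_igraph(ig)
  out$labels <- g$labels
  out
}

# ---- planted modular / hierarchical generators ------------------------------

# level ids: matrix with one column per hierarchy level (coarse -> fine),
# entry = module id of the node at that level.
.level_ids <- function(module_counts, leaf_size) {
  n <- prod(module_counts) * leaf_size
  sizes <- n / cumprod(module_counts)      # module size at each level
  vapply(seq_along(module_counts),
         function(l) as.integer((seq_len(n) - 1L) %/% sizes[l]) + 1L,
         integer(n))
}

# enumerate allowed pairs (i<j) for hierarchy level `lev`:
#   lev in 1..L  : same module at level lev-1 (or any, for lev 1), different at lev
#   lev = L + 1  : same module at level L (within-leaf pairs)
.level_pairs <- function(ids, lev) {
  n <- nrow(ids)
  L <- ncol(ids)
  same_parent <- if (lev == 1L) matrix(TRUE, n, n)
    else outer(ids[, lev - 1L], ids[, lev - 1L], "==")
  mask <- if (lev <= L) same_parent & outer(ids[, lev], ids[, lev], "!=")
    else outer(ids[, L], ids[, L], "==")
  mask[!upper.tri(mask)] <- FALSE
  which(mask, arr.ind = TRUE)
}

#' Hierarchy specification for nested modular generators
#'
#' Describes a nested-modular layout: `module_counts` branching factors from
#' the coarsest level inwards (e.g. `c(4, 4)` = 4 modules of 4 submodules),
#' `leaf_size` nodes per deepest module, and `level_degrees` the mean degree
#' contributed by the links seeded at each level, ordered outermost first
#' (`kappa^1, ..., kappa^{L+1}`; the last entry is the within-leaf degree).
#' `level_exponents` optionally gives the preferential-attachment exponent
#' `gamma > 1` used to centralise the cross-module links at each of the `L`
#' outer levels (`NA` = uniform seeding at that level).
#'
#' @param module_counts integer vector of branching factors.
#' @param leaf_size nodes per deepest module.
#' @param level_degrees numeric vector, length `length(module_counts) + 1`.
#' @param level_exponents optional numeric vector, length
#'   `length(module_counts)`, entries `> 1` or `NA`.
#' @return an object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(module_counts, leaf_size, level_degrees,
                           level_exponents = NULL) {
  module_counts <- as.integer(module_counts)
  if (any(module_counts < 2L)) stop("module_counts must all be >= 2")
  if (leaf_size < 2L) stop("leaf_size must be >= 2")
  if (length(level_degrees) != length(module_counts) + 1L)
    stop("need one level degree per hierarchy level plus the leaf level")
  if (any(level_degrees < 0)) stop("level degrees must be >= 0")
  if (!is.null(level_exponents)) {
    if (length(level_exponents) != length(module_counts))
      stop("need one exponent (or NA) per cross-module level")
    if (any(!is.na(level_exponents) & level_exponents <= 1))
      stop("preferential-attachment exponents must be > 1")
  }
  structure(list(module_counts = module_counts,
                 leaf_size = as.integer(leaf_size),
                 level_degrees = as.numeric(level_degrees),
                 level_exponents = level_exponents,
                 n = prod(module_counts) * as.integer(leaf_size)),
            class = "hierarchy_spec")
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat(sprintf("hierarchy_spec: N=%d (%s x %d), level degrees (%s)%s\n",
              x$n, paste(x$module_counts, collapse = "x"), x$leaf_size,
              paste(x$level_degrees, collapse = ", "),
              if (is.null(x$level_exponents)) "" else
                sprintf(", exponents (%s)",
                        paste(x$level_exponents, collapse = ", "))))
  invisible(x)
}

# Shared engine for the nested modular generators. Per level, exactly
# round(N * kappa_level / 2) links are seeded among the pairs whose lowest
# common level is that level; the per-level pair sets are disjoint, so link
# counts are conserved independently of the seeding rule. Uniform seeding
# draws pairs without replacement; centralised seeding draws endpoints with
# probability ~ rank^-alpha, alpha = 1/(gamma - 1), rank = the node's fixed
# position within its deepest submodule (shared by all levels, so the same
# nodes centralise every level).
.hm_engine <- function(spec, seed) {
  .seed_rng(seed)
  n <- spec$n
  ids <- .level_ids(spec$module_counts, spec$leaf_size)
  nlev <- length(spec$level_degrees)
  adj <- matrix(0L, n, n)
  rank_in_leaf <- (seq_len(n) - 1L) %% spec$leaf_size + 1L
  for (lev in seq_len(nlev)) {
    l_target <- round(n * spec$level_degrees[lev] / 2)
    if (l_target == 0) next
    pairs <- .level_pairs(ids, lev)
    if (l_target > nrow(pairs))
      stop("level ", lev, " needs ", l_target, " links but only ",
           nrow(pairs), " node pairs are available")
    gam <- if (lev <= length(spec$module_counts) && !is.null(spec$level_exponents))
      spec$level_exponents[lev] else NA_real_
    if (is.na(gam)) {
      sel <- pairs[sample.int(nrow(pairs), l_target), , drop = FALSE]
      adj[sel] <- 1L
      adj[sel[, 2:1, drop = FALSE]] <- 1L
    } else {
      alpha <- 1 / (gam - 1)
      w <- rank_in_leaf^(-alpha)
      adj <- .centralised_fill(adj, pairs, l_target, w, n)
    }
  }
  partitions <- lapply(seq_along(spec$module_counts),
                       function(l) partition(ids[, l]))
  list(graph = netgraph(adj, directed = FALSE), partitions = partitions)
}

# Place l_target links on the allowed pair set with endpoint weights w:
# draw node i ~ w over all nodes with allowed partners, then j ~ w over the
# allowed partners of i; reject existing links. Falls back to weighted
# sampling over the remaining free pairs if rejection stalls near capacity.
.centralised_fill <- function(adj, pairs, l_target, w, n) {
  partners <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    partners[[i]] <- c(partners[[i]], j)
    partners[[j]] <- c(partners[[j]], i)
  }
  src <- which(lengths(partners) > 0L)
  psrc <- w[src] / sum(w[src])
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * l_target
  while (placed < l_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    i <- src[sample.int(length(src), 1L, prob = psrc)]
    cand <- partners[[i]]
    j <- if (length(cand) == 1L) cand
      else cand[sample.int(length(cand), 1L, prob = w[cand])]
    if (!adj[i, j]) {
      adj[i, j] <- 1L
      adj[j, i] <- 1L
      placed <- placed + 1L
    }
  }
  if (placed < l_target) {
    free <- pairs[adj[pairs] == 0L, , drop = FALSE]
    pw <- w[free[, 1]] * w[free[, 2]]
    sel <- free[sample.int(nrow(free), l_target - placed, prob = pw), ,
                drop = FALSE]
    adj[sel] <- 1L
    adj[sel[, 2:1, drop = FALSE]] <- 1L
  }
  adj
}

#' Planted-partition modular graph
#'
#' `n` nodes split into `n_modules` equal communities; exactly
#' `round(n * k_int / 2)` links are seeded uniformly among within-module pairs
#' and `round(n * k_ext / 2)` among cross-module pairs.
#'
#' @param n node count (divisible by `n_modules`).
#' @param n_modules number of equal modules.
#' @param k_int mean within-module degree.
#' @param k_ext mean cross-module degree.
#' @param seed optional integer seed.
#' @return list with elements `graph` ([netgraph]) and `partition` (the
#'   planted [partition]).
#' @export
modular_graph <- function(n, n_modules, k_int, k_ext, seed = NULL) {
  if (n %% n_modules != 0L) stop("n must be divisible by n_modules")
  spec <- hierarchy_spec(n_modules, n %/% n_modules, c(k_ext, k_int))
  res <- .hm_engine(spec, seed)
  list(graph = res$graph, partition = res$partitions[[1]])
}

#' Random hierarchical-modular (RHM) graph
#'
#' Nested modular graph with uniformly seeded links at every level (the
#' Arenas-Diaz-Guilera-Perez-Vicente construction): e.g. 256 nodes in 4
#' modules of 4 submodules of 16 nodes with level degrees (5, 6, 13).
#'
#' @param spec a [hierarchy_spec] (exponents, if present, are ignored).
#' @param seed optional integer seed.
#' @return list with `graph` and `partitions` (one [partition] per level,
#'   coarsest first).
#' @export
hm_random_graph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  spec$level_exponents <- NULL
  .hm_engine(spec, seed)
}

#' Centralised hierarchical-modular (CHM) graph
#'
#' As [hm_random_graph()] but the cross-module links at each outer level are
#' routed preferentially through high-rank nodes: endpoints are drawn with
#' probability proportional to `rank^-alpha` with `alpha = 1/(gamma - 1)`,
#' where rank is a single fixed ordering of the nodes within their deepest
#' submodule. The same nodes therefore centralise every level, producing hubs
#' that form local and global rich-clubs while the per-level link counts stay
#' identical to the RHM counterpart.
#'
#' @param spec a [hierarchy_spec] with `level_exponents` set.
#' @param seed optional integer seed.
#' @return list with `graph` and `partitions`.
#' @export
hm_centralised_graph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  if (is.null(spec$level_exponents))
    stop("spec must carry level_exponents for the centralised model")
  .hm_engine(spec, seed)
}

#' Ravasz-Barabasi fractal hierarchical graph
#'
#' Deterministic construction: the generating motif is a central hub plus a
#' ring of `n0 - 1` nodes, each ring node linked to its two ring neighbours
#' and to the hub. At each added level every existing node becomes the centre
#' of a fresh motif copy (gaining its own ring). Finally every branch hub is
#' linked to all non-hub nodes in the lower levels of its own branch, i.e. to
#' every leaf descendant beyond its own ring. `N = n0^levels`.
#'
#' @param n0 motif size (`>= 3`).
#' @param levels hierarchy depth (`>= 1`).
#' @return a deterministic undirected [netgraph].
#' @export
ravasz_barabasi_graph <- function(n0, levels) {
  if (n0 < 3L) stop("motif size n0 must be >= 3")
  if (levels < 1L) stop("levels must be >= 1")
  n0 <- as.integer(n0); levels <- as.integer(levels)
  n_total <- n0^levels
  parent <- integer(n_total)          # 0 = root
  edges_i <- integer(0); edges_j <- integer(0)
  add_motif <- function(centre, ring) {
    # ring lattice of coordination 2 plus spokes to the centre
    k <- length(ring)
    ri <- ring
    rj <- ring[c(2:k, 1)]
    if (k == 2L) { ri <- ring[1]; rj <- ring[2] }   # avoid duplicate 2-ring
    list(i = c(ri, rep(centre, k)), j = c(rj, ring))
  }
  nodes <- 1L
  parent[1L] <- 0L
  current <- 1L
  ring0 <- nodes + seq_len(n0 - 1L)
  parent[ring0] <- 1L
  m <- add_motif(1L, ring0)
  edges_i <- m$i; edges_j <- m$j
  nodes <- nodes + n0 - 1L
  if (levels > 1L) {
    for (lv in 2:levels) {
      existing <- seq_len(nodes)
      for (u in existing) {
        ring <- nodes + seq_len(n0 - 1L)
        parent[ring] <- u
        m <- add_motif(u, ring)
        edges_i <- c(edges_i, m$i); edges_j <- c(edges_j, m$j)
        nodes <- nodes + n0 - 1L
      }
    }
  }
  adj <- matrix(0L, n_total, n_total)
  adj[cbind(edges_i, edges_j)] <- 1L
  adj[cbind(edges_j, edges_i)] <- 1L
  # hub-to-branch links: every leaf connects to all its ancestors beyond the
  # parent (the parent spoke already exists)
  is_leaf <- !(seq_len(n_total) %in% parent)
  for (v in which(is_leaf)) {
    a <- parent[v]
    a <- parent[a]                    # skip the direct parent
    while (a != 0L) {
      adj[v, a] <- 1L; adj[a, v] <- 1L
      a <- parent[a]
    }
  }
  diag(adj) <- 0L
  netgraph(adj, directed = FALSE)
}

#' Modularity-preserving randomisation
#'
#' Redistributes links uniformly at random while conserving, for every
#' community pair (r, s) including r = s, the exact number of links between or
#' within those communities. Degrees (and hubs) are destroyed but the
#' block-count structure, and hence Newman modularity with respect to the
#' given partition, is preserved exactly.
#'
#' @param g a [netgraph].
#' @param p a [partition] covering all nodes of `g`.
#' @param seed optional integer seed.
#' @return a randomised [netgraph] with identical per-block link counts.
#' @export
modularity_preserving_graph <- function(g, p, seed = NULL) {
  stopifnot(inherits(g, "netgraph"))
  if (length(p) != n_nodes(g)) stop("partition does not cover all nodes")
  .seed_rng(seed)
  n <- n_nodes(g)
  comm <- as.integer(p)
  adj <- g$adjacency
  out <- matrix(0L, n, n)
  K <- max(comm)
  for (r in seq_len(K)) {
    for (s in r:K) {
      ir <- which(comm == r)
      is <- which(comm == s)
      if (r == s) {
        block <- adj[ir, ir, drop = FALSE]
        if (g$directed) {
          l_rs <- sum(block)
          cand <- which(row(block) != col(block))
        } else {
          l_rs <- sum(block[upper.tri(block)])
          cand <- which(upper.tri(block))
        }
        if (l_rs > length(cand))
          stop("community ", r, " cannot hold ", l_rs, " links")
        sel <- cand[sample.int(length(cand), l_rs)]
        nb <- matrix(0L, length(ir), length(ir))
        nb[sel] <- 1L
        if (!g$directed) nb <- nb + t(nb)
        out[ir, ir] <- nb
      } else {
        block <- adj[ir, is, drop = FALSE]
        if (g$directed) {
          # each direction's arc count is randomised separately
          l_fwd <- sum(block)
          nb <- matrix(0L, length(ir), length(is))
          nb[sample.int(length(nb), l_fwd)] <- 1L
          out[ir, is] <- nb
          back <- adj[is, ir, drop = FALSE]
          l_bwd <- sum(back)
          nb <- matrix(0L, length(is), length(ir))
          nb[sample.int(length(nb), l_bwd)] <- 1L
          out[is, ir] <- nb
        } else {
          l_rs <- sum(block)
          sel <- sample.int(length(block), l_rs)
          nb <- matrix(0L, nrow(block), ncol(block)); nb[sel] <- 1L
          out[ir, is] <- nb
          out[is, ir] <- t(nb)
        }
      }
    }
  }
  netgraph(out, directed = g$directed)
}

#' Pseudo-connectome fixture generator
#'
#' Emits a centralised hierarchical-modular graph scaled to `n` nodes
#' (4 modules of 4 submodules; `n` must be a multiple of 16 and at least 32)
#' with planted modules and a rich-club, standing in for an empirical
#' connectome in examples and tests. Level degrees are (5, 6, min(13,
#' leaf_size - 2)) with exponents (1.7, 2.0), the configuration used for the
#' 256-node centralised model, capped for small leaves.
#'
#' @param n node count (multiple of 16, `>= 32`).
#' @param seed optional integer seed.
#' @return list with `graph` and `partition` (the 4 top-level modules).
#' @export
pseudo_connectome <- function(n, seed = NULL) {
  if (n < 32L || n %% 16L != 0L) stop("n must be a multiple of 16, >= 32")
  leaf <- n %/% 16L
  spec <- hierarchy_spec(c(4, 4), leaf,
                         c(5, 6, min(13, leaf - 2)),
                         level_exponents = c(1.7, 2.0))
  res <- hm_centralised_graph(spec, seed = seed)
  list(graph = res$graph, partition = res$partitions[[1]])
}

#' Pseudo-empirical functional connectivity
#'
#' The analytic FC of `g` at coupling `g_coupling`, perturbed by symmetric
#' zero-mean Gaussian noise of standard deviation `noise_sd`, with the
#' diagonal reset to 1 and values clipped to `[-1, 1]`. A stand-in for an
#' empirically measured (e.g. resting-state) correlation matrix.
#'
#' @param g a [netgraph].
#' @param g_coupling coupling strength.
#' @param noise_sd noise standard deviation (0 returns the exact mapping).
#' @param seed optional integer seed.
#' @param method propagator choice, see [estimate_fc()].
#' @return a symmetric correlation matrix.
#' @export
pseudo_empirical_fc <- function(g, g_coupling, noise_sd = 0.02, seed = NULL,
                                method = "exponential") {
  R <- estimate_fc(g, g_coupling, method = method)
  .seed_rng(seed)
  if (noise_sd > 0) {
    n <- nrow(R)
    e <- matrix(0, n, n)
    e[upper.tri(e)] <- stats::rnorm(n * (n - 1) / 2, sd = noise_sd)
    R <- R + e + t(e)
    R[R > 1] <- 1
    R[R < -1] <- -1
    diag(R) <- 1
  }
  R
}
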