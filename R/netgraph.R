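#' Binary network (connectome) objects
#'
#' A `netgraph` is a binary, optionally directed graph stored as a dense 0/1
#' adjacency matrix. Entry `adjacency[i, j] = 1` means a link *from* node `i`
#' *to* node `j` (for directed graphs, "i sends a projection to j");
#' undirected graphs are stored symmetrically. Self-loops and weights are not
#' allowed: connectome datasets handled here are binarised wiring diagrams.
#'
#' @param adjacency square numeric matrix with entries in `{0, 1}` and zero
#'   diagonal.
#' @param directed logical; if `NULL` (default) directedness is auto-detected:
#'   a symmetric adjacency is stored as undirected. Requesting
#'   `directed = FALSE` on an asymmetric matrix is an error.
#' @param labels optional character vector of unique node names.
#'
#' @return An object of class `netgraph`: a list with elements `adjacency`
#'   (integer matrix), `directed` (logical) and `labels` (character or `NULL`).
#'
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
#' g <- netgraph(a)
#' n_nodes(g)
#' link_count(g)
#' @export
netgraph <- function(adjacency, directed = NULL, labels = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix")
  n <- nrow(adjacency)
  if (n < 1L) stop("graph must have at least one node")
  if (anyNA(adjacency)) stop("adjacency contains missing values")
  if (!all(adjacency == 0 | adjacency == 1))
    stop("adjacency entries must be 0 or 1 (binary connectomes only)")
  if (any(diag(adjacency) != 0))
    stop("self-loops are not allowed (diagonal must be zero)")
  sym <- all(adjacency == t(adjacency))
  if (is.null(directed)) {
    directed <- !sym
  } else {
    directed <- isTRUE(directed)
    if (!directed && !sym)
      stop("adjacency is not symmetric; cannot store as undirected")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels must have one entry per node")
    if (anyDuplicated(labels)) stop("labels must be unique")
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- NULL
  structure(list(adjacency = adjacency, directed = directed, labels = labels),
            class = "netgraph")
}

#' @rdname netgraph
#' @param g a `netgraph` object.
#' @export
n_nodes <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  nrow(g$adjacency)
}

#' Number of links in a graph
#'
#' Counts unordered node pairs for undirected graphs and ordered pairs (arcs)
#' for directed graphs.
#'
#' @param g a `netgraph` object.
#' @return integer link count.
#' @export
link_count <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  s <- sum(g$adjacency)
  as.integer(if (g$directed) s else s / 2)
}

#' @export
print.netgraph <- function(x, ...) {
  cat(sprintf("netgraph: %d nodes, %d %s links%s\n",
              n_nodes(x), link_count(x),
              if (x$directed) "directed" else "undirected",
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' @export
as.matrix.netgraph <- function(x, ...) {
  m <- x$adjacency
  if (!is.null(x$labels)) dimnames(m) <- list(x$labels, x$labels)
  m
}

# igraph bridge -- used for GraphML I/O, G(N,L) sampling and rewiring.
.to_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(
    g$adjacency, mode = if (g$directed) "directed" else "undirected")
  if (!is.null(g$labels)) igraph::V(ig)$name <- g$labels
  ig
}

.from_igraph <- function(ig) {
  adj <- as.matrix(igraph::as_adjacency_matrix(ig, type = "both", sparse = TRUE))
  adj[adj > 1] <- 1L
  labels <- if ("name" %in% igraph::vertex_attr_names(ig))
    igraph::V(ig)$name else NULL
  netgraph(adj, directed = igraph::is_directed(ig), labels = labels)
}

#' Partition constructor
#'
#' A partition assigns every node to one community. Communities are stored as
#' dense integer ids `1..n_comms`; arbitrary input ids (strings, sparse
#' integers) are re-indexed in order of first appearance.
#'
#' @param assignment vector of community ids, one per node.
#' @return integer vector of class `partition` with dense ids starting at 1.
#' @export
partition <- function(assignment) {
  if (length(assignment) < 1L) stop("empty partition")
  if (anyNA(assignment)) stop("partition contains missing values")
  ids <- match(assignment, unique(assignment))
  structure(as.integer(ids), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes in %d communities (sizes: %s)\n",
              length(x), max(x), paste(tabulate(x), collapse = ", ")))
  invisible(x)
}

# Validate a correlation / FC matrix. Mapping outputs are symmetric with unit
# diagonal; empirical (Fisher-z) matrices may exceed [0,1], which is advisory.
.check_fc <- function(R, tol = 1e-10, advisory_range = TRUE) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("FC must be a square matrix")
  if (anyNA(R)) stop("FC contains missing values")
  if (max(abs(R - t(R))) > tol)
    stop("FC matrix is not symmetric within tolerance ", tol)
  if (advisory_range) {
    off <- R[row(R) != col(R)]
    if (length(off) && (min(off) < -1 - tol || max(off) > 1 + tol))
      warning("FC has off-diagonal entries outside [-1, 1] (z-scored data?); ",
              "consider a wider histogram support")
  }
  invisible(R)
}
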