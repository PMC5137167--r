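#' Read a network from file
#'
#' Supported formats: `"edgelist"` (whitespace-separated integer pairs, one
#' link per line, 0-based node ids, lines starting with `#` ignored),
#' `"dense"` (whitespace-separated 0/1 matrix, row i / column j meaning a link
#' from i to j) and `"graphml"`.
#'
#' Directedness is resolved in this order: the `directed` argument if not
#' `NULL`; a `directed=TRUE/FALSE` token in a leading `#` comment (written by
#' [write_network()], so round-trips are exact); otherwise auto-detection.
#' Auto-detection treats a dense matrix as undirected iff symmetric, and an
#' edge list as undirected when its arcs are fully non-reciprocal or fully
#' reciprocal (each line then names one undirected link).
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"dense"`, `"graphml"`.
#' @param directed logical or `NULL` (auto).
#' @return a [netgraph].
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("edgelist", "dense", "graphml"),
                         directed = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         edgelist = .read_edgelist(path, directed),
         dense = .read_dense(path, directed),
         graphml = .from_igraph(igraph::read_graph(path, format = "graphml")))
}

.parse_header <- function(lines) {
  # leading comment lines may carry n=<int> and directed=<logical>
  hdr <- grep("^\\s*#", lines, value = TRUE)
  out <- list(n = NULL, directed = NULL)
  if (length(hdr)) {
    m <- regmatches(hdr, regexpr("n=[0-9]+", hdr))
    if (length(m) && nzchar(m[1])) out$n <- as.integer(sub("n=", "", m[1]))
    d <- regmatches(hdr, regexpr("directed=(TRUE|FALSE)", hdr))
    if (length(d) && nzchar(d[1])) out$directed <- sub("directed=", "", d[1]) == "TRUE"
  }
  out
}

.read_edgelist <- function(path, directed) {
  lines <- readLines(path)
  hdr <- .parse_header(lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L && is.null(hdr$n))
    stop("edge list is empty and carries no node count header")
  pairs <- matrix(NA_integer_, length(idx), 2)
  for (k in seq_along(idx)) {
    tok <- strsplit(trimws(lines[idx[k]]), "\\s+")[[1]]
    v <- suppressWarnings(as.integer(tok))
    if (length(v) != 2L || anyNA(v) || any(v < 0))
      stop("malformed edge list at line ", idx[k], ": '", lines[idx[k]], "'")
    pairs[k, ] <- v
  }
  n <- if (!is.null(hdr$n)) hdr$n else max(pairs) + 1L
  if (length(idx) && max(pairs) + 1L > n)
    stop("edge list references node ", max(pairs), " but header says n=", n)
  if (length(idx) && any(pairs[, 1] == pairs[, 2]))
    stop("self-loop at line ", idx[which(pairs[, 1] == pairs[, 2])[1]])
  if (is.null(directed)) directed <- hdr$directed
  if (is.null(directed)) {
    # fully non-reciprocal or fully reciprocal arc sets read as undirected
    fwd <- paste(pairs[, 1], pairs[, 2])
    rev <- paste(pairs[, 2], pairs[, 1])
    rec <- fwd %in% rev
    directed <- any(rec) && !all(rec)
  }
  adj <- matrix(0L, n, n)
  adj[pairs + 1L] <- 1L
  if (!directed) adj <- pmax(adj, t(adj))
  netgraph(adj, directed = directed)
}

.read_dense <- function(path, directed) {
  lines <- readLines(path)
  hdr <- .parse_header(lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- lapply(which(keep), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v)) stop("malformed matrix row at line ", i)
    v
  })
  if (!length(rows)) stop("no matrix rows in ", path)
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged matrix rows in ", path)
  adj <- do.call(rbind, rows)
  if (nrow(adj) != ncol(adj)) stop("matrix in ", path, " is not square")
  if (is.null(directed)) directed <- hdr$directed
  netgraph(adj, directed = directed)
}

#' Write a network to file
#'
#' Round-trips exactly through [read_network()]: edge-list and dense files get
#' a `# netgraph n=<N> directed=<...>` comment header so empty graphs,
#' isolated nodes and directedness survive. Node ids on disk are 0-based.
#' Labels are preserved by GraphML only.
#'
#' @param g a [netgraph].
#' @inheritParams read_network
#' @return invisibly, `path`.
#' @export
write_network <- function(g, path, format = c("edgelist", "dense", "graphml")) {
  stopifnot(inherits(g, "netgraph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(.to_igraph(g), path, format = "graphml")
    return(invisible(path))
  }
  hdr <- sprintf("# netgraph n=%d directed=%s", n_nodes(g), g$directed)
  if (format == "edgelist") {
    a <- g$adjacency
    if (!g$directed) a[lower.tri(a)] <- 0L
    w <- which(a == 1L, arr.ind = TRUE)
    body <- sprintf("%d\t%d", w[, 1] - 1L, w[, 2] - 1L)
  } else {
    body <- apply(g$adjacency, 1, paste, collapse = " ")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a node-community partition
#'
#' Two-column whitespace/tab-separated file: node id (0-based integer) and a
#' community label (any token). Community labels are re-indexed densely in
#' order of first appearance along increasing node id.
#'
#' @param path file path.
#' @param n_nodes optional expected node count; mismatch is an error.
#' @return a [partition].
#' @export
read_partition <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = c("integer", "character"))
  if (ncol(tab) != 2L) stop("partition file must have two columns")
  if (anyDuplicated(tab[[1]])) stop("duplicate node id in partition file")
  o <- order(tab[[1]])
  ids <- tab[[1]][o]
  if (!identical(ids, seq_along(ids) - 1L))
    stop("partition node ids must be contiguous 0-based integers")
  if (!is.null(n_nodes) && length(ids) != n_nodes)
    stop("partition covers ", length(ids), " nodes but graph has ", n_nodes)
  partition(tab[[2]][o])
}

#' Write a partition as two-column TSV (0-based node ids)
#' @param p a [partition] (or integer vector).
#' @param path file path.
#' @export
write_partition <- function(p, path) {
  writeLines(sprintf("%d\t%d", seq_along(p) - 1L, as.integer(p)), path)
  invisible(path)
}

#' Read a functional-connectivity matrix from dense text
#'
#' The matrix must be square and symmetric within `tol`. Off-diagonal values
#' outside `[-1, 1]` are accepted with a warning (empirical Fisher-z matrices
#' are legitimate inputs for distance and complexity operations, paired with a
#' suitable histogram support).
#'
#' @param path file path.
#' @param tol symmetry tolerance.
#' @return a symmetric numeric matrix.
#' @export
read_fc_matrix <- function(path, tol = 1e-10) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- lapply(which(keep), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v)) stop("malformed matrix row at line ", i)
    v
  })
  if (!length(rows)) stop("no matrix rows in ", path)
  R <- do.call(rbind, rows)
  if (nrow(R) != ncol(R)) stop("FC matrix in ", path, " is not square")
  .check_fc(R, tol = tol)
  R
}

#' Write a matrix as dense whitespace-separated text
#' @param m numeric matrix.
#' @param path file path.
#' @param digits significant digits to print.
#' @export
write_fc_matrix <- function(m, path, digits = 12) {
  writeLines(apply(m, 1, function(r) paste(signif(r, digits), collapse = " ")),
             path)
  invisible(path)
}
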