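# Analytic structural-to-functional connectivity mapping.
#
# A network of coupled noise-driven units (an Ornstein-Uhlenbeck system on the
# graph) has covariance sigma^2 Q^T Q with propagator Q = (I - g A^T)^-1,
# the geometric accumulation of influence over walks of every length. The
# linear propagator diverges as g -> 1 (after spectral normalisation); the
# communicability variant Q = exp(g A^T) weights walks of length l by 1/l!
# instead of geometrically and stays finite for every coupling, saturating at
# global synchrony. Relaxation and noise scales are fixed at alpha = sigma = 1:
# they only rescale the coupling axis.

#' Spectral normalisation of an adjacency matrix
#'
#' Divides the adjacency matrix by its spectral radius `lambda_max` (largest
#' eigenvalue for undirected graphs; largest eigenvalue modulus for directed
#' ones), so that couplings are comparable across networks of different size
#' and density and the linear propagator converges for `g` in `[0, 1)`.
#'
#' @param g a [netgraph].
#' @param tol smallest admissible `lambda_max`; acyclic graphs (e.g. DAGs,
#'   empty graphs) have spectral radius 0 and cannot be normalised.
#' @return list with `matrix` (the normalised adjacency, spectral radius 1)
#'   and `lambda_max`.
#' @export
spectral_normalize <- function(g, tol = 1e-9) {
  stopifnot(inherits(g, "netgraph"))
  A <- g$adjacency
  storage.mode(A) <- "double"
  lam <- if (g$directed) {
    max(Mod(eigen(A, only.values = TRUE)$values))
  } else {
    max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (lam <= tol)
    stop("spectral radius is ", signif(lam, 3),
         "; graph has no cycles or reciprocal pairs and cannot be normalised")
  list(matrix = A / lam, lambda_max = lam)
}

.propagator <- function(matrix, method, g) {
  structure(list(matrix = matrix, method = method, g = g),
            class = "propagator")
}

#' @export
print.propagator <- function(x, ...) {
  cat(sprintf("propagator: %s, g = %g, %d nodes\n",
              x$method, x$g, nrow(x$matrix)))
  invisible(x)
}

#' Linear-Gaussian propagator
#'
#' `Q = (I - g * t(A_norm))^-1`, the resolvent accumulating influence along
#' walks of all lengths with geometric weights `g^l`. Defined for normalised
#' coupling `0 <= g < 1`; at `g >= 1` the underlying diffusion diverges.
#'
#' @param norm_adjacency spectrally normalised adjacency (see
#'   [spectral_normalize()]).
#' @param g normalised coupling in `[0, 1)`.
#' @return a `propagator` object.
#' @export
linear_propagator <- function(norm_adjacency, g) {
  if (g < 0) stop("coupling g must be >= 0")
  if (g >= 1)
    stop("linear propagator diverges for g >= 1 (normalised coupling); ",
         "use the exponential propagator for strong coupling")
  n <- nrow(norm_adjacency)
  Q <- solve(diag(n) - g * t(norm_adjacency))
  .propagator(Q, "linear", g)
}

#' Communicability (matrix-exponential) propagator
#'
#' `Q = exp(g * t(A_norm))`: walks of length `l` are weighted by `g^l / l!`,
#' so long walks are damped factorially and the propagator is finite for every
#' coupling `g >= 0`.
#'
#' @inheritParams linear_propagator
#' @param g coupling `>= 0` (unbounded).
#' @export
exponential_propagator <- function(norm_adjacency, g) {
  if (g < 0) stop("coupling g must be >= 0")
  M <- t(norm_adjacency)
  Q <- if (isSymmetric(unname(M), tol = 1e-12)) {
    e <- eigen(M, symmetric = TRUE)
    tcrossprod(e$vectors * rep(exp(g * e$values / 2), each = nrow(M)))
  } else {
    as.matrix(Matrix::expm(g * M))
  }
  .propagator(Q, "exponential", g)
}

#' Covariance matrix from a propagator
#'
#' `Sigma = t(Q) %*% Q` (unit noise variance): the Gram matrix of propagated
#' influences, symmetric positive semi-definite by construction.
#'
#' @param prop a `propagator`.
#' @return symmetric PSD covariance matrix.
#' @export
covariance_from_propagator <- function(prop) {
  stopifnot(inherits(prop, "propagator"))
  crossprod(prop$matrix)
}

#' Correlation matrix from a covariance matrix
#'
#' Standard normalisation `r_ij = cov_ij / sqrt(cov_ii * cov_jj)`.
#'
#' @param cov symmetric covariance matrix with strictly positive diagonal.
#' @return correlation matrix with unit diagonal.
#' @export
correlation_from_covariance <- function(cov) {
  d <- diag(cov)
  if (any(d <= 0)) stop("covariance diagonal must be strictly positive")
  R <- cov / sqrt(outer(d, d))
  diag(R) <- 1
  R
}

#' Analytic functional connectivity of a structural connectome
#'
#' Composition normalise -> propagator -> covariance -> correlation. For the
#' default exponential (communicability) propagator the correlations grow
#' monotonically with `g` on connected graphs, from the identity at `g = 0`
#' to global synchrony (all `r -> 1`) at strong coupling; disconnected
#' components stay exactly uncorrelated at every coupling.
#'
#' @param g a [netgraph] with positive spectral radius.
#' @param g_coupling coupling strength (normalised scale; the transition to
#'   synchrony typically falls in `[0, 10)`). The linear method requires
#'   `g_coupling < 1`.
#' @param method `"exponential"` (default) or `"linear"`.
#' @return correlation matrix (unit diagonal; off-diagonals in `[0, 1]` for
#'   binary graphs).
#' @examples
#' k2 <- netgraph(matrix(c(0, 1, 1, 0), 2))
#' estimate_fc(k2, 0.25)[1, 2]   # tanh(0.5)
#' @export
estimate_fc <- function(g, g_coupling,
                        method = c("exponential", "linear")) {
  method <- match.arg(method)
  sn <- spectral_normalize(g)
  prop <- if (method == "exponential")
    exponential_propagator(sn$matrix, g_coupling)
  else linear_propagator(sn$matrix, g_coupling)
  correlation_from_covariance(covariance_from_propagator(prop))
}
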