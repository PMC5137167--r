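# Functional complexity of a correlation matrix.
#
# The statistic measures how far the distribution p(r_ij) of pairwise
# correlations is from a single narrow peak: it vanishes both at independence
# (all r ~ 0) and at global synchrony (all r ~ 1), and is maximal for a broad
# (uniform) distribution -- the signature of complex intermediate dynamics.

.upper_values <- function(R) {
  if (nrow(R) < 2L) stop("need at least 2 nodes")
  R[upper.tri(R)]
}

# bin assignment: m equal-width bins on [lo, hi), final bin closed; values
# outside the support are clipped to the nearest edge
.bin_index <- function(v, m, support) {
  lo <- support[1]; hi <- support[2]
  v <- pmin(pmax(v, lo), hi)
  pmin(floor((v - lo) / ((hi - lo) / m)) + 1L, m)
}

#' Distribution of pairwise correlations
#'
#' Histogram of the `N(N-1)/2` upper-triangle off-diagonal entries of a
#' correlation matrix (the diagonal `r_ii = 1` carries no pairwise
#' information and is discarded). Bins are equal-width and half-open
#' `[lo, hi)` with the final bin closed; out-of-support values are clipped.
#'
#' @param R correlation matrix (symmetric, `N >= 2`).
#' @param m number of bins (`>= 2`).
#' @param support closed interval, default `c(0, 1)`; use `c(-1, 1)` for
#'   empirical (possibly z-scored) FC.
#' @return object of class `pairwise_distribution`: list with `masses`
#'   (probabilities summing to 1), `breaks`, `m`, `support`.
#' @export
pairwise_distribution <- function(R, m = 50, support = c(0, 1)) {
  if (m < 2) stop("need at least 2 bins")
  m <- as.integer(m)
  v <- .upper_values(R)
  masses <- tabulate(.bin_index(v, m, support), m) / length(v)
  structure(list(masses = masses,
                 breaks = seq(support[1], support[2], length.out = m + 1L),
                 m = m, support = support),
            class = "pairwise_distribution")
}

#' @export
print.pairwise_distribution <- function(x, ...) {
  cat(sprintf("pairwise correlation distribution: %d bins on [%g, %g]\n",
              x$m, x$support[1], x$support[2]))
  invisible(x)
}

.complexity_from_masses <- function(p) {
  m <- length(p)
  cm <- 2 * (m - 1) / m
  1 - sum(abs(p - 1 / m)) / cm
}

#' Functional complexity
#'
#' `C = 1 - (1/C_m) * sum_mu |p_mu - 1/m|` with normaliser
#' `C_m = 2(m - 1)/m`, the total deviation of a Dirac-delta histogram from
#' uniformity. `C = 0` when all correlations fall in one bin (independence or
#' global synchrony), `C = 1` for an exactly uniform distribution.
#'
#' @inheritParams pairwise_distribution
#' @return scalar in `[0, 1]`.
#' @examples
#' functional_complexity(diag(10))       # independence: 0
#' @export
functional_complexity <- function(R, m = 50, support = c(0, 1)) {
  .complexity_from_masses(pairwise_distribution(R, m, support)$masses)
}

#' Mean pairwise correlation
#'
#' Arithmetic mean of the upper-triangle off-diagonal entries; tracks the
#' transition from independence (0) to global synchrony (1).
#'
#' @param R correlation matrix.
#' @return scalar.
#' @export
mean_correlation <- function(R) {
  mean(.upper_values(R))
}

#' Normed-entropy complexity
#'
#' Shannon entropy of the correlation histogram divided by `log(m)`: 0 for a
#' delta distribution, 1 for uniform. Provided as the classical alternative
#' to [functional_complexity()] for comparison; the absolute-deviation form is
#' more discriminative and more robust to the bin count.
#'
#' @inheritParams pairwise_distribution
#' @return scalar in `[0, 1]`.
#' @export
entropy_complexity <- function(R, m = 50, support = c(0, 1)) {
  p <- pairwise_distribution(R, m, support)$masses
  p <- p[p > 0]
  -sum(p * log(p)) / log(m)
}

#' Euclidean distance between two FC matrices
#'
#' Frobenius-style norm over the off-diagonal entries only (the unit diagonal
#' is ignored). Used to fit the coupling of an analytic FC to an empirical
#' one.
#'
#' @param R1,R2 equal-dimension matrices.
#' @return non-negative scalar.
#' @export
fc_distance <- function(R1, R2) {
  if (!all(dim(R1) == dim(R2))) stop("FC matrices differ in dimension")
  d <- (R1 - R2)[row(R1) != col(R1)]
  sqrt(sum(d^2))
}
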