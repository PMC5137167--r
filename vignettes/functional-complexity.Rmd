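---
title: "Functional complexity of network dynamics on structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional complexity of network dynamics on structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(netcomplexity)
```

## The question

Neural connectomes — the wiring diagrams of nervous systems, from the
*C. elegans* neuronal network to corticocortical tract matrices — share two
structural signatures: a modular organisation, and a set of highly connected
hub regions that are densely interlinked among themselves (a *rich-club*).
This package implements a pipeline for asking what those features buy
dynamically: how rich is the repertoire of correlation structures that a
given wiring diagram can host as its coupling is tuned from independence to
global synchrony?

The pipeline has three layers:

1. an **analytic mapping** from a binary structural connectivity (SC) matrix
   to a functional connectivity (FC) matrix of pairwise correlations, with
   the coupling strength $g$ as the only free parameter;
2. a scalar **functional complexity** statistic $C$ on the distribution of
   those correlations; and
3. **generators and surrogates** — modular, hierarchical-modular and
   centralised hierarchical-modular graph models, degree-preserving and
   modularity-preserving randomisations — plus experiment drivers that sweep
   $g$, compare against surrogate ensembles, lesion rich-club links, and fit
   $g$ to an empirical FC matrix.

## The structural-to-functional mapping

Consider $N$ units coupled through the binary adjacency matrix $A$
($A_{ij} = 1$ when $i$ projects to $j$), each driven by unit-variance
Gaussian noise and relaxing at unit rate (an Ornstein–Uhlenbeck system on the
graph; the relaxation and noise scales only rescale the coupling axis, so
both are fixed at 1). The stationary covariance is

$$\Sigma = Q^\top Q, \qquad Q = \left(\mathbb{1} - g\,A^\top\right)^{-1}
        = \sum_{l=0}^{\infty} (g\,A^\top)^l ,$$

so $Q_{ji}$ accumulates the influence of $j$ on $i$ over walks of every
length, weighted geometrically by $g^l$. The transpose matters for directed
graphs: a node's activity is driven by its *inputs*. Correlations follow by
the usual normalisation $r_{ij} = \Sigma_{ij}/\sqrt{\Sigma_{ii}\Sigma_{jj}}$.

Two practical points:

* **Spectral normalisation.** The series diverges when $g$ reaches the
  inverse spectral radius of $A$. `spectral_normalize()` divides $A$ by its
  largest eigenvalue $\lambda_{max}$ (largest eigenvalue modulus for directed
  graphs), making couplings comparable across networks and placing the linear
  regime at $g \in [0, 1)$. Graphs without cycles or reciprocal pairs have
  $\lambda_{max} = 0$ and are rejected explicitly.
* **The exponential (communicability) propagator.** Geometric weighting of
  walk lengths is unrealistic for neural signalling, where information is
  attenuated and transformed along the way, and it diverges at $g \ge 1$.
  Replacing the coefficients $g^l$ by $g^l/l!$ gives
  $Q = e^{\,g A^\top}$ — the communicability matrix of the graph — which is
  finite for every coupling and saturates smoothly into global synchrony.
  This is the default `method = "exponential"` of `estimate_fc()` and the
  scans; after normalisation the transition to synchrony falls inside
  $g \in [0, 10)$ for most networks, the default grid (step 0.1,
  configurable).

On the two-node chain both propagators have closed forms
($r_{12} = \tanh 2g$ exponential, $r_{12} = 2g/(1+g^2)$ linear); the test
suite holds the implementation to those at $10^{-12}$.

Numerically, symmetric normalised adjacencies are exponentiated through
their eigendecomposition (and the coupling scans reuse one decomposition for
the whole grid, since $Q^\top Q = V e^{2g\Lambda} V^\top$); non-symmetric
(directed) matrices go through `Matrix::expm`. Matrix comparisons in the
tests use a $10^{-9}$ tolerance.

```{r closed-form}
k2 <- netgraph(matrix(c(0, 1, 1, 0), 2))
c(mapped = estimate_fc(k2, 0.25)[1, 2], closed_form = tanh(0.5))
```

## The functional complexity statistic

At $g = 0$ all pairwise correlations sit at 0; at strong coupling they all
sit at 1. In both extremes the distribution $p(r_{ij})$ is a single narrow
peak. Complex intermediate regimes — clusters that are internally coherent
but mutually distinct — show up as a *broad* distribution. Functional
complexity measures that broadness as the distance from uniformity: with
$p(r_{ij})$ histogrammed into $m$ bins,

$$C = 1 - \frac{1}{C_m} \sum_{\mu=1}^{m}
      \left| p_\mu - \tfrac{1}{m} \right|,
      \qquad C_m = \frac{2(m-1)}{m},$$

where $C_m$ is the deviation of a Dirac-delta histogram from uniformity. So
$C = 0$ at independence and at global synchrony, and $C = 1$ for an exactly
uniform correlation histogram. Compared with the normed-entropy alternative
(provided as `entropy_complexity()` for reference), the absolute-deviation
form discriminates topologies better and is less sensitive to the bin count.

Conventions, all exposed as arguments:

* diagonal entries $r_{ii} = 1$ are discarded; only the $N(N-1)/2$
  upper-triangle values are binned (mapping outputs are symmetric);
* bins are equal-width and half-open $[\text{lo}, \text{hi})$ with the final
  bin closed; values outside the support are clipped to the nearest edge;
* default $m = 50$ bins on support $[0, 1]$: a binary connectome mapped
  through the propagators has $r_{ij} \in [0, 1]$, and at $N = 256$ (the
  benchmark generator size) 50 bins keep $\ge 10$ expected pairs per bin.
  Empirical, possibly Fisher-z-transformed FC matrices can use
  `support = c(-1, 1)` (and are accepted with a warning by the readers when
  they exceed $[-1,1]$);
* histogram masses are probabilities (sum 1), not densities, and the uniform
  reference is $1/m$.

## Network models

All generators are exact about their link counts (targets $N\kappa/2$ are
rounded half-to-even), never emit self-loops or duplicate links, and are
reproducible from a seed.

* `random_graph(n, l)` — $G(N, L)$.
* `scale_free_graph(n, l, alpha)` — rank-based preferential attachment:
  endpoint probabilities $\propto i^{-\alpha}$ over node ranks, giving
  power-law degrees with $\gamma = (1+\alpha)/\alpha$ in the sparse limit
  ($\alpha = 0.5 \Rightarrow \gamma = 3$).
* `modular_graph(n, n_modules, k_int, k_ext)` — planted partition with exact
  within/between link counts.
* `hm_random_graph(spec)` — nested hierarchy (e.g. 256 nodes = 4 modules
  × 4 submodules × 16 nodes) with uniformly seeded links at every level;
  level degrees $(\kappa^1, \kappa^2, \kappa^3) = (5, 6, 13)$ is the
  classical benchmark configuration.
* `hm_centralised_graph(spec)` — same skeleton and the same per-level link
  counts, but cross-module endpoints are drawn with probability
  $\propto \text{rank}^{-\alpha_\ell}$. The published exponents are
  $\gamma^1 = 1.7$ and $\gamma^2 = 2.0$; since the sparse-limit law
  $\gamma = (1+\alpha)/\alpha$ cannot produce $\gamma < 2$, the generator
  inverts the smooth extension $\alpha = 1/(\gamma - 1)$, which reproduces
  the law where it holds and extends it continuously below $\gamma = 2$.
  A single fixed within-submodule ranking is shared by all levels, so the
  same nodes centralise local and global traffic — that choice is what makes
  the hubs of different levels coincide and form a cross-level rich-club
  (the construction is ambiguous on this point; re-drawing ranks per level
  produces weaker rich-clubs).
* `ravasz_barabasi_graph(n0, levels)` — the deterministic fractal model: a
  hub-plus-ring motif, each node becoming the centre of a motif copy at each
  added level ("first neighbours" on the ring is read as a ring lattice of
  coordination 2), and finally every branch hub wired to all non-hub nodes
  in its branch's lower levels — implemented as each non-leaf node linking to
  every leaf descendant beyond its own ring. This reading was validated
  against the published size and density of the $(N_0 = 6,\ 3)$ instance
  ($N = 216$, $\rho = 0.031$); the alternative copy-and-connect reading
  gives a visibly different density and was rejected.
* Surrogates: `rewire_preserving_degrees()` (Maslov–Sneppen switching,
  $10L$ attempted switches by default, via igraph; destroys modules, keeps
  hubs) and `modularity_preserving_graph()` (uniform redistribution
  conserving every block count $L_{rs}$ exactly; destroys hubs, keeps
  modules). Because the Newman–Girvan modularity
  $q = \sum_r (e_{rr} - a_r^2)$ depends only on the $L_{rs}$, the latter
  conserves $q$ to machine precision — a testable invariant.

`pseudo_connectome()` scales the centralised model to a requested size (4×4
modules, leaf degree capped at the leaf capacity) as a fixture standing in
for empirical connectomes; `pseudo_empirical_fc()` perturbs an analytic FC
with symmetric Gaussian noise, mimicking a measured resting-state matrix.
These fixtures reproduce the *structural* ingredients (modules, rich-club,
planted partition) but none of the biological realities — weighted and
spatially embedded connections, measurement artefacts, inter-subject
variability — so tests passing on them validate the machinery, not claims
about any particular brain.

## Experiments

`coupling_scan()` sweeps the grid and records the mean correlation
$\langle r \rangle$ and the complexity $C$ per coupling; `peak_complexity()`
takes the grid argmax (ties to the smallest $g$ — no continuous optimiser,
keeping runs deterministic), and `synchronization_coupling()` interpolates
the crossing of $\langle r \rangle = 0.85$.

```{r scan}
res <- pseudo_connectome(128, seed = 1)
scan <- coupling_scan(res$graph)
scan
plot(scan)
```

`surrogate_comparison()` scans ensembles of rewired, modularity-preserving
and random surrogates on a shared grid. Defaults are desk-scale (100
realisations; the benchmark studies used 1000) and every report records the
counts used. Whether "peak complexity" of an ensemble means the peak of the
mean curve or the mean of per-realisation peaks is ambiguous, so both are
reported. Per-realisation seeds are derived from the base seed, making
results independent of execution order.

```{r surrogates}
cmp <- surrogate_comparison(res$graph, res$partition, n_realisations = 10,
                            seed = 2)
cmp
```

The ordering — original above both single-feature surrogates, random lowest —
is the core claim: modules and hubs each contribute complexity, and their
combination contributes most.

`lesion_study()` removes all links among a set of hub nodes, re-evaluates
$C$ at the intact network's optimal coupling $g^\*$, and compares against
random lesions of equal size drawn uniformly from the non-rich-club links
(never touching rich-club links; the reported probability is the fraction of
random lesions *strictly* below the targeted lesion's complexity). Lesioned
and surrogate graphs are re-normalised by their own $\lambda_{max}$ by
default — the normalisation rule is stated unconditionally, so we apply it
to every graph we map; `renormalise = FALSE` freezes the intact network's
$\lambda_{max}$ for sensitivity analysis.

On membership: `rich_club_profile()` computes $\phi(k)$ (density among nodes
of total degree $> k$, on the symmetrised graph) normalised by a
degree-preserving rewired ensemble, and applies a persistence rule for
membership ($k^\*$ = the smallest threshold from which $\phi_{norm} > 1$ at
every larger defined threshold). On strongly modular graphs the rewired null
is depressed at *every* threshold, so the persistence rule can admit most of
the network; for lesion experiments the hub set should be chosen
deliberately — `hub_nodes()` (top degree decile) matches the protocol of
removing only the small fraction of hub–hub links, and is what the examples
and tests use.

```{r lesion}
les <- lesion_study(res$graph, hub_nodes(res$graph), n_random = 100, seed = 3)
les
```

`fit_coupling()` fits the single free parameter $g$ to an empirical FC by
minimising the Euclidean distance over off-diagonal entries along the grid;
with the fixture generator the generating coupling is recovered within one
grid step under realistic noise.

```{r fit}
fc <- pseudo_empirical_fc(res$graph, 2.0, noise_sd = 0.02, seed = 4)
fit_coupling(res$graph, fc)
```

## Degenerate inputs, tie-breaks and tolerances

* Graphs that cannot be spectrally normalised (no cycles) raise an error
  rather than returning an arbitrary FC.
* The linear propagator refuses $g \ge 1$; scans with `method = "linear"`
  require the whole grid below 1.
* FC symmetry is checked at $10^{-10}$; PSD checks and matrix-identity tests
  run at $10^{-9}$; the complexity statistic is validated against a
  brute-force per-value binning oracle at $10^{-12}$.
* Grid ties in `peak_complexity()` resolve to the smallest coupling;
  `synchronization_coupling()` errors when the threshold is never reached.
* Rich-club thresholds with fewer than two qualifying nodes are `NA`, never
  zero, and the normalising ensemble size and seed are stored in the result.

## Problem sizes used in the checks

The bundled tests and the acceptance script run at the published benchmark
scales where those are cheap (N = 256 hierarchical models, N = 1000 random
and scale-free graphs, full $g$ grid of 100 couplings) and at reduced
realisation counts chosen as sensible desk-scale defaults elsewhere
(20–30 realisations per ensemble where the original studies used 100–1000;
100–1000 random lesions where they used 100,000). Every driver reports the
counts it used.

## Limitations

The mapping estimates time-averaged correlations of a linear
(or factorially damped) diffusion; it says nothing about temporal structure,
nonlinear local dynamics, or directed/effective connectivity, and weighted
connectomes are out of scope (inputs are binarised). The complexity statistic
inherits the usual histogram caveats — with very small $N$ the
$N(N-1)/2$ pairs cannot fill 50 bins, and $m$ should be reduced accordingly.
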