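# netcomplexity

Functional complexity of network dynamics on structural connectomes.

Neural connectomes — *C. elegans* neuronal wiring, cat and macaque
corticocortical tract matrices, human DTI connectomes — are modular networks
whose cross-module traffic is centralised through a small set of densely
interlinked hubs (a rich-club). `netcomplexity` is a toolkit for quantifying
what that architecture buys dynamically. It is aimed at researchers in
network and systems neuroscience who want a fast, simulation-free pipeline
from a binary wiring diagram to a scalar measure of how rich the correlation
structures it can host are.

## The method

Given a binary structural connectivity (SC) matrix `A` (spectrally
normalised, `A <- A / lambda_max`) and a global coupling `g`, the stationary
covariance of a noise-driven linear diffusion on the graph is

    Sigma = t(Q) %*% Q

with the propagator `Q` accumulating influence over walks of all lengths:

* linear (Ornstein–Uhlenbeck): `Q = solve(I - g * t(A))`, valid for
  `g` in `[0, 1)`;
* exponential (communicability, the default): `Q = expm(g * t(A))`, walks of
  length `l` damped by `1/l!`, finite for every `g` and saturating smoothly
  into global synchrony.

Correlations `r_ij = Sigma_ij / sqrt(Sigma_ii Sigma_jj)` form the analytic
functional connectivity (FC). Its **functional complexity** is the distance
of the correlation histogram (`m` bins, default 50) from uniformity:

    C = 1 - (1 / C_m) * sum_mu | p_mu - 1/m |,    C_m = 2 (m - 1) / m

so `C = 0` at independence (`g = 0`) and at global synchrony (large `g`),
and `C = 1` for a maximally broad correlation distribution. Sweeping `g`
traces the transition; the peak of `C` is the headline statistic.

Around this core the package provides exact-contract graph generators
(Erdős–Rényi, rank-preferential scale-free, planted modular, random and
centralised hierarchical-modular, deterministic Ravasz–Barabási), surrogate
randomisations (degree-preserving rewiring, modularity-preserving block
randomisation), rich-club profiling, lesion studies and coupling fits to
empirical FC, plus readers/writers for edge-list, dense-matrix and GraphML
files.

## Worked example

```r
library(netcomplexity)

res  <- pseudo_connectome(128, seed = 1)   # centralised hierarchical-modular fixture
res$graph
#> netgraph: 128 nodes, 1088 undirected links

scan <- coupling_scan(res$graph)           # g = 0 .. 9.9, step 0.1
scan
#> coupling scan (exponential propagator, 100 couplings, m = 50, lambda_max = 22.46)
#> peak complexity C = 0.5925 at g = 3 (mean r there: 0.478)
```

The fixture's complexity peaks mid-transition (mean correlation ~0.48),
the regime where internally coherent but mutually distinct clusters coexist.
Destroying either structural ingredient lowers the peak:

```r
surrogate_comparison(res$graph, res$partition, n_realisations = 10, seed = 2)
#> surrogate comparison (10 realisations per condition)
#>   original               peak(mean curve) = 0.5925  mean(peaks) = 0.5925
#>   rewired                peak(mean curve) = 0.5260  mean(peaks) = 0.5261 (sd 0.0111)
#>   modularity_preserving  peak(mean curve) = 0.4971  mean(peaks) = 0.4974 (sd 0.0118)
#>   random                 peak(mean curve) = 0.3807  mean(peaks) = 0.3809 (sd 0.0138)
```

Rewiring keeps the hubs but destroys the modules; modularity-preserving
randomisation keeps the modules but destroys the hubs; both fall short of
the original, and featureless random graphs fall lowest. Removing just the
55 hub–hub links (5% of the network) measurably lowers complexity, and none
of 100 equally sized random lesions does as much damage:

```r
lesion_study(res$graph, hub_nodes(res$graph), n_random = 100, seed = 3)
#> rich-club lesion: 55 links removed at g* = 3
#> C(real) = 0.5925  C(lesion) = 0.5724  (-3.40%)
#> P(random lesion < C(lesion)) = 0  (100 random lesions)
```

The single free parameter is recoverable from data: fitting `g` to a noisy
pseudo-empirical FC generated at `g = 2.0` finds it exactly on the grid:

```r
fc <- pseudo_empirical_fc(res$graph, 2.0, noise_sd = 0.02, seed = 4)
fit_coupling(res$graph, fc)
#> coupling fit (exponential propagator): g_best = 2, distance = 2.541, C = 0.4135
```

See `vignettes/functional-complexity.Rmd` for the model assumptions, the
generator constructions and all numerical conventions.

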