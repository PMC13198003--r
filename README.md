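# phdms — persistent multiscale spatial domains

`phdms` is for spatial-transcriptomics analysts who already run a domain
segmentation method (GraphST, SCAN-IT, Banksy, SpaGCN, BayesSpace, …) and
want more than one resolution's answer. Tissue is organized across scales —
large anatomical regions contain smaller specialized subregions, and spots
mix at region frontiers — so any single clustering resolution is a
compromise. Given the *sequence* of clusterings produced by a resolution
sweep, `phdms` extracts the domains that persist across scales and scores
every spot's stability of membership in each of them.

## Method in brief

With clusters $C_{i,j}$ (cluster $j$ at scale $k_i$, fine → coarse), build a
graph with one node per cluster and edges between overlapping clusters at
consecutive scales, weighted by a dissimilarity

$$f_C = 1-\frac{|C_{i,j}\cap C_{i+1,l}|}{|C_{i,j}|}
\qquad\text{or}\qquad
f_J = 1-\frac{|C_{i,j}\cap C_{i+1,l}|}{|C_{i,j}\cup C_{i+1,l}|},$$

containment for largely nested sweeps, Jaccard for general tissue. Adding
edges in order of dissimilarity defines a filtration; 0-dimensional
persistent homology (union-find) records when connected components of
clusters merge. A component $D$ with lifetime $p$ (death − birth; 1 if it
never dies) is a **multiscale domain**, with per-spot **coreness**

$$c_D(x)=1-\min\{f(e): e\ \text{internal to}\ D,\ x\in e\},$$

rescaled over the domain's support to $\bar c_D\in[0,1]$ (1 = stable core,
0 = unstable frontier). The **heterogeneity score**
$h(x)=\sum_i p_i\,\bar c_{D_i}(x)$ estimates how many persistent domains
contain each spot. For benchmarking against binary annotations the package
provides a generalized NMI for soft overlapping domains (reducing exactly
to classical NMI on partitions) and an exact spatial 2-Wasserstein
distance, in tissue coordinate units, computed by an exact transportation
simplex (no entropic approximation).

## Worked example

The package ships a synthetic generator that plants a nested Voronoi
hierarchy of domains and observes it as a noisy multi-resolution
clustering (frontier spots flip to adjacent domains with probability
`rho`, independently per scale):

```r
library(phdms)
h   <- generate_hierarchy(16, n_levels = 2, branching = 2, seed = 7)
cs  <- degrade_to_clusterings(h, scales_per_level = 2, rho = 0.05, seed = 7)
fit <- phdms(cs, index = "jaccard")
summary(fit)
#> Persistent multiscale domains (jaccard filtration)
#> Reported domains (ranked by lifetime x support size):
#>  domain     death  lifetime n_spots     score
#>      12       Inf 1.0000000     256 256.00000
#>      11 0.9867841 0.9867841     110 108.54626
#>       8 0.3944954 0.3944954      71  28.00917
#>       7 0.2105263 0.2105263     126  26.52632
#>       9 0.6448598 0.6448598      41  26.43925
#>      10 0.8187919 0.8187919      27  22.10738
#> Heterogeneity quantiles:
#>    0%   25%   50%   75%  100%
#> 1.211 1.211 1.381 1.632 2.381
```

Domain 12 never dies (the whole tissue, lifetime 1); domain 11 is one of
the two planted coarse regions, persisting almost the full filtration;
domains 7–10 are the four planted fine subregions, whose lifetimes reflect
their size relative to their parents. `coreness(fit)` returns the
spots-by-domains matrix of $\bar c_D$, `heterogeneity(fit)` the per-spot
$h$, and `plot(fit, "diagram" | "coreness" | "heterogeneity")` the standard
maps.

Benchmarking against the planted fine-level annotation:

```r
tr <- truth_from_hierarchy(h, level = 2)
match_to_truth(fit$ranked, tr)
#>   truth_domain domain_id        w2
#> 1         L2.1         7 0.3910537
#> 2         L2.2        10 0.4560452
#> 3         L2.3         9 0.4944976
#> 4         L2.4         8 0.5088284
```

Each planted domain is matched by a recovered domain within ~0.5 grid
units in Wasserstein distance (the grid spacing is 1, so recovered
domains sit within half a spot of the truth); at `rho = 0` all four
distances are exactly 0. `select_best_subset(fit$ranked, tr)` greedily
assembles the NMI-maximizing subset (here NMI 0.83 with 4 domains).

A command-line front end wrapping these functions is installed at
`inst/cli/phdms.R` (`Rscript .../phdms.R run|simulate|metrics|at …`).

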