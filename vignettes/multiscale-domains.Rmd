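---
title: "Persistent multiscale domains: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent multiscale domains: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phdms)
```

## The problem

Spatial-transcriptomics clustering methods partition a tissue into spatial
domains at one resolution. Real tissue is organized hierarchically: a large
anatomical region contains smaller specialized subregions, and at tissue
interfaces (e.g. a tumor frontier) spots mix between neighboring programs.
A single resolution cannot represent both facts at once. `phdms` takes a
*sequence* of clusterings of the same spot set at several resolutions —
produced by any upstream pipeline — and extracts the domains that remain
stable across resolutions, together with a per-spot score of how stably
each spot belongs to each domain.

## The model

### Cluster filtration

Write $C_{i,j}$ for the $j$-th cluster at scale $k_i$ (scales ordered fine
to coarse). Build a graph with one node per cluster and an edge between
every overlapping pair of clusters at *consecutive* scales, weighted by a
dissimilarity of their spot sets:

* containment, $f_C = 1 - |C_{i,j} \cap C_{i+1,l}| / |C_{i,j}|$ — zero when
  the finer cluster is nested in the coarser one; the default, suited to
  sweeps whose clusters are largely hierarchical;
* Jaccard, $f_J = 1 - |C_{i,j} \cap C_{i+1,l}| / |C_{i,j} \cup C_{i+1,l}|$
  — symmetric and applicable to any clusterings (e.g. tumor tissue without
  nested organization). Always $f_C \le f_J$.

All vertices enter the filtration at value $0$, edges at their weight.
Pairs of disjoint clusters are not materialized: an edge of weight exactly
1 cannot merge anything before the terminal filtration value, so omitting
it changes no death and keeps the graph sparse — components that never
merge simply survive with lifetime 1. Weights are ratios of integer
overlap counts; equal weights are therefore exact ties, resolved by the
fixed key (source scale, source label, target label) so runs are
bit-reproducible.

### Persistence and multiscale domains

Zero-dimensional persistent homology of this filtration is computed by
union-find over the sorted edge list: a connected component dies when an
edge merges it into an older one, and its persistence lifetime is its
death value (1 for components that survive the whole filtration). A
component's membership is snapshotted immediately before its death.

All components are born at 0, so the classical elder rule does not decide
which class survives a merge. We make the *coarsest* class survive: the
survivor is the class containing the node of largest scale index (ties to
the smaller cluster label). This choice matters only for membership
attribution — the diagram is identical under any tie-break — and it is the
one under which a perfectly nested sweep decomposes into one component per
planted domain: each finer domain dies, with support exactly itself, at
the edge linking it to its parent, instead of silently absorbing the
parent and surviving. With fine-preferred survival the largest child of
every parent would never appear as any component's snapshot.

Each kept component $D$ becomes a multiscale domain via the coreness
$$c_D(x) = 1 - \min\{\, f(e) : e \text{ internal to } D,\; x \in e \,\},$$
zero for spots touched by no internal edge, then affinely rescaled over
its support so the stable core scores 1 and the least stable supported
spot scores 0 ($\bar c_D$). The min and max of the rescaling are taken
over the support only; over all spots the minimum would be 0 whenever the
domain is a strict subset of the tissue and the rescaling would be
vacuous. A component with no internal edge (one cluster) scores 1 on that
cluster's spots — the limit as overlap information vanishes; the default
reporting filter (`min_clusters = 2`) hides these unless requested.

The heterogeneity score $h(x) = \sum_i p_i\, \bar c_{D_i}(x)$ (lifetimes
$p_i$, clamped at 1) estimates how many persistent domains contain each
spot. Domains are ranked by $p_i \cdot |\mathrm{supp}(D_i)|$ — persistence
weighted by size, so tiny long-lived outliers do not crowd out the domains
that describe the tissue; the exact weighting is this package's choice.

### Evaluation metrics

Soft, overlapping domains cannot be scored with classical partition
metrics, so two generalizations are provided.

* **Generalized NMI.** Domains enter as a spots-by-domains coreness matrix
  with rows normalized to unit sum; spots with no membership in either
  input are dropped from both and the retained count is $N$ (binary
  partitions have no such rows, which preserves the exact reduction to
  classical arithmetic-mean NMI). Natural logarithms, $0\ln 0 = 0$; a
  degenerate pair of zero-entropy inputs returns 0 with a warning. The
  membership matrix uses the normalized coreness $\bar c$ — the per-domain
  score the package reports — for consistency with the Wasserstein
  representation.
* **Spatial 2-Wasserstein distance.** Each domain becomes a probability
  distribution over spot coordinates ($\bar c_D$ normalized to unit mass;
  binary domains uniform on their members) and distances are exact
  optimal-transport values under squared Euclidean cost, in tissue
  coordinate units. The solver is a transportation simplex (block pricing,
  degeneracy handled by marginal perturbation, with flows re-solved on the
  optimal basis against the unperturbed marginals) — no entropic
  regularization, so zero means identical distributions and the triangle
  inequality holds to solver tolerance. Supports larger than
  `max_support` (default 5000 spots, above typical Visium sections) are
  reduced by seeded multinomial subsampling, trading exactness for
  tractability only when asked.

For benchmarking, `match_to_truth()` reports for each annotated domain the
candidate minimizing this distance; `best_matching_scale()` picks the
single scale whose cluster count is closest to the annotation's (ties to
the finer scale); `select_best_subset()` greedily grows the
NMI-maximizing subset. One subtlety of the zero-row-drop rule: a subset
covering part of the tissue perfectly already reaches NMI 1, so greedy
additions that leave the NMI unchanged but extend coverage of annotated
spots are still accepted; the search stops only when an addition would do
neither. Exhaustive search is deliberately avoided; greedy selection is a
lower bound on the best subset's NMI and dominates every single domain by
construction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `index` | `"containment"` | filtration dissimilarity; use `"jaccard"` for non-nested tissue |
| `min_lifetime` | 0 | lifetime threshold (filtration units, $[0,1]$) for reported components |
| `min_clusters` | 2 | minimum clusters per reported component; hides singletons |
| `top_k` | 25 | domains kept after size-weighted persistence ranking |
| `max_support` | 5000 | spot count above which transport is subsampled |
| resolutions | 0.95 → 0.15, 8 steps | default Leiden sweep of the adapter |

The resolution schedule is the conventional uniform grid from 0.95 down to
0.15 in eight steps; it can be replaced freely, and the pipeline consumes
any label matrix regardless of how it was produced.

## The synthetic generator

`generate_hierarchy()` plants what the method is supposed to find: spots
on a `grid_side`² unit grid, recursively partitioned by seeded Voronoi
splits so each level strictly refines the previous one. Voronoi growth
gives irregular domain shapes rather than symmetric rings. Spots within
`frontier_radius` (default 1.5, the 8-neighborhood) of any planted
boundary are frontier spots. `degrade_to_clusterings()` observes each
level at `scales_per_level` scales; at every scale each frontier spot
independently flips to a spatially adjacent domain with probability `rho`.
Because noise is redrawn per scale, frontier spots oscillate between
domains across scales — which is exactly what depresses their coreness —
while interior spots are always stable.

At `rho = 0` the sequence is perfectly nested, every planted domain is
recovered exactly (support equality, per-truth Wasserstein distance 0),
and each finer domain's death equals the closed form
$1 - |\text{child}|/|\text{parent}|$ under the Jaccard filtration. The
test suite checks this, plus, at `rho = 0.05` over ten noise replicates,
support recovery (best-match Jaccard similarity ≥ 0.9) and a positive
core-versus-frontier coreness contrast, and at `rho = 0.1` the
localization of heterogeneity on the frontier. The standard study size is
a 32 × 32 grid, two levels, branching two, two scales per level — sizes at
which every recovery property is checked exactly rather than
approximately.

What the generator does *not* emulate: expression noise (the package
consumes labels, not counts), spatially correlated label errors, doublets,
scale-dependent cluster fragmentation of real Leiden sweeps, or unassigned
spots. Passing tests therefore demonstrate the correctness of the
filtration/persistence/coreness machinery and the metrics, not the quality
of any upstream embedding.

## Numerical choices

* Overlap weights are ratios of integer counts computed by bucketing spots
  by label pair (each spot touched once per scale step); ties are exact
  and no epsilon comparisons are used anywhere in the filtration.
* Union-find uses path compression; equal-weight edges are processed in
  the deterministic tie order, so simultaneous merges resolve
  sequentially and byte-identical outputs follow from identical inputs.
* The transport solver's optimality tolerance is $10^{-10}\,\max|C|$ on
  reduced costs; marginal perturbation is $10^{-11}$ of total mass and is
  removed before the reported value, so it never leaks into distances.
* Zero-persistence components (merges at weight 0, e.g. duplicated
  partitions) are retained internally — diagram counts must match
  brute-force component counts — but excluded from reporting by default.
* Degenerate cases: an empty domain support is an error; constant
  coreness normalizes to 1 on the support; a single all-covering domain
  pair has entropy 0 and NMI defined as 0 with a warning.

## Known limitations

* Only 0-dimensional structure is tracked; loops or higher-order
  relationships between domains are invisible.
* Coreness is attributed through the membership snapshot at death, so a
  domain absorbed early contributes no frontier information afterwards.
* Heterogeneity need not peak on frontiers for every geometry: a frontier
  spot holds *partial* membership in each sibling domain, and when parent
  splits are strongly unbalanced the lifetime-weighted sum of partial
  memberships can fall below an interior spot's full membership. On
  balanced nested tissue the frontier excess is clearly positive; on
  arbitrary Voronoi geometries its sign can flip.
* The greedy subset search is a heuristic; it can be arbitrarily far from
  the exhaustive optimum on adversarial inputs, though it dominates every
  single-domain score.
* `cluster_sweep()` builds a dense distance matrix, which is fine to a few
  thousand spots; beyond that, produce the label matrix with a dedicated
  pipeline and feed it directly.
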