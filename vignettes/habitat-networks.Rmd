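---
title: "Habitat networks from GPS tracking: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat networks from GPS tracking: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habnet)
```

This vignette is the package's account of its science: the movement and
network models it implements, the estimators behind the null model, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design decisions a
maintainer would want written down.

## 1. From relocations to tracks

The analysis unit is the **bird-year**: all relocations of one individual
inside one nonbreeding-season window. Windows are closed intervals
`[start, end]` supplied as data (season segmentation itself is out of
scope). Three preprocessing steps make tracks comparable:

* **Fix-rate normalization** (`normalize_fix_rate()`): a greedy anchor
  walk. The first fix is kept; from a kept fix at time $t$, the next kept
  fix is the earliest one at or after $t + \Delta - \tau$, with interval
  $\Delta = 2$ h and tolerance $\tau = 20$ min. Fixes arriving sooner are
  oversampling and are skipped. A gap beyond $\Delta + \tau$ starts a new
  *burst*; bursts are remembered so that no movement step is ever formed
  across a data hole. The walk is idempotent: renormalizing a normalized
  track changes nothing (this is a property test).
* **Speed filtering** (`filter_speed()`): the later member of any
  consecutive pair implying a straight-line speed above 12 m/s (43 km/h)
  is removed, and pairs are re-examined until no violation remains.
  Removing the *later* point is a choice; the alternative (removing
  whichever point resolves more violations) needs look-ahead and changes
  nothing on clean data. Default order is normalize-then-filter,
  configurable via `preprocess_tracks(normalize_first = )`.
* **Projection** (`eqc_projection()`): a spherical equidistant conic with
  standard parallels 33°N and 45°N, implemented from the closed-form
  forward/inverse equations (mean Earth radius 6 371 008.8 m). It is
  distance-true along meridians; east–west scale error at 26.5°N is
  about +1.7 %, irrelevant at the 325–650 m scales that drive node
  construction. Round-trip error is far below 1 m.

## 2. Habitat nodes

Nodes are point clusters, not raster patches. `greedy_cluster()` assigns,
at each iteration, the unassigned point with the most unassigned
neighbors within 650 m (the species' expected foraging radius) plus all
those neighbors to a new cluster; leftover isolated points become
singletons. Ties in neighbor count break to the lowest input index, and
"within" is inclusive ($\le$). The implementation uses grid-binned
neighbor lists with incremental count updates; a deliberately naive
$O(n^2)$ re-implementation of the same rule serves as its oracle in the
tests, with exact partition equality required on random instances.

`join_clusters()` merges clusters when any point of one lies within 325 m
of a point of another — i.e. inside the other's buffer — and takes
connected components, so joining is transitive. A **node** is then the
union of 325-m discs around its member points. The disc-union area is
computed exactly by Green's theorem over the uncovered boundary arcs of
each disc (no polygon library involved); a single-point node has area
$\pi \cdot 0.325^2 \approx 0.332$ km², and the tests check random
configurations against a closed-form two-disc formula and a fine-grid
oracle. Point-in-node queries reduce to "within 325 m of a member
point", with ties between overlapping node polygons resolved by nearest
centroid.

## 3. Urbanization score

Each node gets a composition over 12 land-cover classes, from either a
categorical raster (`grid_raster()` + `extract_node_landcover()`, cell
centers inside the polygon) or per-site composition rows
(`site_landcover_to_nodes()`); unmapped source classes are a hard error.
`nmds_scores()` ordinates the node × class table by non-metric MDS in
k = 3 dimensions on Bray–Curtis dissimilarities of untransformed
proportions (delegated to `vegan::metaMDS`, ≥ 20 seeded random restarts,
lowest stress kept, stress reported on the 0–1 scale). NMDS axes carry no
intrinsic sign, so the package fixes an orientation convention: axis 1 is
flipped, if necessary, so nodes whose majority class is `urban` average
positive (falling back to a positive correlation with the summed
urban-type proportions when no node is urban-majority). NMDS1 is then a
continuous **urbanization score**. Tables whose distinct rows number
fewer than k + 2 are rejected rather than ordinated unstably.

## 4. The habitat network

A directed edge u→v counts relocations from node u to node v within one
valid time step (same burst, gap ≤ 2 h 20 min); consecutive fixes at one
node collapse into a single *visit*, and node size is the pooled visit
count — returning to a node after an excursion is a new visit. Unassigned
fixes break both steps and visit runs. Nodes and edges carry the number
of distinct bird-years using them. The network is clipped to the study
bounding box (−80.52° to −80° E, 26.25° to 27.5° N by default; membership
is by node centroid) and nodes left without any edge are pruned; tracks
whose every node disappeared are dropped and reported. Rebuilding from
tracks in any order yields an identical network.

## 5. The random-walk null model

The null asks what the network would look like if individuals moved with
the same propensity and distance scale but indiscriminately with respect
to habitat. Each replicate simulates one walk per observed track — same
starting node, same number of time steps — on the observed node set. Per
step, the walker stays with probability $1 - p$ and otherwise moves to
node $j \ne i$ with probability proportional to $w(d_{ij})$.

**Move probability.** $p$ is the fraction of valid fix pairs whose two
fixes occupy different nodes. Pooled mode uses the ratio of pooled counts
(not the mean of per-track ratios, which would overweight short tracks);
per-track mode estimates $p$ within each track. Both modes are
first-class (`mode = "pooled" | "per_track"`).

**Distance kernel.** The realized step-distance distribution is
estimated by a Gaussian KDE on $\log_{10}$ distance with Silverman's
bandwidth (a histogram form is available; a single observation falls back
to a 0.1-log10-unit bandwidth; weights are floored at $10^{-12}$ so no
destination is ever impossible). The subtle point: the realized
distribution is the product of the walker's distance *preference* and the
*availability* of candidates at each distance, so using it directly as a
choice weight double-counts availability and systematically
over-disperses the simulated walks. We verified this on synthetic walks
with a known kernel: nulls driven by the true kernel reproduce observed
density, assortativity, and modularity (|z| ≲ 1), while nulls weighted by
the plain marginal miss by |z| ≈ 10. The default weight is therefore the
**use/availability density ratio** — the same correction logic as step-
and resource-selection functions — with the plain marginal available via
`correct_availability = FALSE` for comparison with the uncorrected
variant. Replicates (default 50) use per-replicate RNG substreams drawn
deterministically from one seed, so a replicate set is exactly
reproducible.

## 6. Metrics and statistical models

* **Edge density** $m / (n(n-1))$, self-loops excluded (none can arise).
* **Assortativity**: Pearson correlation of a node attribute across the
  source and target of each directed edge, each realized edge counted
  once; zero-variance endpoint sets return `NA` rather than a spurious
  number. A weight-expanded variant (`weighted = TRUE`) replicates each
  edge by its relocation count, measuring movement *rates* instead of
  edge *presence*: the unweighted version saturates on long tracks (one
  rare crossing realizes an edge forever), so graded habitat preference
  is visible mainly in the weighted version, which is what the
  specialization-recovery test uses. Per-class assortativities use each
  class's proportion column.
* **Modules**: detected on the undirected projection (reciprocal weights
  summed) by greedy modularity optimization (primary), edge betweenness,
  or simulated annealing (spin-glass, largest connected component only)
  — all delegated to igraph. Q is the weighted Newman–Girvan modularity
  of the detected partition; if a detected partition scores Q < 0 the
  trivial single-module partition (Q = 0 exactly) is returned instead,
  since an optimizer should never do worse than not partitioning.
* **Node metrics**: out-degree (distinct successors), betweenness on the
  directed graph with unweighted shortest paths, normalized by
  $(n-1)(n-2)$, and stored visit counts.
* **Observed vs null**: per metric, the observed value, null mean ± SD, a
  z-score (flagged undefined when the null SD is 0 and values differ),
  and a two-group linear model on network type; per-class assortativity
  gets the type × class interaction model.
* **Node GLMs**: out-degree and size as Poisson (log link), log
  betweenness as Gaussian restricted to positive-betweenness nodes (no
  pseudo-count; configurable in principle, documented here), on
  urbanization score, latitude, longitude and their quadratics, all
  centered and scaled.
* **ANOVAs**: urbanization score on module membership, and on individual
  identity over the per-visit dataset; a zero within-group sum of squares
  is flagged as degenerate rather than reported as a huge F.

## 7. Individual specialization and knockout

Per track (or per bird, via a track→bird map), the habitat profile is the
visit-weighted mean and SD of NMDS1 with frequency-weight semantics
(denominator $\sum w - 1$; a single node or total weight 1 gives SD 0).
The knockout removes one track (or all of a bird's tracks), rebuilds the
edge set, and records the change in edge density and assortativity.

**Design choice — fixed node set.** By default the full network's node
set is held fixed during knockout, so the density denominator does not
change and removal can only remove edges: $\Delta$density ≤ 0 is then a
theorem, matching the sign structure the analysis relies on. The
alternative — re-pruning nodes left edgeless, consistent with the
original pruning rule — shrinks $n(n-1)$ and can *raise* density on small
graphs (drop a pendant node with its two reciprocal edges from a small
dense graph and the ratio grows); it is available as
`drop_empty_nodes = TRUE`. Undefined assortativity on a sparse network
propagates as a flagged missing value.

The three OLS models are: weighted mean on weighted SD and its square
(the hump-shaped mean–variation relation); and each knockout delta on
weighted mean and SD. Rank-deficient designs are reported as errors, not
silently aliased.

## 8. The synthetic study system

The generator exists so every stage runs and every property is testable
without field data. A landscape is a set of sites (minimum separation
1 500 m, comfortably over twice the 650-m clustering radius, so each site
should become exactly one node — a tested recovery property) with
land-cover rows drawn from urban / natural Dirichlet archetypes.
Concentration parameters are moderate, so each type spans a range of
compositions: an urbanization *gradient*, like real land-cover data,
rather than a binary label (sharper archetypes make NMDS stress and the
module ANOVA degenerate). Agents move by: stay with probability $f$
(site fidelity), else pick site $j$ with probability
$\propto e^{-d_{ij}/\lambda} m_j$, where $m_j = (1-s) + s\,[{\rm type}_j
= {\rm preferred}]$; $s = 0$ is type-blind, $s = 1$ never uses the other
type. Fixes are site coordinates plus 100-m Gaussian jitter (so a site's
fixes always cluster together) at exact 2-h timestamps.

Defaults, chosen once as the study conditions: sites inside a ~30 × 33 km
core of the study extent (tracked birds' patches concentrate around a
capture region; this also keeps inter-site spacing a few km), kernel
scale $\lambda = 15$ km (2-h displacements of a few to ~20 km for a bird
that covers 30–60 km daily), $f = 0.5$, 500 steps per default track.
The generator's exponential kernel deliberately differs in form from the
analysis-side KDE so the estimator is never checked against itself, and
ground truth is written to a separate JSON so analysis code cannot read
labels.

**What the generator does not emulate**: daylight-only fix schedules and
roosting rhythms, GPS error beyond isotropic jitter, gradual seasonal
drift of site use, within-site movement, landscape rasters (compositions
stand in), or density dependence among agents. Passing tests therefore
demonstrate correctness of the estimators under a stylized movement
model, not ecological realism of any particular parameter value.

## 9. Problem sizes and known limitations

The test suite runs scaled-down study systems chosen for tight runtime:
null-model self-consistency uses 20 runs × (12 type-blind agents × 100
steps) × 50 replicates; specialization recovery uses 5 runs × a
five-point $s$ grid × (20 agents × 500 steps) × 15 replicates; the
knockout pattern uses 10 runs of 8 specialists + 2 generalists × 300
steps; the acceptance script uses 40 sites and 30 bird-years × 100 steps.

Two limitations worth knowing:

* Even with the availability correction, a smoothed kernel retains a
  small residual bias relative to a sharply concentrated true kernel. The
  50-replicate null band is *conditional* on the estimated parameters and
  narrows as $\sqrt{\text{steps}}$, so for very long series the residual
  bias eventually exceeds the band (at 150-step tracks, central-95 %
  coverage drops to ~16–19/20 runs; at 100 steps it is nominal). Interpret
  observed-vs-null z-scores on very long series accordingly.
* The unweighted assortativity and edge density saturate as effort grows
  (every pair eventually connects); on long tracks the weighted
  assortativity and the null contrast carry the signal.
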