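# habnet

Habitat connectivity networks from animal GPS tracking data.

## The problem

Highly mobile animals connect habitat patches by moving among them,
transporting nutrients, propagules, and pathogens. When some individuals
specialize on particular habitat types — for example wading birds that
forage mainly in urban parks while others stay in wetlands — realized
connectivity can be far lower than what patch geometry and movement
capacity alone would predict. `habnet` provides a complete pipeline for
quantifying this effect from relocation data, for movement ecologists
working with Movebank-style GPS tables.

The pipeline:

1. **Track preprocessing** — subset relocations to nonbreeding-season
   windows per individual ("bird-years"), resample the fix rate to 2 h
   (tolerance 20 min) by a greedy anchor walk, remove positions implying
   speeds > 12 m/s, and project coordinates with an equidistant conic
   projection (standard parallels 33°N / 45°N).
2. **Habitat nodes** — cluster fixes by the greedy most-neighbors rule at
   650 m, join clusters whose points fall within 325 m of each other, and
   represent each node as the union of 325-m discs around member points
   (areas computed exactly).
3. **Urbanization score** — per-node land-cover composition over 12
   classes, ordinated by 3-D NMDS on Bray–Curtis dissimilarities; axis 1
   is oriented so human-dominated nodes score positive (NMDS1 = the
   urbanization score).
4. **Habitat network** — a directed, weighted graph: an edge u→v counts
   relocations from node u to node v within one time step; node size
   counts run-length-collapsed visits; the network is clipped to the
   study extent and pruned of isolated nodes.
5. **Null model** — replicate random walks paired 1:1 with observed
   tracks (same start node, same number of steps), governed by the
   observed move probability `p` and an empirical step-distance kernel
   (use/availability-corrected KDE on the log scale), pooled or per-track.
6. **Metrics and inference** — edge density m/(n(n−1)), assortativity of
   node attributes across edges, modularity Q with three community
   detection methods, node-level out-degree/betweenness/size GLMs,
   observed-vs-null contrasts, per-individual habitat profiles (visit-
   weighted mean/SD of NMDS1), and knockout analysis of each individual's
   contribution to connectivity.
7. **Synthetic data** — a first-class generator of landscapes (urban /
   natural Dirichlet land-cover archetypes) and agents with controllable
   habitat specialization `s`, site fidelity `f`, and an exponential
   distance kernel, producing the same CSV dialects the pipeline reads.

## Worked example

Simulate a small tracked population — 4 urban specialists, 4 natural
specialists (specialization s = 0.9), 2 generalists — then run the full
pipeline and compare the observed network against 50 random-walk nulls:

```r
library(habnet)

land  <- make_landscape(n_sites = 20, frac_urban = 0.5, seed = 42)
birds <- make_agents(n_urban = 4, n_natural = 4, n_generalist = 2,
                     s = 0.9, fidelity = 0.5, n_steps = 120)
sim   <- simulate_agents(land, birds, seed = 42)

site_lc <- data.frame(site_id = land$sites$site_id, lon = land$sites$lon,
                      lat = land$sites$lat, land$landcover, check.names = FALSE)
pipe <- run_habitat_pipeline(sim$tracks, sim$seasons, site_lc, nmds_seed = 42)
pipe
#> habnet pipeline: 10 tracks -> 20 nodes; habitat network: 20 nodes, 251 directed edges, 10 bird-years

obs      <- network_metric_table(pipe$network$graph)
nulls    <- simulate_null_networks(pipe$network, mode = "pooled", n_reps = 50, seed = 42)
null_mat <- t(sapply(nulls$networks, network_metric_table))
cmp      <- compare_observed_null(obs, null_mat)
cmp[cmp$metric %in% c("edge_density", "assortativity_nmds1", "modularity_q"),
    c("metric", "observed", "null_mean", "null_sd", "z")]
#>               metric observed null_mean null_sd     z
#>         edge_density    0.661    0.7433  0.0218 -3.80
#>  assortativity_nmds1    0.220   -0.0618  0.0253 11.13
#>         modularity_q    0.230    0.1009  0.0144  8.95
```

The observed network realizes fewer of the possible connections than the
distance-only nulls (negative z for edge density), while like-with-like
connections (assortativity by urbanization score) and community structure
(Q) are far stronger — the signature of habitat specialization, not of
patch geometry.

Knockout each track and ask who carries connectivity:

```r
ko <- knockout_analysis(pipe$network, pipe$scores)
head(ko[order(ko$delta_density), c("id", "pct_density", "delta_assortativity")], 3)
#>         id pct_density delta_assortativity
#>  agent09_1       -7.97              0.0524
#>  agent10_1       -7.57              0.0741
#>  agent07_1       -5.98             -0.0164
```

The two generalists (`agent09`, `agent10`) top the list: removing either
costs the network ~8 % of its edges and *raises* assortativity — the few
individuals that use both habitat types are the keystones of urban–natural
connectivity.

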