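# Independent brute-force references and shared fixtures for the tests.

# Naive greedy most-neighbors clustering: full distance matrix, recomputed
# neighbor counts every iteration. Deliberately the simplest possible
# rendering of the rule, kept independent of the package implementation.
oracle_greedy_cluster <- function(x, y, radius) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  assigned <- rep(NA_integer_, n)
  cl <- 0L
  while (anyNA(assigned)) {
    un <- which(is.na(assigned))
    cnt <- vapply(un, function(i) sum(d[i, un] <= radius) - 1L, 0L)
    seed <- un[which.max(cnt)]
    members <- un[d[seed, un] <= radius]
    cl <- cl + 1L
    assigned[members] <- cl
  }
  assigned
}

# Connected components of the cluster-joining adjacency (min inter-point
# distance <= join_radius), by repeated label propagation.
oracle_join_clusters <- function(x, y, cluster, join_radius) {
  k <- max(cluster)
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- matrix(FALSE, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a < b && min(d[cluster == a, cluster == b]) <= join_radius)
      adj[a, b] <- adj[b, a] <- TRUE
  }
  lab <- seq_len(k)
  repeat {
    old <- lab
    for (a in seq_len(k)) lab[a] <- min(lab[adj[a, ] | seq_len(k) == a])
    if (identical(old, lab)) break
  }
  match(lab, unique(lab))[cluster]
}

canonical_partition <- function(ids) match(ids, unique(ids))

strip_attrs <- function(v) {
  attributes(v) <- NULL
  v
}

# Grid approximation of the union-of-discs area (square meters).
grid_disc_area <- function(x, y, r, cell = 2) {
  gx <- seq(min(x) - r - cell, max(x) + r + cell, by = cell)
  gy <- seq(min(y) - r - cell, max(y) + r + cell, by = cell)
  pts <- expand.grid(gx = gx, gy = gy)
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_along(x))
    inside <- inside | ((pts$gx - x[i])^2 + (pts$gy - y[i])^2 <= r^2)
  sum(inside) * cell^2
}

# Area of two overlapping equal discs, closed form.
two_disc_area <- function(d, r) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# A manually labeled track data.frame: node labels at a regular 2-h fix
# interval, single burst unless burst_id given.
toy_track <- function(id, nodes, burst = NULL, gap = 7200,
                      t0 = as.POSIXct("2016-01-01 00:00:00", tz = "UTC")) {
  n <- length(nodes)
  data.frame(track_id = id,
             timestamp = t0 + (seq_len(n) - 1) * gap,
             burst_id = if (is.null(burst)) rep(1L, n) else burst,
             node = nodes)
}

# Run the full synthetic study pipeline under fixed seeds.
synth_pipeline <- function(landscape_seed, agents, sim_seed,
                           nmds_seed = landscape_seed, n_sites = 24,
                           frac_urban = 0.5) {
  ls <- make_landscape(n_sites = n_sites, frac_urban = frac_urban,
                       seed = landscape_seed)
  sim <- simulate_agents(ls, agents, seed = sim_seed)
  slc <- data.frame(site_id = ls$sites$site_id, lon = ls$sites$lon,
                    lat = ls$sites$lat, ls$landcover, check.names = FALSE)
  pipe <- run_habitat_pipeline(sim$tracks, sim$seasons, slc,
                               nmds_seed = nmds_seed)
  list(landscape = ls, sim = sim, pipe = pipe)
}

# One-way ANOVA F statistic from the sum-of-squares decomposition.
anova_F_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  k <- nlevels(groups)
  n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}
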