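# Habitat-node delineation: greedy most-neighbors clustering of projected
# GPS fixes, buffer-based joining of adjacent clusters, and node polygons
# defined as the union of buffer discs around member points.

# Grid-binned fixed-radius neighbor search. Returns an adjacency list:
# adj[[i]] = indices j != i with planar distance <= radius (inclusive).
.neighbor_adjacency <- function(x, y, radius) {
  n <- length(x)
  if (n == 0) return(list())
  cs <- radius
  cx <- floor(x / cs)
  cy <- floor(y / cs)
  key <- paste(cx, cy, sep = ",")
  cells <- split(seq_len(n), key)
  r2 <- radius^2
  adj <- vector("list", n)
  for (cell in names(cells)) {
    idx <- cells[[cell]]
    cc <- as.integer(strsplit(cell, ",", fixed = TRUE)[[1]])
    nb_keys <- as.vector(outer(cc[1] + (-1:1), cc[2] + (-1:1), paste, sep = ","))
    cand <- unlist(cells[intersect(nb_keys, names(cells))], use.names = FALSE)
    for (i in idx) {
      d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
      nb <- cand[d2 <= r2]
      adj[[i]] <- nb[nb != i]
    }
  }
  adj
}

#' Greedy most-neighbors clustering of points
#'
#' Repeatedly picks, among unassigned points, the one with the most
#' unassigned neighbors within `radius` (ties broken by lowest input
#' index), and assigns it together with all its unassigned neighbors to a
#' new cluster. Points with no remaining neighbors end up as singleton
#' clusters. Distances are planar and "within radius" is inclusive.
#'
#' @param x,y Projected point coordinates in meters.
#' @param radius Clustering radius in meters (default 650, the expected
#'   foraging radius).
#' @return Integer vector of cluster ids (1-based, in order of cluster
#'   creation), with the seed point index of each cluster in attribute
#'   `seeds`.
#' @export
greedy_cluster <- function(x, y, radius = 650) {
  n <- length(x)
  if (n == 0) return(integer(0))
  adj <- .neighbor_adjacency(x, y, radius)
  cnt <- lengths(adj)
  cluster <- integer(n)
  seeds <- integer(0)
  n_left <- n
  while (n_left > 0) {
    seed <- which.max(cnt)           # ties: lowest index (which.max takes first)
    nb <- adj[[seed]]
    members <- c(seed, nb[cluster[nb] == 0L])
    cl <- length(seeds) + 1L
    cluster[members] <- cl
    seeds[cl] <- seed
    # decrement unassigned-neighbor counts of everything adjacent to a new member
    touched <- unlist(adj[members], use.names = FALSE)
    if (length(touched)) cnt <- cnt - tabulate(touched, nbins = n)
    cnt[members] <- -1L
    n_left <- n_left - length(members)
  }
  attr(cluster, "seeds") <- seeds
  cluster
}

#' Join adjacent clusters into habitat nodes
#'
#' Two clusters are adjacent when any point of one lies within
#' `join_radius` of a point of the other (i.e. falls inside the other's
#' buffer). Connected components of this adjacency (transitive closure)
#' become nodes.
#'
#' @param x,y Projected point coordinates.
#' @param cluster Cluster id per point, from [greedy_cluster()].
#' @param join_radius Joining distance in meters (default 325).
#' @return Integer vector of node ids per point, numbered in order of first
#'   appearance by cluster id.
#' @export
join_clusters <- function(x, y, cluster, join_radius = 325) {
  k <- max(cluster, 0L)
  if (k == 0L) return(integer(0))
  adj <- .neighbor_adjacency(x, y, join_radius)
  # union-find over clusters
  parent <- seq_len(k)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (i in seq_along(adj)) {
    ci <- cluster[i]
    for (j in adj[[i]]) {
      cj <- cluster[j]
      if (ci != cj) {
        ri <- find(ci); rj <- find(cj)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  node_of_cluster <- match(roots, unique(roots))
  node_of_cluster[cluster]
}

#' Area of a union of equal-radius discs
#'
#' Exact area (Green's theorem over the boundary arcs) of the union of
#' discs of radius `r` centered on the given points. Used to measure node
#' polygon areas without a polygon-geometry dependency.
#'
#' @param x,y Disc centers in meters.
#' @param r Disc radius in meters.
#' @return Area in square meters.
#' @export
disc_union_area <- function(x, y, r) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n == 0) return(0)
  total <- 0
  two_pi <- 2 * pi
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    dx <- pts[, 1] - xi; dy <- pts[, 2] - yi
    d <- sqrt(dx^2 + dy^2)
    nb <- which(d < 2 * r & d > 0)
    if (!length(nb)) {
      total <- total + pi * r^2
      next
    }
    # angular intervals of circle i covered by each overlapping disc
    a <- atan2(dy[nb], dx[nb])
    hw <- acos(pmin(1, d[nb] / (2 * r)))
    lo <- (a - hw) %% two_pi
    hi <- lo + 2 * hw
    # split intervals wrapping past 2*pi
    wrap <- hi > two_pi
    ints <- rbind(
      if (any(!wrap)) cbind(lo[!wrap], hi[!wrap]),
      if (any(wrap)) cbind(lo[wrap], rep(two_pi, sum(wrap))),
      if (any(wrap)) cbind(rep(0, sum(wrap)), hi[wrap] - two_pi))
    ints <- ints[order(ints[, 1]), , drop = FALSE]
    # merge covered intervals, collect uncovered (boundary) arcs
    arcs <- NULL
    cur <- 0
    for (j in seq_len(nrow(ints))) {
      if (ints[j, 1] > cur) arcs <- rbind(arcs, c(cur, ints[j, 1]))
      cur <- max(cur, ints[j, 2])
    }
    if (cur < two_pi) arcs <- rbind(arcs, c(cur, two_pi))
    if (is.null(arcs)) next   # circle fully interior: no boundary contribution
    a1 <- arcs[, 1]; a2 <- arcs[, 2]
    total <- total + sum(0.5 * (r^2 * (a2 - a1) +
                                  xi * r * (sin(a2) - sin(a1)) -
                                  yi * r * (cos(a2) - cos(a1))))
  }
  total
}

#' Build habitat nodes from clean fixes
#'
#' Clusters the pooled, projected fixes with [greedy_cluster()], joins
#' adjacent clusters with [join_clusters()], and summarizes each node:
#' member count, centroid (mean of member points, back-projected to
#' lon/lat), and polygon area, where the node polygon is the union of
#' `buffer`-radius discs around member points.
#'
#' @param fixes Data.frame of projected fixes (`x`, `y`, optionally
#'   `track_id`), typically `do.call(rbind, tracks)`.
#' @param radius Clustering radius in meters.
#' @param join_radius Cluster-joining distance in meters.
#' @param buffer Disc radius defining node polygons, in meters (default
#'   equal to `join_radius`).
#' @param proj Projection used to back-compute centroid lon/lat; `NULL` to
#'   skip.
#' @return An object of class `habitat_nodes`: a list with `nodes` (one row
#'   per node: `node_id`, `n_member_fixes`, `centroid_x`, `centroid_y`,
#'   `lon`, `lat`, `area_km2`), `membership` (node id per input fix),
#'   `points` (member coordinates), and `buffer`.
#' @export
build_nodes <- function(fixes, radius = 650, join_radius = 325,
                        buffer = join_radius, proj = eqc_projection()) {
  stopifnot(!is.null(fixes$x), !is.null(fixes$y))
  cl <- greedy_cluster(fixes$x, fixes$y, radius)
  node <- join_clusters(fixes$x, fixes$y, cl, join_radius)
  ids <- sort(unique(node))
  nodes <- data.frame(
    node_id = ids,
    n_member_fixes = as.integer(tabulate(node, nbins = max(ids))[ids]),
    centroid_x = vapply(ids, function(i) mean(fixes$x[node == i]), 0),
    centroid_y = vapply(ids, function(i) mean(fixes$y[node == i]), 0)
  )
  nodes$area_km2 <- vapply(ids, function(i) {
    disc_union_area(fixes$x[node == i], fixes$y[node == i], buffer) / 1e6
  }, 0)
  if (!is.null(proj)) {
    ll <- eqc_inverse(proj, nodes$centroid_x, nodes$centroid_y)
    nodes$lon <- ll$lon
    nodes$lat <- ll$lat
  }
  structure(
    list(nodes = nodes, membership = node,
         points = data.frame(x = fixes$x, y = fixes$y, node = node),
         buffer = buffer),
    class = "habitat_nodes"
  )
}

#' @export
print.habitat_nodes <- function(x, ...) {
  cat(sprintf("%d habitat nodes from %d fixes (buffer %g m)\n",
              nrow(x$nodes), nrow(x$points), x$buffer))
  cat(sprintf("node areas: %.2f-%.2f km2\n",
              min(x$nodes$area_km2), max(x$nodes$area_km2)))
  invisible(x)
}

#' Assign arbitrary points to habitat nodes
#'
#' A point belongs to a node when it falls inside the node polygon, i.e.
#' within `buffer` meters of any member point. Points inside several node
#' polygons are resolved to the node with the nearest centroid; points in
#' no polygon get `NA`.
#'
#' @param x,y Query coordinates in meters.
#' @param nodes A `habitat_nodes` object.
#' @return Integer vector of node ids (`NA` = unassigned).
#' @export
assign_fixes_to_nodes <- function(x, y, nodes) {
  stopifnot(inherits(nodes, "habitat_nodes"))
  mp <- nodes$points
  r <- nodes$buffer
  nq <- length(x)
  out <- rep(NA_integer_, nq)
  if (nq == 0 || nrow(mp) == 0) return(out)
  cs <- r
  mkey <- paste(floor(mp$x / cs), floor(mp$y / cs), sep = ",")
  cells <- split(seq_len(nrow(mp)), mkey)
  r2 <- r^2
  for (q in seq_len(nq)) {
    cqx <- floor(x[q] / cs); cqy <- floor(y[q] / cs)
    nb_keys <- as.vector(outer(cqx + (-1:1), cqy + (-1:1), paste, sep = ","))
    cand <- unlist(cells[intersect(nb_keys, names(cells))], use.names = FALSE)
    if (!length(cand)) next
    d2 <- (mp$x[cand] - x[q])^2 + (mp$y[cand] - y[q])^2
    hit <- unique(mp$node[cand[d2 <= r2]])
    if (length(hit) == 1L) {
      out[q] <- hit
    } else if (length(hit) > 1L) {
      cd <- (nodes$nodes$centroid_x[hit] - x[q])^2 +
        (nodes$nodes$centroid_y[hit] - y[q])^2
      out[q] <- hit[which.min(cd)]
    }
  }
  out
}
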