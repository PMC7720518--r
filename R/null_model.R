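# Distance-kernel random-walk null model: paired simulated tracks on the
# observed node set, governed by a move probability and an empirical
# step-distance weight function, built into replicate null networks with
# the same semantics as the observed network.

#' Estimate the probability of moving between nodes per time step
#'
#' The move probability is the proportion of valid 2-h fix pairs whose two
#' fixes sit at different nodes. Pooled mode uses the ratio of pooled
#' counts across all tracks; per-track mode computes the ratio within each
#' track.
#'
#' @param track_summary Data.frame with `track_id`, `n_valid_pairs`,
#'   `n_moving_pairs` (from [compile_movements()]).
#' @param mode `"pooled"` or `"per_track"`.
#' @return A single probability (pooled) or a named vector per track.
#' @export
estimate_move_prob <- function(track_summary, mode = c("pooled", "per_track")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    tot <- sum(track_summary$n_valid_pairs)
    if (tot == 0) stop("no valid fix pairs in any track")
    return(sum(track_summary$n_moving_pairs) / tot)
  }
  zero <- track_summary$track_id[track_summary$n_valid_pairs == 0]
  if (length(zero))
    stop("track(s) with zero valid fix pairs: ", paste(zero, collapse = ", "))
  stats::setNames(track_summary$n_moving_pairs / track_summary$n_valid_pairs,
                  track_summary$track_id)
}

#' Fit an empirical step-distance weight function
#'
#' Estimates the distance dependence of destination choice from observed
#' between-node step distances. The realized step-distance density is
#' estimated by a Gaussian kernel density estimate on the log10 scale with
#' Silverman's bandwidth (default) or a binned log-scale histogram.
#'
#' The realized (marginal) step-distance distribution mixes the walker's
#' distance preference with the availability of candidate nodes at each
#' distance; reused directly as a per-pair choice weight it double-counts
#' availability, which systematically over-disperses simulated walks. When
#' the `available` candidate distances are supplied (the default path in
#' [simulate_null_networks()]), the weight is therefore the
#' use/availability density ratio -- the same correction logic as
#' resource- and step-selection functions -- which is a consistent
#' estimator of the choice kernel itself. Omit `available` for the plain
#' marginal weight.
#'
#' The returned weight function is floored at a small positive value so no
#' candidate ever has exactly zero weight. A single observed distance
#' falls back to a bandwidth of 0.1 log10 units.
#'
#' @param distances Observed between-node step distances in meters (> 0).
#' @param method `"kde"` (default) or `"histogram"`.
#' @param available Optional vector of available candidate distances
#'   (every possible destination's distance, one set per realized step);
#'   when given, weights are use/availability ratios.
#' @param floor Minimum weight.
#' @return Function mapping distance (meters) to a nonnegative weight,
#'   with class `movement_kernel`.
#' @export
fit_distance_kernel <- function(distances, method = c("kde", "histogram"),
                                available = NULL, floor = 1e-12) {
  method <- match.arg(method)
  dens_fun <- function(values) {
    d <- values[is.finite(values) & values > 0]
    if (!length(d)) stop("no positive step distances to fit a kernel to")
    ld <- log10(d)
    if (method == "kde") {
      bw <- if (length(ld) >= 2) stats::bw.nrd0(ld) else 0.1
      if (!is.finite(bw) || bw <= 0) bw <- 0.1
      list(f = function(z) vapply(z, function(zi) mean(stats::dnorm(zi, ld, bw)), 0),
           bw = bw, n = length(d))
    } else {
      nb <- max(1L, grDevices::nclass.Sturges(ld))
      brk <- seq(min(ld) - 1e-9, max(ld) + 1e-9, length.out = nb + 1L)
      h <- graphics::hist(ld, breaks = brk, plot = FALSE)
      list(f = function(z) {
        i <- findInterval(z, brk, rightmost.closed = TRUE)
        ifelse(i >= 1 & i <= nb, h$density[pmax(i, 1)], 0)
      }, bw = brk, n = length(d))
    }
  }
  use <- dens_fun(distances)
  avail <- if (!is.null(available)) dens_fun(available) else NULL
  f <- function(dist) {
    z <- log10(pmax(dist, .Machine$double.xmin))
    w <- use$f(z)
    if (!is.null(avail)) w <- w / pmax(avail$f(z), floor)
    pmax(w, floor)
  }
  attr(f, "bandwidth") <- use$bw
  attr(f, "method") <- method
  attr(f, "availability_corrected") <- !is.null(avail)
  attr(f, "n_obs") <- use$n
  class(f) <- c("movement_kernel", "function")
  f
}

# Precompute, per current node, the candidate destinations and their
# cumulative move probabilities under a kernel.
.destination_tables <- function(xy, kernel) {
  n <- nrow(xy)
  dest <- vector("list", n)
  cum <- vector("list", n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    d <- sqrt((xy[j, 1] - xy[i, 1])^2 + (xy[j, 2] - xy[i, 2])^2)
    w <- kernel(d)
    p <- w / sum(w)
    dest[[i]] <- j
    cum[[i]] <- cumsum(p)
  }
  list(dest = dest, cum = cum)
}

.simulate_sequence <- function(start, n_steps, p, tabs) {
  out <- integer(n_steps + 1L)
  out[1] <- start
  if (n_steps == 0L) return(out)
  mv <- stats::runif(n_steps) < p
  cur <- start
  prev <- 1L
  for (t in which(mv)) {
    if (t >= prev + 1L) out[(prev + 1L):t] <- cur
    u <- stats::runif(1)
    cw <- tabs$cum[[cur]]
    j <- findInterval(u, cw) + 1L
    cur <- tabs$dest[[cur]][min(j, length(cw))]
    out[t + 1L] <- cur
    prev <- t + 1L
  }
  if (prev <= n_steps) out[(prev + 1L):(n_steps + 1L)] <- cur
  out
}

#' Simulate one random-walk track over the node set
#'
#' At each time step the walker stays with probability `1 - p`; otherwise
#' it moves to another node with probability proportional to the kernel
#' weight of the internode distance.
#'
#' @param start_node Index into `centroids` of the starting node.
#' @param n_steps Number of time steps (sequence length is `n_steps + 1`).
#' @param p Move probability per step.
#' @param kernel A [fit_distance_kernel()] weight function.
#' @param centroids Two-column matrix of node coordinates in meters.
#' @return Integer vector of node indices, length `n_steps + 1`.
#' @export
simulate_track <- function(start_node, n_steps, p, kernel, centroids) {
  centroids <- as.matrix(centroids)
  stopifnot(start_node >= 1, start_node <= nrow(centroids), n_steps >= 0)
  tabs <- .destination_tables(centroids, kernel)
  .simulate_sequence(as.integer(start_node), as.integer(n_steps), p, tabs)
}

#' Simulate replicate null networks paired with the observed tracks
#'
#' For each replicate, simulates one random walk per observed track
#' (same starting node, same number of time steps), collapses each walk
#' into steps and visits, and builds a network with the same semantics as
#' the observed one (including pruning of unvisited/isolated nodes).
#' Movement parameters (move probability and distance kernel) are
#' estimated from the observed tracks, either pooled or per track.
#' Replicates differ only by deterministic per-replicate RNG substreams
#' derived from `seed`.
#'
#' @param net A `habitat_network` from [build_habitat_network()].
#' @param mode `"pooled"` or `"per_track"` parameter estimation.
#' @param n_reps Number of replicate networks (default 50).
#' @param seed Integer seed.
#' @param kernel_method Passed to [fit_distance_kernel()].
#' @param correct_availability Estimate the choice kernel as the
#'   use/availability density ratio (default; see
#'   [fit_distance_kernel()]); `FALSE` uses the plain marginal
#'   step-distance density as the weight.
#' @return List of class `null_network_set`: `networks` (list of igraph),
#'   `mode`, `p`, `seed`, `rep_seeds`.
#' @export
simulate_null_networks <- function(net, mode = c("pooled", "per_track"),
                                   n_reps = 50, seed = 1,
                                   kernel_method = "kde",
                                   correct_availability = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "habitat_network"))
  g <- net$graph
  mv <- net$movements
  vids <- as.integer(igraph::V(g)$name)
  xy <- cbind(igraph::V(g)$centroid_x, igraph::V(g)$centroid_y)
  if (any(!is.finite(xy)))
    stop("null model requires vertex attributes centroid_x / centroid_y")
  # observed step distances as internode (centroid) distances
  step_dist <- function(steps) {
    fi <- match(steps$from, vids)
    ti <- match(steps$to, vids)
    sqrt((xy[fi, 1] - xy[ti, 1])^2 + (xy[fi, 2] - xy[ti, 2])^2)
  }
  # candidate distances available at each realized step's source node
  avail_dist <- function(steps) {
    if (!correct_availability || !nrow(steps)) return(NULL)
    cnt <- table(match(steps$from, vids))
    unlist(lapply(seq_along(cnt), function(q) {
      i <- as.integer(names(cnt)[q])
      d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)[-i]
      rep(d, cnt[q])
    }), use.names = FALSE)
  }
  ts <- mv$track_summary
  ts <- ts[!is.na(ts$start_node) & ts$start_node %in% vids, , drop = FALSE]
  p <- estimate_move_prob(ts, mode)
  if (mode == "pooled") {
    kern <- fit_distance_kernel(step_dist(mv$steps), method = kernel_method,
                                available = avail_dist(mv$steps))
    tabs <- .destination_tables(xy, kern)
    tabs_of <- function(track_id) tabs
    p_of <- function(track_id) p
  } else {
    per <- lapply(ts$track_id, function(id) {
      st <- mv$steps[mv$steps$track_id == id, , drop = FALSE]
      if (!nrow(st)) return(NULL)   # track never moved: p = 0, kernel unused
      kern <- fit_distance_kernel(step_dist(st), method = kernel_method,
                                  available = avail_dist(st))
      .destination_tables(xy, kern)
    })
    names(per) <- ts$track_id
    tabs_of <- function(track_id) per[[track_id]]
    p_of <- function(track_id) p[[track_id]]
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  networks <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    steps_l <- vector("list", nrow(ts))
    visits_l <- vector("list", nrow(ts))
    for (k in seq_len(nrow(ts))) {
      id <- ts$track_id[k]
      start <- match(ts$start_node[k], vids)
      pk <- p_of(id)
      tb <- tabs_of(id)
      seqk <- if (is.null(tb)) {
        rep(start, ts$n_valid_pairs[k] + 1L)
      } else {
        .simulate_sequence(start, ts$n_valid_pairs[k], pk, tb)
      }
      nodes_seq <- vids[seqk]
      chg <- which(diff(nodes_seq) != 0)
      steps_l[[k]] <- data.frame(track_id = id,
                                 from = nodes_seq[chg], to = nodes_seq[chg + 1])
      runs <- nodes_seq[c(TRUE, diff(nodes_seq) != 0)]
      visits_l[[k]] <- data.frame(track_id = id, node = runs)
    }
    steps <- do.call(rbind, steps_l)
    visits <- do.call(rbind, visits_l)
    gr <- .network_from_movements(steps, visits,
                                  node_info = .vertex_info(g))
    networks[[r]] <- clip_and_prune(gr, bbox = NULL)
  }
  structure(list(networks = networks, mode = mode, p = p, seed = seed,
                 rep_seeds = rep_seeds),
            class = "null_network_set")
}

# node_info data.frame recovered from an igraph's vertex attributes
.vertex_info <- function(g) {
  at <- igraph::vertex_attr(g)
  keep <- setdiff(names(at), c("name", "size", "n_birdyears"))
  out <- data.frame(node_id = as.integer(at$name))
  for (col in keep) out[[col]] <- at[[col]]
  out
}

#' @export
print.null_network_set <- function(x, ...) {
  cat(sprintf("null network set: %d replicates (%s parameters, seed %d)\n",
              length(x$networks), x$mode, x$seed))
  invisible(x)
}
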