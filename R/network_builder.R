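# From node-labeled tracks to the directed, weighted habitat network:
# between-node steps within one valid time step become edges (weight =
# relocation count), run-length-collapsed occupancy becomes visits (node
# size), and the network is clipped to the study extent and pruned of
# isolated nodes.

#' Extract between-node steps and the visit sequence of a track
#'
#' Consecutive fix pairs in the same burst with a time gap of at most
#' `interval + tolerance` and two different node labels yield directed
#' steps. Runs of consecutive fixes at the same node collapse into single
#' visits; unassigned fixes (`NA` label) break runs and never form steps.
#'
#' @param track Labeled track data.frame with columns `track_id`,
#'   `timestamp`, `burst_id`, `node`.
#' @param interval,tolerance Fix interval and tolerance in seconds.
#' @return List with `steps` (track_id, from, to, t_from, t_to), `visits`
#'   (track_id, node, t_start, n_fixes), `n_valid_pairs` and
#'   `n_moving_pairs` (counts used to estimate the move probability).
#' @export
extract_steps <- function(track, interval = 7200, tolerance = 1200) {
  n <- nrow(track)
  empty <- list(
    steps = data.frame(track_id = character(0), from = integer(0),
                       to = integer(0), t_from = track$timestamp[0],
                       t_to = track$timestamp[0]),
    visits = data.frame(track_id = character(0), node = integer(0),
                        t_start = track$timestamp[0], n_fixes = integer(0)),
    n_valid_pairs = 0L, n_moving_pairs = 0L)
  if (n == 0) return(empty)
  stopifnot(!is.null(track$node), !is.null(track$burst_id))
  tid <- track$track_id[1]
  t <- as.numeric(track$timestamp)
  node <- track$node
  if (n >= 2) {
    i <- seq_len(n - 1)
    valid <- (track$burst_id[i] == track$burst_id[i + 1]) &
      (t[i + 1] - t[i] <= interval + tolerance) &
      !is.na(node[i]) & !is.na(node[i + 1])
    moving <- valid & node[i] != node[i + 1]
    si <- which(moving)
    steps <- if (length(si)) {
      data.frame(track_id = tid, from = node[si], to = node[si + 1],
                 t_from = track$timestamp[si],
                 t_to = track$timestamp[si + 1])
    } else empty$steps
    n_valid <- sum(valid)
    n_moving <- sum(moving)
  } else {
    steps <- empty$steps
    n_valid <- 0L
    n_moving <- 0L
  }
  # run-length collapse per burst; NA labels break runs and are dropped
  brk <- c(TRUE, (node[-1] != node[-n]) | is.na(node[-1]) | is.na(node[-n]) |
             (track$burst_id[-1] != track$burst_id[-n]))
  run <- cumsum(brk)
  keep <- !is.na(node)
  if (any(keep)) {
    first <- !duplicated(run) & keep
    visits <- data.frame(track_id = tid, node = node[first],
                         t_start = track$timestamp[first],
                         n_fixes = as.integer(table(run[keep])[as.character(run[first])]))
  } else {
    visits <- empty$visits
  }
  list(steps = steps, visits = visits,
       n_valid_pairs = as.integer(n_valid), n_moving_pairs = as.integer(n_moving))
}

#' Pool steps and visits across labeled tracks
#'
#' Runs [extract_steps()] on each track and binds the results, keeping a
#' per-track summary of valid and moving fix pairs.
#'
#' @param tracks Named list of labeled track data.frames.
#' @param interval,tolerance Seconds.
#' @return List with pooled `steps`, `visits`, and `track_summary`
#'   (track_id, n_valid_pairs, n_moving_pairs, start_node, n_fixes).
#' @export
compile_movements <- function(tracks, interval = 7200, tolerance = 1200) {
  parts <- lapply(tracks, extract_steps, interval = interval, tolerance = tolerance)
  steps <- do.call(rbind, c(lapply(parts, `[[`, "steps"), list(make.row.names = FALSE)))
  visits <- do.call(rbind, c(lapply(parts, `[[`, "visits"), list(make.row.names = FALSE)))
  summary <- data.frame(
    track_id = vapply(tracks, function(tr) tr$track_id[1], ""),
    n_valid_pairs = vapply(parts, `[[`, 0L, "n_valid_pairs"),
    n_moving_pairs = vapply(parts, `[[`, 0L, "n_moving_pairs"),
    start_node = vapply(tracks, function(tr) {
      lab <- tr$node[!is.na(tr$node)]
      if (length(lab)) as.integer(lab[1]) else NA_integer_
    }, NA_integer_),
    n_fixes = vapply(tracks, nrow, 0L),
    row.names = NULL
  )
  list(steps = steps, visits = visits, track_summary = summary)
}

# Vertex/edge attribute assembly shared by observed and null networks.
.network_from_movements <- function(steps, visits, node_info = NULL) {
  vids <- sort(unique(c(steps$from, steps$to, visits$node)))
  g <- igraph::make_empty_graph(n = length(vids), directed = TRUE)
  igraph::V(g)$name <- as.character(vids)
  if (nrow(steps)) {
    key <- paste(steps$from, steps$to)
    agg_w <- table(key)
    agg_b <- tapply(steps$track_id, key, function(z) length(unique(z)))
    uk <- names(agg_w)
    ft <- do.call(rbind, strsplit(uk, " ", fixed = TRUE))
    el <- rbind(match(as.integer(ft[, 1]), vids), match(as.integer(ft[, 2]), vids))
    g <- igraph::add_edges(g, as.vector(el))
    igraph::E(g)$weight <- as.integer(agg_w)
    igraph::E(g)$n_birdyears <- as.integer(agg_b[uk])
  }
  size <- tapply(rep(1L, nrow(visits)), visits$node, sum)
  nby <- tapply(visits$track_id, visits$node, function(z) length(unique(z)))
  igraph::V(g)$size <- as.integer(size[as.character(vids)])
  igraph::V(g)$n_birdyears <- as.integer(nby[as.character(vids)])
  if (!is.null(node_info)) {
    idx <- match(vids, node_info$node_id)
    for (col in setdiff(names(node_info), "node_id"))
      g <- igraph::set_vertex_attr(g, col, value = node_info[[col]][idx])
  }
  g
}

#' Build the directed, weighted habitat network
#'
#' Edge (u, v) weight is the number of observed relocations u -> v pooled
#' across bird-years; node size is the pooled visit count; `n_birdyears`
#' on nodes and edges counts the distinct tracks contributing. Self-loops
#' never arise because steps require differing node labels.
#'
#' @param steps,visits Pooled tables from [compile_movements()].
#' @param node_info Optional data.frame of node attributes keyed by
#'   `node_id` (e.g. centroid lon/lat, `area_km2`, `nmds1`) copied onto
#'   vertices.
#' @return An igraph directed graph with vertex names equal to node ids.
#' @export
build_network <- function(steps, visits, node_info = NULL) {
  .network_from_movements(steps, visits, node_info)
}

#' Clip a network to a bounding box and prune isolated nodes
#'
#' Drops nodes whose centroid falls outside the lon/lat bounding box
#' (with incident edges), then drops nodes left with no incident edge.
#'
#' @param g igraph network with vertex attributes `lon`, `lat`.
#' @param bbox Numeric `c(lon_min, lon_max, lat_min, lat_max)`, or `NULL`
#'   to skip clipping (pruning still applies).
#' @return The clipped, pruned igraph.
#' @export
clip_and_prune <- function(g, bbox = NULL) {
  if (!is.null(bbox)) {
    stopifnot(length(bbox) == 4)
    lon <- igraph::V(g)$lon
    lat <- igraph::V(g)$lat
    if (is.null(lon) || is.null(lat))
      stop("clipping requires vertex attributes lon and lat")
    out <- which(lon < bbox[1] | lon > bbox[2] | lat < bbox[3] | lat > bbox[4])
    if (length(out)) g <- igraph::delete_vertices(g, out)
  }
  iso <- which(igraph::degree(g, mode = "all") == 0)
  if (length(iso)) g <- igraph::delete_vertices(g, iso)
  g
}

#' Build, clip, and prune the habitat network with a track report
#'
#' Full network-construction pass: build the graph from pooled movements,
#' clip to the study bounding box, prune isolated nodes, and report which
#' tracks lost every node they used (these are excluded from downstream
#' per-individual analyses).
#'
#' @param movements Output of [compile_movements()].
#' @param node_info Node attribute data.frame (must include `lon`, `lat`
#'   when `bbox` is given).
#' @param bbox Study bounding box `c(lon_min, lon_max, lat_min, lat_max)`
#'   or `NULL`.
#' @return List of class `habitat_network`: `graph`, `dropped_tracks`
#'   (character vector), `movements` (filtered to surviving tracks and
#'   nodes), `node_info`.
#' @export
build_habitat_network <- function(movements, node_info = NULL, bbox = NULL) {
  g <- build_network(movements$steps, movements$visits, node_info)
  g <- clip_and_prune(g, bbox)
  keep_nodes <- as.integer(igraph::V(g)$name)
  by_track <- split(movements$visits$node, movements$visits$track_id)
  dropped <- names(by_track)[!vapply(by_track, function(nd) any(nd %in% keep_nodes), TRUE)]
  mv <- movements
  mv$steps <- mv$steps[mv$steps$from %in% keep_nodes &
                         mv$steps$to %in% keep_nodes &
                         !(mv$steps$track_id %in% dropped), , drop = FALSE]
  mv$visits <- mv$visits[mv$visits$node %in% keep_nodes &
                           !(mv$visits$track_id %in% dropped), , drop = FALSE]
  mv$track_summary <- mv$track_summary[!(mv$track_summary$track_id %in% dropped), , drop = FALSE]
  structure(list(graph = g, dropped_tracks = dropped, movements = mv,
                 node_info = node_info),
            class = "habitat_network")
}

#' @export
print.habitat_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("habitat network: %d nodes, %d directed edges, %d bird-years\n",
              igraph::vcount(g), igraph::ecount(g),
              length(unique(x$movements$visits$track_id))))
  if (length(x$dropped_tracks))
    cat("dropped tracks:", paste(x$dropped_tracks, collapse = ", "), "\n")
  invisible(x)
}
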