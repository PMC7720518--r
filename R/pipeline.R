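#' Run the full habitat-network pipeline
#'
#' One-call orchestration of the analysis stages: read/clean relocations,
#' split into bird-year tracks, resample and speed-filter, cluster fixes
#' into habitat nodes, attach land-cover composition (per-site table
#' path), ordinate compositions into urbanization scores, and build the
#' clipped, pruned habitat network.
#'
#' @param tracks Relocation CSV path or data.frame (Movebank dialect).
#' @param seasons Season-window CSV path or data.frame.
#' @param site_landcover Data.frame/CSV with `site_id`, `lon`, `lat` and
#'   one column per land-cover class (per-site composition rows).
#' @param bbox Study bounding box `c(lon_min, lon_max, lat_min, lat_max)`
#'   or `NULL`.
#' @param proj Analysis projection.
#' @param interval,tolerance,vmax Preprocessing parameters (seconds,
#'   seconds, m/s).
#' @param radius,join_radius Node-building distances in meters.
#' @param nmds_seed Seed for the ordination restarts.
#' @return List of class `habnet_pipeline`: `tracks`, `nodes`,
#'   `landcover`, `scores` (with stress attribute), `movements`, `network`
#'   (a `habitat_network`).
#' @export
run_habitat_pipeline <- function(tracks, seasons, site_landcover,
                                 bbox = c(-80.52, -80, 26.25, 27.5),
                                 proj = eqc_projection(),
                                 interval = 7200, tolerance = 1200, vmax = 12,
                                 radius = 650, join_radius = 325,
                                 nmds_seed = 1) {
  fixes <- read_relocations(tracks)
  windows <- read_season_windows(seasons)
  trk <- preprocess_tracks(fixes, windows, proj, interval, tolerance, vmax)
  if (!length(trk)) stop("no tracks survived preprocessing")
  all_fixes <- do.call(rbind, c(trk, list(make.row.names = FALSE)))
  nodes <- build_nodes(all_fixes, radius, join_radius, proj = proj)
  all_fixes$node <- nodes$membership
  trk <- split(all_fixes, all_fixes$track_id)
  if (is.character(site_landcover))
    site_landcover <- utils::read.csv(site_landcover, check.names = FALSE)
  lc_cols <- setdiff(names(site_landcover), c("site_id", "lon", "lat", "x", "y"))
  sxy <- eqc_forward(proj, site_landcover$lon, site_landcover$lat)
  lc <- site_landcover_to_nodes(nodes, sxy$x, sxy$y,
                                site_landcover[, lc_cols, drop = FALSE])
  scores <- nmds_scores(lc, k = 3, seed = nmds_seed)
  movements <- compile_movements(trk, interval, tolerance)
  node_info <- cbind(nodes$nodes[, c("node_id", "centroid_x", "centroid_y",
                                     "lon", "lat", "area_km2")],
                     nmds1 = scores$nmds1[match(nodes$nodes$node_id,
                                                scores$node_id)])
  network <- build_habitat_network(movements, node_info, bbox)
  structure(list(tracks = trk, nodes = nodes, landcover = lc,
                 scores = scores, movements = movements, network = network),
            class = "habnet_pipeline")
}

#' @export
print.habnet_pipeline <- function(x, ...) {
  cat(sprintf("habnet pipeline: %d tracks -> %d nodes; ", length(x$tracks),
              nrow(x$nodes$nodes)))
  print(x$network)
  invisible(x)
}
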