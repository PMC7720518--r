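# Land-cover composition of habitat nodes and the continuous urbanization
# score derived from it (NMDS axis 1 of Bray-Curtis dissimilarities).

#' The 12 analysis land-cover classes
#'
#' Habitat classes relevant to a wading bird moving between urban and
#' wetland sites; source land-cover products are reclassified onto these.
#'
#' @return Character vector of 12 class labels.
#' @export
landcover_classes <- function() {
  c("artificial_impoundments_reservoirs", "coastal", "cropland",
    "estuarine", "forest", "freshwater_forested_wetlands",
    "freshwater_nonforested_wetlands", "lakes", "parks_zoos",
    "scrub", "urban", "urban_open_land")
}

# classes treated as human-dominated when orienting the ordination
.urbanish_classes <- function() c("urban", "urban_open_land", "parks_zoos")

#' In-memory categorical grid raster
#'
#' Minimal planar categorical raster: a matrix of class labels (or source
#' codes) with a rectangular extent in projected meters. Cell (i, j) of
#' `values` covers row i from the top (max y) and column j from the left
#' (min x).
#'
#' @param values Matrix of class labels/codes.
#' @param xmin,xmax,ymin,ymax Extent in meters.
#' @return Object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin, xmax, ymin, ymax) {
  stopifnot(is.matrix(values), xmax > xmin, ymax > ymin)
  structure(list(values = values, xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax,
                 dx = (xmax - xmin) / ncol(values),
                 dy = (ymax - ymin) / nrow(values)),
            class = "grid_raster")
}

#' Reclassify land-cover codes
#'
#' Maps source land-cover codes to the 12 analysis classes using a lookup
#' table. Any code present in the input but absent from the map is a hard
#' error naming the offending codes.
#'
#' @param x A vector of source codes, or a [grid_raster()].
#' @param class_map Data.frame with columns `source_code`, `target_class`.
#' @return Reclassified vector or raster.
#' @export
reclassify_landcover <- function(x, class_map) {
  stopifnot(all(c("source_code", "target_class") %in% names(class_map)))
  if (inherits(x, "grid_raster")) {
    v <- x$values
    v[] <- reclassify_landcover(as.vector(v), class_map)
    x$values <- v
    return(x)
  }
  idx <- match(as.character(x), as.character(class_map$source_code))
  if (anyNA(idx)) {
    bad <- unique(as.character(x)[is.na(idx)])
    stop("unmapped land-cover code(s): ", paste(bad, collapse = ", "))
  }
  as.character(class_map$target_class)[idx]
}

#' Per-node land-cover proportions from a categorical raster
#'
#' For each node, tabulates the classes of raster cells whose centers fall
#' inside the node polygon (within the node buffer of a member point) and
#' normalizes to proportions.
#'
#' @param nodes A `habitat_nodes` object.
#' @param raster A reclassified [grid_raster()] in the same projection,
#'   with values drawn from [landcover_classes()].
#' @return Matrix (nodes x 12 classes) of proportions; rows sum to 1.
#'   Row names are node ids.
#' @export
extract_node_landcover <- function(nodes, raster) {
  stopifnot(inherits(nodes, "habitat_nodes"), inherits(raster, "grid_raster"))
  classes <- landcover_classes()
  if (!all(unique(as.vector(raster$values)) %in% classes))
    stop("raster contains labels outside landcover_classes(); reclassify first")
  nn <- nrow(nodes$nodes)
  out <- matrix(0, nn, length(classes), dimnames = list(nodes$nodes$node_id, classes))
  r <- nodes$buffer
  ncol_r <- ncol(raster$values); nrow_r <- nrow(raster$values)
  cell_x <- raster$xmin + (seq_len(ncol_r) - 0.5) * raster$dx
  cell_y <- raster$ymax - (seq_len(nrow_r) - 0.5) * raster$dy
  for (k in seq_len(nn)) {
    id <- nodes$nodes$node_id[k]
    px <- nodes$points$x[nodes$points$node == id]
    py <- nodes$points$y[nodes$points$node == id]
    if (min(px) - r < raster$xmin || max(px) + r > raster$xmax ||
        min(py) - r < raster$ymin || max(py) + r > raster$ymax)
      stop("node ", id, " polygon extends outside the raster extent")
    jx <- which(cell_x >= min(px) - r & cell_x <= max(px) + r)
    jy <- which(cell_y >= min(py) - r & cell_y <= max(py) + r)
    if (!length(jx) || !length(jy))
      stop("node ", id, " covers no raster cells")
    gx <- rep(cell_x[jx], each = length(jy))
    gy <- rep(cell_y[jy], times = length(jx))
    inside <- rep(FALSE, length(gx))
    for (m in seq_along(px)) {
      inside <- inside | ((gx - px[m])^2 + (gy - py[m])^2 <= r^2)
    }
    if (!any(inside)) stop("node ", id, " covers no raster cells")
    vals <- as.vector(raster$values[jy, jx, drop = FALSE])[inside]
    tab <- table(factor(vals, levels = classes))
    out[k, ] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' Per-node land-cover proportions from per-site composition rows
#'
#' Alternative to the raster path: when land cover is supplied as one
#' composition row per site, node composition is the mean of the rows of
#' the sites falling inside the node polygon, renormalized.
#'
#' @param nodes A `habitat_nodes` object.
#' @param site_x,site_y Site coordinates in meters.
#' @param site_props Matrix/data.frame of per-site class proportions
#'   (sites x classes).
#' @return Matrix (nodes x classes); rows sum to 1, row names node ids.
#' @export
site_landcover_to_nodes <- function(nodes, site_x, site_y, site_props) {
  site_props <- as.matrix(site_props)
  assignment <- assign_fixes_to_nodes(site_x, site_y, nodes)
  ids <- nodes$nodes$node_id
  orphan <- ids[!ids %in% assignment]
  if (length(orphan))
    stop("no land-cover site falls inside node(s): ", paste(orphan, collapse = ", "))
  out <- t(vapply(ids, function(id) {
    rows <- site_props[which(assignment == id), , drop = FALSE]
    p <- colMeans(rows)
    p / sum(p)
  }, numeric(ncol(site_props))))
  dimnames(out) <- list(ids, colnames(site_props))
  out
}

#' Urbanization scores by non-metric multidimensional scaling
#'
#' Ordinates node land-cover compositions by NMDS in `k` dimensions on
#' Bray-Curtis dissimilarities (untransformed proportions), using at least
#' 20 seeded random restarts and keeping the lowest-stress solution. The
#' first axis is oriented so that human-dominated nodes (majority class
#' `urban`, or, lacking any, positive correlation with the summed
#' urban-type proportions) have positive scores; `nmds1` then serves as a
#' continuous urbanization score.
#'
#' @param lc Node x class proportion matrix (rows sum to 1).
#' @param k Number of ordination dimensions (default 3).
#' @param seed RNG seed controlling the random restarts.
#' @param trymax Maximum number of restarts (>= 20 are always attempted).
#' @return Data.frame `node_id`, `nmds1` ... `nmds{k}` with the final
#'   stress (0-1 scale) in attribute `stress`.
#' @export
nmds_scores <- function(lc, k = 3, seed = 1, trymax = 50) {
  lc <- as.matrix(lc)
  if (nrow(unique(lc)) < k + 2)
    stop("need at least k + 2 distinct composition rows for a ", k, "-D ordination")
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(lc, distance = "bray", k = k, try = 20,
                   trymax = max(20, trymax), trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  ))
  sc <- vegan::scores(fit, display = "sites")
  urbanish <- intersect(.urbanish_classes(), colnames(lc))
  maj <- colnames(lc)[max.col(lc, ties.method = "first")]
  urban_major <- maj == "urban"
  flip <- if (any(urban_major)) {
    mean(sc[urban_major, 1]) < 0
  } else if (length(urbanish)) {
    stats::cor(sc[, 1], rowSums(lc[, urbanish, drop = FALSE])) < 0
  } else FALSE
  if (isTRUE(flip)) sc[, 1] <- -sc[, 1]
  out <- data.frame(node_id = rownames(lc), sc, row.names = NULL)
  names(out) <- c("node_id", paste0("nmds", seq_len(k)))
  attr(out, "stress") <- fit$stress
  out
}
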