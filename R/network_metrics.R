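# Network- and node-level connectivity metrics, module detection, and the
# observed-vs-null and node-attribute statistical models.

#' Edge density of a directed network
#'
#' Realized fraction of possible directed edges, m / (n (n - 1)),
#' self-loops excluded.
#'
#' @param g igraph directed graph with at least 2 vertices.
#' @return Scalar in (0, 1].
#' @export
edge_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("edge density needs at least 2 nodes")
  m <- igraph::ecount(igraph::simplify(g, remove.multiple = TRUE,
                                       remove.loops = TRUE))
  m / (n * (n - 1))
}

#' Assortativity of a numeric node attribute
#'
#' Pearson correlation between the attribute value at an edge's source and
#' at its target, over all directed edges. By default each realized edge
#' counts once (unweighted); with `weighted = TRUE` each edge is expanded
#' by its relocation count, so the correlation is over individual
#' between-node movements -- more sensitive to graded preference than the
#' presence/absence version. Positive values mean like connects to like.
#' Returns `NA` when either endpoint set has zero variance.
#'
#' @param g igraph directed graph.
#' @param values Numeric vertex values, in vertex order.
#' @param weighted Expand edges by their `weight` attribute.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
assortativity_numeric <- function(g, values, weighted = FALSE) {
  stopifnot(length(values) == igraph::vcount(g))
  if (igraph::ecount(g) < 2) return(NA_real_)
  el <- igraph::as_edgelist(g, names = FALSE)
  xs <- values[el[, 1]]
  xt <- values[el[, 2]]
  if (weighted) {
    w <- igraph::E(g)$weight
    if (is.null(w)) w <- rep(1L, nrow(el))
    xs <- rep(xs, w)
    xt <- rep(xt, w)
  }
  if (stats::sd(xs) == 0 || stats::sd(xt) == 0) return(NA_real_)
  stats::cor(xs, xt)
}

#' Detect modules on the weighted undirected projection
#'
#' Projects the directed network onto an undirected weighted graph
#' (reciprocal edge weights summed) and detects communities. The primary
#' method is greedy agglomerative modularity optimization; edge
#' betweenness and simulated annealing (spin glass, largest connected
#' component only) are available for membership cross-comparison. Q is the
#' standard Newman-Girvan weighted modularity of the detected partition.
#'
#' @param g igraph directed graph with edge attribute `weight`.
#' @param method `"greedy"`, `"edge_betweenness"`, or `"annealing"`.
#' @return List with `membership` (named by vertex), `Q`, `n_modules`,
#'   `method`.
#' @export
detect_modules <- function(g, method = c("greedy", "edge_betweenness", "annealing")) {
  method <- match.arg(method)
  if (igraph::ecount(g) < 1) stop("module detection needs at least one edge")
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "sum", "ignore"))
  if (method == "annealing") {
    comp <- igraph::components(gu)
    big <- which.max(comp$csize)
    gq <- igraph::induced_subgraph(gu, which(comp$membership == big))
    comm <- igraph::cluster_spinglass(gq, weights = igraph::E(gq)$weight)
  } else {
    gq <- gu
    comm <- switch(method,
      greedy = igraph::cluster_fast_greedy(gq, weights = igraph::E(gq)$weight),
      edge_betweenness = suppressWarnings(
        igraph::cluster_edge_betweenness(gq, weights = igraph::E(gq)$weight)))
  }
  memb <- igraph::membership(comm)
  Q <- igraph::modularity(gq, memb, weights = igraph::E(gq)$weight)
  # an optimized partition can never beat the trivial one and still have
  # Q < 0; fall back to a single module (Q = 0 exactly) in that case
  if (is.finite(Q) && Q < 0) {
    memb[] <- 1L
    Q <- igraph::modularity(gq, memb, weights = igraph::E(gq)$weight)
  }
  list(membership = memb, Q = Q, n_modules = length(unique(memb)),
       method = method)
}

#' Node-level connectivity metrics
#'
#' Out-degree (number of distinct successor nodes), betweenness on the
#' directed graph (unweighted shortest paths, normalized by
#' (n-1)(n-2)), and the stored node size (pooled visit count).
#'
#' @param g igraph directed graph.
#' @return Data.frame `node_id`, `out_degree`, `betweenness`, `size`, plus
#'   `nmds1`, `lon`, `lat` when present as vertex attributes.
#' @export
node_metrics <- function(g) {
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  out <- data.frame(
    node_id = igraph::V(g)$name,
    out_degree = as.integer(igraph::degree(gs, mode = "out")),
    betweenness = igraph::betweenness(g, directed = TRUE, weights = NA,
                                      normalized = TRUE),
    row.names = NULL
  )
  for (col in c("size", "nmds1", "lon", "lat", "area_km2")) {
    v <- igraph::vertex_attr(g, col)
    if (!is.null(v)) out[[col]] <- v
  }
  out
}

#' Network-level metric vector
#'
#' Computes edge density, urbanization-score assortativity, modularity
#' (greedy optimization), module count, and optionally the per-class
#' land-cover assortativities, as one named vector. Used for both the
#' observed network and every null replicate.
#'
#' @param g igraph directed graph with vertex attribute `nmds1` (or pass
#'   `scores`).
#' @param scores Optional named numeric vector of nmds1 by node id.
#' @param landcover Optional node x class proportion matrix (row names =
#'   node ids) for per-class assortativity.
#' @param modules Logical; include modularity (default TRUE).
#' @return Named numeric vector.
#' @export
network_metric_table <- function(g, scores = NULL, landcover = NULL,
                                 modules = TRUE) {
  vals <- if (is.null(scores)) igraph::V(g)$nmds1 else
    unname(scores[igraph::V(g)$name])
  out <- c(edge_density = edge_density(g),
           assortativity_nmds1 = assortativity_numeric(g, vals),
           assortativity_nmds1_w = assortativity_numeric(g, vals, weighted = TRUE))
  if (modules) {
    md <- detect_modules(g, "greedy")
    out <- c(out, modularity_q = md$Q, n_modules = md$n_modules)
  }
  if (!is.null(landcover)) {
    lc <- as.matrix(landcover)[igraph::V(g)$name, , drop = FALSE]
    ac <- vapply(colnames(lc), function(cl) assortativity_numeric(g, lc[, cl]), 0)
    names(ac) <- paste0("assort_class_", colnames(lc))
    out <- c(out, ac)
  }
  out
}

#' Compare observed network metrics with a null distribution
#'
#' For each metric: the observed value, null mean and SD, a z-score
#' ((obs - mean)/SD; flagged undefined when the null SD is 0 and the
#' observed value differs), and the two-group linear-model contrast of
#' metric on network type (observed vs simulated).
#'
#' @param obs Named numeric vector of observed metrics
#'   ([network_metric_table()]).
#' @param null_mat Matrix of null metrics, one row per replicate, columns
#'   matching `obs`.
#' @return Data.frame with one row per metric: `metric`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `z_defined`, `lm_estimate`, `lm_p`.
#' @export
compare_observed_null <- function(obs, null_mat) {
  null_mat <- as.matrix(null_mat)
  stopifnot(nrow(null_mat) >= 2)
  metrics <- intersect(names(obs), colnames(null_mat))
  rows <- lapply(metrics, function(mn) {
    nv <- null_mat[, mn]
    ok <- is.finite(nv)
    mu <- mean(nv[ok]); sdv <- stats::sd(nv[ok])
    z_def <- sdv > 0 || obs[[mn]] == mu
    z <- if (sdv > 0) (obs[[mn]] - mu) / sdv else if (z_def) 0 else NA_real_
    dat <- data.frame(value = c(obs[[mn]], nv[ok]),
                      type = factor(c("observed", rep("simulated", sum(ok))),
                                    levels = c("observed", "simulated")))
    fit <- try(stats::lm(value ~ type, data = dat), silent = TRUE)
    cf <- if (!inherits(fit, "try-error"))
      suppressWarnings(summary(fit)$coefficients) else NULL
    has <- !is.null(cf) && "typesimulated" %in% rownames(cf) && ncol(cf) >= 4
    data.frame(metric = mn, observed = unname(obs[[mn]]), null_mean = mu,
               null_sd = sdv, z = z, z_defined = z_def,
               lm_estimate = if (has) cf["typesimulated", 1] else NA_real_,
               lm_p = if (has) cf["typesimulated", 4] else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Land-cover class assortativity model (type x class interaction)
#'
#' Linear model of per-class assortativity on network type, land-cover
#' class, and their interaction, over the observed network and all null
#' replicates.
#'
#' @param obs,null_mat As in [compare_observed_null()]; only columns
#'   prefixed `assort_class_` are used.
#' @return The fitted `lm` object.
#' @export
class_assortativity_model <- function(obs, null_mat) {
  cols <- grep("^assort_class_", names(obs), value = TRUE)
  if (!length(cols)) stop("no per-class assortativity columns present")
  obs_df <- data.frame(value = unname(obs[cols]),
                       class = sub("^assort_class_", "", cols),
                       type = "observed")
  nm <- as.matrix(null_mat)[, cols, drop = FALSE]
  null_df <- data.frame(value = as.vector(nm),
                        class = rep(sub("^assort_class_", "", cols),
                                    each = nrow(nm)),
                        type = "simulated")
  dat <- rbind(obs_df, null_df)
  dat <- dat[is.finite(dat$value), , drop = FALSE]
  dat$type <- factor(dat$type, levels = c("observed", "simulated"))
  stats::lm(value ~ type * class, data = dat)
}

#' GLMs of node connectivity on urbanization and spatial position
#'
#' Fits the three node-attribute models: out-degree and node size as
#' Poisson (log link), and log(betweenness) as Gaussian restricted to
#' nodes with positive betweenness. Predictors are the urbanization score
#' (nmds1), latitude, longitude and their quadratics, all centered and
#' scaled to mean 0 / SD 1.
#'
#' @param nm Node metric data.frame from [node_metrics()] with `nmds1`,
#'   `lat`, `lon` columns.
#' @return List of coefficient tables (`out_degree`, `size`,
#'   `log_betweenness`) and the scaled design (`design`).
#' @export
node_attribute_glms <- function(nm) {
  need <- c("out_degree", "size", "betweenness", "nmds1", "lat", "lon")
  miss <- setdiff(need, names(nm))
  if (length(miss)) stop("missing node metric columns: ", paste(miss, collapse = ", "))
  nm <- nm[stats::complete.cases(nm[, need]), , drop = FALSE]
  if (nrow(nm) < 10) stop("need at least 10 nodes with complete covariates")
  X <- data.frame(nmds1 = nm$nmds1, lat = nm$lat, lon = nm$lon,
                  lat2 = nm$lat^2, lon2 = nm$lon^2)
  X <- as.data.frame(scale(X))
  coefs <- function(fit) {
    cf <- summary(fit)$coefficients
    data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
               p = cf[, 4], row.names = NULL)
  }
  f <- stats::as.formula(paste("y ~", paste(names(X), collapse = " + ")))
  m_deg <- stats::glm(f, data = cbind(y = nm$out_degree, X), family = stats::poisson())
  m_size <- stats::glm(f, data = cbind(y = nm$size, X), family = stats::poisson())
  pos <- nm$betweenness > 0
  m_btw <- if (sum(pos) >= 10) {
    stats::lm(f, data = cbind(y = log(nm$betweenness[pos]), X[pos, , drop = FALSE]))
  } else NULL
  list(out_degree = coefs(m_deg), size = coefs(m_size),
       log_betweenness = if (!is.null(m_btw)) coefs(m_btw) else NULL,
       design = X)
}

#' One-way ANOVA of urbanization score on module membership
#'
#' Tests whether detected modules differ systematically in urbanization.
#'
#' @param membership Module id per node (from [detect_modules()]).
#' @param nmds1 Urbanization score per node, same order.
#' @return List `F`, `p`, `df`, and `degenerate` (TRUE when the
#'   within-group sum of squares is zero).
#' @export
module_anova <- function(membership, nmds1) {
  grp <- factor(membership)
  if (nlevels(grp) < 2) stop("need at least 2 modules")
  fit <- stats::aov(nmds1 ~ grp)
  tab <- summary(fit)[[1]]
  within_ss <- tab["Residuals", "Sum Sq"]
  degenerate <- is.na(tab[1, "F value"]) || within_ss <= .Machine$double.eps
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(tab[1, "Df"], tab["Residuals", "Df"]),
       degenerate = degenerate)
}
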