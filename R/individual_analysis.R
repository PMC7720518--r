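# Per-individual habitat specialization (visit-weighted mean/SD of the
# urbanization score) and each individual's contribution to connectivity
# (knockout deltas of edge density and assortativity).

#' Visit-weighted habitat profile of one individual
#'
#' Weighted mean and weighted standard deviation of node urbanization
#' scores, weighting each node by the number of visits (frequency-weight
#' semantics: the SD denominator is the total weight minus 1). A single
#' visited node, or total weight 1, gives SD 0.
#'
#' @param node_scores Urbanization score of each visited node.
#' @param weights Visit counts, same length.
#' @return List `wmean`, `wsd`, `n_nodes_used`.
#' @export
habitat_profile <- function(node_scores, weights) {
  ok <- is.finite(node_scores) & is.finite(weights) & weights > 0
  x <- node_scores[ok]
  w <- weights[ok]
  if (!length(x)) stop("no visited node with a score")
  sw <- sum(w)
  wmean <- sum(w * x) / sw
  wsd <- if (length(x) == 1L || sw <= 1) 0 else
    sqrt(sum(w * (x - wmean)^2) / (sw - 1))
  list(wmean = wmean, wsd = wsd, n_nodes_used = length(x))
}

#' Habitat profiles for all tracks (or birds)
#'
#' @param visits Pooled visit table (`track_id`, `node`).
#' @param scores Data.frame `node_id`, `nmds1` (from [nmds_scores()]).
#' @param group_map Optional data.frame `track_id`, `group` pooling tracks
#'   (e.g. into birds); default one group per track.
#' @return Data.frame `id`, `n_nodes_used`, `wmean_nmds1`, `wsd_nmds1`.
#' @export
habitat_profiles <- function(visits, scores, group_map = NULL) {
  sc <- stats::setNames(scores$nmds1, as.character(scores$node_id))
  grp <- if (is.null(group_map)) visits$track_id else
    group_map$group[match(visits$track_id, group_map$track_id)]
  ids <- unique(grp)
  rows <- lapply(ids, function(id) {
    v <- visits$node[grp == id]
    cnt <- table(v)
    pr <- habitat_profile(sc[names(cnt)], as.numeric(cnt))
    data.frame(id = id, n_nodes_used = pr$n_nodes_used,
               wmean_nmds1 = pr$wmean, wsd_nmds1 = pr$wsd)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Density and assortativity from a pooled step table on a fixed vertex set.
.edge_metrics <- function(steps, node_set, scores) {
  keep <- steps$from %in% node_set & steps$to %in% node_set
  uq <- unique(steps[keep, c("from", "to")])
  n <- length(node_set)
  dens <- nrow(uq) / (n * (n - 1))
  assort <- if (nrow(uq) >= 2) {
    xs <- scores[as.character(uq$from)]
    xt <- scores[as.character(uq$to)]
    if (stats::sd(xs) == 0 || stats::sd(xt) == 0) NA_real_ else stats::cor(xs, xt)
  } else NA_real_
  list(density = dens, assortativity = assort, m = nrow(uq))
}

#' Knockout analysis: each individual's contribution to connectivity
#'
#' Removes one track (or one bird's tracks) at a time, rebuilds the
#' network from the remaining movements, and records the change in edge
#' density and urbanization-score assortativity (sparse minus full, plus
#' percent change for density). By default the full network's node set is
#' held fixed, under which edge density can only decrease upon removal;
#' `drop_empty_nodes = TRUE` instead re-prunes nodes left without edges
#' (the denominator n(n-1) then shrinks too).
#'
#' @param net A `habitat_network` from [build_habitat_network()].
#' @param scores Data.frame `node_id`, `nmds1`.
#' @param group_map Optional `track_id`/`group` data.frame pooling tracks
#'   into birds; default one knockout per track.
#' @param drop_empty_nodes Logical (default `FALSE`).
#' @return Data.frame, one row per removed unit: `id`, `delta_density`,
#'   `pct_density`, `delta_assortativity`, `flagged` (TRUE when the
#'   sparse network was empty or a metric was undefined).
#' @export
knockout_analysis <- function(net, scores, group_map = NULL,
                              drop_empty_nodes = FALSE) {
  stopifnot(inherits(net, "habitat_network"))
  steps <- net$movements$steps
  node_set <- as.integer(igraph::V(net$graph)$name)
  sc <- stats::setNames(scores$nmds1, as.character(scores$node_id))
  full_set <- if (drop_empty_nodes)
    sort(unique(c(steps$from, steps$to))) else node_set
  full <- .edge_metrics(steps, full_set, sc)
  all_tracks <- net$movements$track_summary$track_id
  grp <- if (is.null(group_map)) {
    stats::setNames(all_tracks, all_tracks)
  } else stats::setNames(group_map$group, group_map$track_id)
  units <- unique(unname(grp[names(grp) %in% all_tracks]))
  if (length(units) < 2) stop("knockout needs at least 2 tracks in the network")
  rows <- lapply(units, function(u) {
    drop_tracks <- names(grp)[grp == u]
    sp <- steps[!(steps$track_id %in% drop_tracks), , drop = FALSE]
    if (!nrow(sp)) {
      return(data.frame(id = u, delta_density = NA_real_, pct_density = NA_real_,
                        delta_assortativity = NA_real_, flagged = TRUE))
    }
    sparse_set <- if (drop_empty_nodes)
      sort(unique(c(sp$from, sp$to))) else full_set
    sparse <- .edge_metrics(sp, sparse_set, sc)
    data.frame(
      id = u,
      delta_density = sparse$density - full$density,
      pct_density = 100 * (sparse$density - full$density) / full$density,
      delta_assortativity = sparse$assortativity - full$assortativity,
      flagged = !is.finite(sparse$assortativity) || !is.finite(full$assortativity))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "full") <- full
  out
}

#' Specialization and connectivity-role models
#'
#' Three ordinary least-squares models: (A) weighted mean urbanization on
#' its weighted SD and the quadratic term (the hump-shaped mean-variation
#' relation); (B) knockout change in edge density, and (C) in
#' assortativity, each on weighted mean and weighted SD.
#'
#' @param profiles Output of [habitat_profiles()].
#' @param knockouts Output of [knockout_analysis()] (ids must match).
#' @return List of coefficient tables `mean_vs_sd`, `density_role`,
#'   `assortativity_role`.
#' @export
specialization_models <- function(profiles, knockouts) {
  if (nrow(profiles) < 10) stop("need at least 10 profiles")
  dat <- merge(profiles, knockouts, by = "id")
  coefs <- function(fit) {
    mm <- stats::model.matrix(fit)
    if (qr(mm)$rank < ncol(mm)) stop("rank-deficient model: collinear predictors")
    cf <- summary(fit)$coefficients
    data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
               p = cf[, 4], row.names = NULL)
  }
  mA <- stats::lm(wmean_nmds1 ~ wsd_nmds1 + I(wsd_nmds1^2), data = profiles)
  mB <- stats::lm(delta_density ~ wmean_nmds1 + wsd_nmds1, data = dat)
  mC <- stats::lm(delta_assortativity ~ wmean_nmds1 + wsd_nmds1, data = dat)
  list(mean_vs_sd = coefs(mA), density_role = coefs(mB),
       assortativity_role = coefs(mC))
}

#' One-way ANOVA of node urbanization on individual identity
#'
#' Tests whether individuals (tracks or birds) differ in the urbanization
#' scores of the nodes they visit, over the dataset of all visits.
#'
#' @param visits Pooled visit table (`track_id`, `node`).
#' @param scores Data.frame `node_id`, `nmds1`.
#' @param group_map Optional `track_id`/`group` pooling (bird level).
#' @return List `F`, `p`, `df`.
#' @export
individual_anova <- function(visits, scores, group_map = NULL) {
  sc <- stats::setNames(scores$nmds1, as.character(scores$node_id))
  grp <- if (is.null(group_map)) visits$track_id else
    group_map$group[match(visits$track_id, group_map$track_id)]
  dat <- data.frame(score = sc[as.character(visits$node)], id = factor(grp))
  dat <- dat[is.finite(dat$score), , drop = FALSE]
  if (nlevels(droplevels(dat$id)) < 2) stop("need at least 2 individuals")
  fit <- stats::aov(score ~ id, data = dat)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(tab[1, "Df"], tab["Residuals", "Df"]))
}

#' Pool track-level analyses to the bird level
#'
#' Convenience wrapper running profiles, knockouts (all of a bird's
#' tracks removed at once), and the specialization models with tracks
#' pooled by bird.
#'
#' @param net A `habitat_network`.
#' @param scores Data.frame `node_id`, `nmds1`.
#' @param bird_map Data.frame `track_id`, `bird_id`.
#' @param drop_empty_nodes Passed to [knockout_analysis()].
#' @return List `profiles`, `knockouts`, `models`, `anova`.
#' @export
aggregate_to_bird <- function(net, scores, bird_map, drop_empty_nodes = FALSE) {
  stopifnot(all(c("track_id", "bird_id") %in% names(bird_map)))
  gm <- data.frame(track_id = bird_map$track_id, group = bird_map$bird_id)
  profiles <- habitat_profiles(net$movements$visits, scores, gm)
  knockouts <- knockout_analysis(net, scores, gm, drop_empty_nodes)
  models <- if (nrow(profiles) >= 10) specialization_models(profiles, knockouts) else NULL
  anova <- individual_anova(net$movements$visits, scores, gm)
  list(profiles = profiles, knockouts = knockouts, models = models,
       anova = anova)
}
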