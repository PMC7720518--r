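# Synthetic study system: a landscape of spatially separated urban and
# natural foraging/roosting sites with Dirichlet land-cover archetypes,
# and agents whose movements have controllable habitat specialization,
# site fidelity, and an exponential distance kernel (deliberately a
# different functional form from the analysis-side KDE so generator and
# estimator are not circular). Outputs use the same tracking-CSV dialect
# the ingestion functions consume.

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Dirichlet concentration parameters of the two habitat archetypes over
# the 12 land-cover classes. Concentrations are kept moderate so patches
# of one type still vary substantially in composition -- an urbanization
# gradient rather than a binary label -- as real land-cover data do.
.archetype_alpha <- function(type) {
  cl <- landcover_classes()
  a <- stats::setNames(rep(0.3, length(cl)), cl)
  if (type == "urban") {
    a["urban"] <- 6; a["urban_open_land"] <- 2.5; a["parks_zoos"] <- 1.5
    a["lakes"] <- 1; a["forest"] <- 0.5
  } else {
    a["freshwater_nonforested_wetlands"] <- 6
    a["freshwater_forested_wetlands"] <- 2.5; a["scrub"] <- 1.5
    a["estuarine"] <- 0.8; a["lakes"] <- 0.8; a["cropland"] <- 0.5
  }
  a
}

#' Generate a synthetic landscape of habitat sites
#'
#' Sites are placed uniformly in a lon/lat bounding box by rejection
#' sampling subject to a minimum projected separation (default 1500 m,
#' comfortably above twice the 650-m clustering radius so each site maps
#' to its own habitat node), and each site receives a land-cover
#' composition drawn from its type's Dirichlet archetype.
#'
#' The default bounding box is a roughly 30 x 33 km core inside the South
#' Florida study extent: tracked birds' habitat patches concentrate around
#' their capture region rather than spreading uniformly over the full
#' clipping extent, and inter-site spacings of a few kilometers match the
#' within-season movement scale of the simulated agents.
#'
#' @param n_sites Number of sites (>= 4).
#' @param frac_urban Fraction of sites of urban type.
#' @param bbox Lon/lat bounding box `c(lon_min, lon_max, lat_min,
#'   lat_max)` for site placement.
#' @param min_sep Minimum inter-site distance in meters.
#' @param seed Integer seed.
#' @param proj Analysis projection.
#' @return Object of class `synthetic_landscape`: `sites` (site_id, lon,
#'   lat, x, y, type), `landcover` (site x 12 matrix), `bbox`, `proj`.
#' @export
make_landscape <- function(n_sites = 20, frac_urban = 0.5,
                           bbox = c(-80.4, -80.1, 26.45, 26.75),
                           min_sep = 1500, seed = 1, proj = eqc_projection()) {
  stopifnot(n_sites >= 4, frac_urban >= 0, frac_urban <= 1)
  set.seed(seed)
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n_sites) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place sites; lower min_sep or n_sites")
    lon <- stats::runif(1, bbox[1], bbox[2])
    lat <- stats::runif(1, bbox[3], bbox[4])
    xy <- eqc_forward(proj, lon, lat)
    if (length(xs) == 0 ||
        min((xs - xy$x)^2 + (ys - xy$y)^2) >= min_sep^2) {
      xs <- c(xs, xy$x); ys <- c(ys, xy$y)
    }
  }
  n_urban <- round(frac_urban * n_sites)
  type <- sample(c(rep("urban", n_urban), rep("natural", n_sites - n_urban)))
  lc <- matrix(0, n_sites, length(landcover_classes()),
               dimnames = list(seq_len(n_sites), landcover_classes()))
  for (tp in c("urban", "natural")) {
    idx <- which(type == tp)
    if (length(idx))
      lc[idx, ] <- .rdirichlet(length(idx), .archetype_alpha(tp))
  }
  ll <- eqc_inverse(proj, xs, ys)
  structure(list(
    sites = data.frame(site_id = seq_len(n_sites), lon = ll$lon, lat = ll$lat,
                       x = xs, y = ys, type = type),
    landcover = lc, bbox = bbox, proj = proj, seed = seed),
    class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("synthetic landscape: %d sites (%d urban, %d natural)\n",
              nrow(x$sites), sum(x$sites$type == "urban"),
              sum(x$sites$type == "natural")))
  invisible(x)
}

#' Build an agent specification table
#'
#' Each agent has a preferred habitat type (`"urban"`, `"natural"`, or
#' `"none"`), a specialization strength `s` in \[0, 1\] (0 = type-blind,
#' 1 = never uses the other type), a per-step stay probability `fidelity`,
#' an exponential distance-kernel scale `lambda` (meters), and a number of
#' 2-h steps.
#'
#' @param n_urban,n_natural,n_generalist Counts of urban specialists,
#'   natural specialists, and type-blind generalists.
#' @param s Specialization of the specialists.
#' @param fidelity Stay probability per step (site fidelity).
#' @param lambda Distance-kernel scale in meters.
#' @param n_steps Steps per agent (fixes = steps + 1).
#' @return Data.frame of agent specs.
#' @export
make_agents <- function(n_urban = 0, n_natural = 0, n_generalist = 0,
                        s = 0.9, fidelity = 0.5, lambda = 15000,
                        n_steps = 500) {
  n <- n_urban + n_natural + n_generalist
  stopifnot(n > 0)
  data.frame(
    agent_id = sprintf("agent%02d", seq_len(n)),
    preferred_type = c(rep("urban", n_urban), rep("natural", n_natural),
                       rep("none", n_generalist)),
    s = c(rep(s, n_urban + n_natural), rep(0, n_generalist)),
    fidelity = fidelity, lambda = lambda, n_steps = n_steps,
    stringsAsFactors = FALSE
  )
}

#' Simulate agent movements over a synthetic landscape
#'
#' Per agent and step: stay at the current site with probability
#' `fidelity`; otherwise move to site j != current with probability
#' proportional to `exp(-d_ij / lambda) * m_j`, where the habitat
#' multiplier is `m_j = 1` for type-blind agents and
#' `(1 - s) + s * [type_j == preferred]` otherwise. The starting site is
#' sampled proportionally to `m`. Emitted fixes are the site coordinates
#' plus isotropic Gaussian jitter (default SD 100 m, small enough that a
#' site's fixes stay within one 650-m cluster), time-stamped every
#' `fix_interval` seconds from `start_date`.
#'
#' @param landscape A [make_landscape()] object.
#' @param agents A [make_agents()] data.frame.
#' @param start_date First timestamp (UTC).
#' @param fix_interval Seconds between fixes (default 2 h).
#' @param jitter_sd GPS jitter SD in meters.
#' @param seed Integer seed.
#' @return List of class `synthetic_tracks`: `tracks` (Movebank-dialect
#'   data.frame), `seasons` (one window per agent), `truth` (site
#'   sequences and specs).
#' @export
simulate_agents <- function(landscape, agents, start_date = "2015-11-01",
                            fix_interval = 7200, jitter_sd = 100, seed = 1) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  set.seed(seed)
  sites <- landscape$sites
  ns <- nrow(sites)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  rows <- vector("list", nrow(agents))
  seasons <- vector("list", nrow(agents))
  truth_seq <- vector("list", nrow(agents))
  for (a in seq_len(nrow(agents))) {
    ag <- agents[a, ]
    m <- if (ag$preferred_type == "none") rep(1, ns) else
      (1 - ag$s) + ag$s * (sites$type == ag$preferred_type)
    start <- sample.int(ns, 1, prob = m)
    seqa <- integer(ag$n_steps + 1L)
    seqa[1] <- start
    cur <- start
    mv <- stats::runif(ag$n_steps) >= ag$fidelity
    for (t in seq_len(ag$n_steps)) {
      if (mv[t]) {
        d <- sqrt((sites$x - sites$x[cur])^2 + (sites$y - sites$y[cur])^2)
        w <- exp(-d / ag$lambda) * m
        w[cur] <- 0
        if (sum(w) <= 0) w <- as.numeric(seq_len(ns) != cur)
        cur <- sample.int(ns, 1, prob = w)
      }
      seqa[t + 1L] <- cur
    }
    nf <- ag$n_steps + 1L
    jx <- sites$x[seqa] + stats::rnorm(nf, 0, jitter_sd)
    jy <- sites$y[seqa] + stats::rnorm(nf, 0, jitter_sd)
    ll <- eqc_inverse(landscape$proj, jx, jy)
    ts <- t0 + (seq_len(nf) - 1L) * fix_interval
    rows[[a]] <- data.frame(
      `individual-local-identifier` = ag$agent_id,
      timestamp = format(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      `location-long` = ll$lon, `location-lat` = ll$lat,
      check.names = FALSE)
    seasons[[a]] <- data.frame(
      individual_id = ag$agent_id, season_label = "1",
      start = format(t0, "%Y-%m-%d %H:%M:%S"),
      end = format(ts[nf], "%Y-%m-%d %H:%M:%S"))
    truth_seq[[a]] <- seqa
  }
  structure(list(
    tracks = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    seasons = do.call(rbind, c(seasons, list(make.row.names = FALSE))),
    truth = list(agents = agents, site_type = sites$type,
                 site_sequences = stats::setNames(truth_seq, agents$agent_id),
                 seed = seed)),
    class = "synthetic_tracks")
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the tracking CSV, season-window CSV, per-site land-cover CSV
#' (the pipeline's clustering must rediscover sites as nodes), and a
#' ground-truth JSON holding site types, agent specs and seeds. Ground
#' truth is kept in a separate file so analysis code cannot accidentally
#' read labels.
#'
#' @param landscape A `synthetic_landscape`.
#' @param sim A `synthetic_tracks` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture_bundle <- function(landscape, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tracks = file.path(dir, "tracks.csv"),
    seasons = file.path(dir, "seasons.csv"),
    landcover = file.path(dir, "site_landcover.csv"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$tracks, paths["tracks"], row.names = FALSE)
  utils::write.csv(sim$seasons, paths["seasons"], row.names = FALSE)
  lc <- data.frame(site_id = landscape$sites$site_id,
                   lon = landscape$sites$lon, lat = landscape$sites$lat,
                   landscape$landcover, check.names = FALSE)
  utils::write.csv(lc, paths["landcover"], row.names = FALSE)
  truth <- list(site_type = landscape$sites$type,
                agents = sim$truth$agents,
                site_sequences = sim$truth$site_sequences,
                landscape_seed = landscape$seed,
                track_seed = sim$truth$seed)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
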