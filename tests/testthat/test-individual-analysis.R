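# Assemble a habitat_network directly from manually labeled tracks.
net_from_tracks <- function(tracks, nmds1 = NULL) {
  mv <- compile_movements(tracks)
  ids <- sort(unique(c(mv$steps$from, mv$steps$to, mv$visits$node)))
  info <- data.frame(node_id = ids, lon = -80.2, lat = 26.5,
                     centroid_x = ids * 1000, centroid_y = 0,
                     nmds1 = if (is.null(nmds1)) as.numeric(ids) else nmds1)
  build_habitat_network(mv, info)
}

test_that("weighted habitat profiles follow the frequency-weight formulas", {
  pr <- habitat_profile(c(0, 1), c(1, 1))
  expect_equal(pr$wmean, 0.5)
  expect_equal(pr$wsd, sqrt(0.5), tolerance = 1e-12)  # = 0.7071
  expect_equal(habitat_profile(3.2, 5)$wsd, 0)        # single node
  pr <- habitat_profile(c(2, 2, 2), c(1, 4, 2))       # equal scores
  expect_equal(pr$wmean, 2)
  expect_equal(pr$wsd, 0)
  # weighting by visit counts: direct hand computation
  pr <- habitat_profile(c(0, 1), c(3, 1))
  expect_equal(pr$wmean, 0.25)
  expect_equal(pr$wsd, sqrt((3 * 0.0625 + 1 * 0.5625) / 3))
})

test_that("knockout of a one-unique-edge track changes density by -10%", {
  t1 <- toy_track("t1", c(1, 2, 1, 3, 1, 4, 1, 5, 1, 2, 3))  # 9 unique edges
  t2 <- toy_track("t2", c(3, 2))                             # 1 new edge
  net <- net_from_tracks(list(t1, t2))
  expect_equal(edge_density(net$graph), 10 / 20)
  sc <- data.frame(node_id = 1:5, nmds1 = c(-1, -0.5, 0, 0.5, 1))
  ko <- knockout_analysis(net, sc)
  expect_equal(ko$pct_density[ko$id == "t2"], -10)
  expect_equal(ko$delta_density[ko$id == "t2"], -0.05)
})

test_that("knockout deltas are zero for fully redundant tracks", {
  t1 <- toy_track("t1", c(1, 2, 3, 1))
  t2 <- toy_track("t2", c(1, 2, 3, 1))
  net <- net_from_tracks(list(t1, t2))
  sc <- data.frame(node_id = 1:3, nmds1 = c(-1, 0, 1))
  ko <- knockout_analysis(net, sc)
  expect_equal(ko$delta_density, c(0, 0))
  expect_equal(ko$delta_assortativity, c(0, 0))
})

test_that("density never increases upon removal, on synthetic populations", {
  ag <- make_agents(n_urban = 3, n_natural = 3, n_generalist = 2, n_steps = 80)
  run <- synth_pipeline(4, ag, sim_seed = 17, n_sites = 12)
  ko <- knockout_analysis(run$pipe$network, run$pipe$scores)
  expect_true(all(ko$delta_density <= 1e-12))
  expect_equal(nrow(ko), 8)
})

test_that("specialization models recover a planted quadratic", {
  set.seed(23)
  n <- 60
  wsd <- runif(n, 0, 1)
  wmean <- 0.5 + 2 * wsd - 2.5 * wsd^2 + rnorm(n, 0, 0.05)
  profiles <- data.frame(id = as.character(1:n), n_nodes_used = 5,
                         wmean_nmds1 = wmean, wsd_nmds1 = wsd)
  kn <- data.frame(id = as.character(1:n),
                   delta_density = rnorm(n, 0, 1e-3),
                   pct_density = 0, delta_assortativity = rnorm(n, 0, 1e-3),
                   flagged = FALSE)
  fits <- specialization_models(profiles, kn)
  cf <- fits$mean_vs_sd
  expect_lt(abs(cf$estimate[cf$term == "wsd_nmds1"] - 2),
            2 * cf$se[cf$term == "wsd_nmds1"])
  expect_lt(abs(cf$estimate[cf$term == "I(wsd_nmds1^2)"] + 2.5),
            2 * cf$se[cf$term == "I(wsd_nmds1^2)"])
  # knockout deltas unrelated to profiles: slopes near zero
  cfB <- fits$density_role
  expect_lt(max(abs(cfB$estimate[cfB$term != "(Intercept)"])), 0.01)
  # perfectly collinear predictors are a reported error
  profiles2 <- profiles
  profiles2$wmean_nmds1 <- profiles2$wsd_nmds1
  expect_error(suppressWarnings(specialization_models(profiles2, kn)),
               "collinear|rank")
})

test_that("individual ANOVA matches the sum-of-squares oracle", {
  visits <- rbind(
    data.frame(track_id = "a", node = c(1, 1, 2, 1)),
    data.frame(track_id = "b", node = c(3, 4, 3, 4)))
  sc <- data.frame(node_id = 1:4, nmds1 = c(-1, -0.6, 0.7, 1.1))
  out <- individual_anova(visits, sc)
  vals <- sc$nmds1[visits$node]
  expect_equal(out$F, anova_F_oracle(vals, visits$track_id))
  expect_error(individual_anova(visits[visits$track_id == "a", ], sc), "2")
})

test_that("bird-level pooling matches the concatenated-visit identity", {
  t1 <- toy_track("b1_1", c(1, 2, 1))
  t2 <- toy_track("b1_2", c(2, 3, 2))
  t3 <- toy_track("b2_1", c(1, 3, 1))
  net <- net_from_tracks(list(t1, t2, t3))
  sc <- data.frame(node_id = 1:3, nmds1 = c(-1, 0.2, 1))
  bm <- data.frame(track_id = c("b1_1", "b1_2", "b2_1"),
                   bird_id = c("b1", "b1", "b2"))
  out <- aggregate_to_bird(net, sc, bm)
  expect_setequal(out$profiles$id, c("b1", "b2"))
  # a bird with one track equals the track-level profile
  trk <- habitat_profiles(net$movements$visits, sc)
  expect_equal(out$profiles[out$profiles$id == "b2", -1],
               trk[trk$id == "b2_1", -1], ignore_attr = TRUE)
  # pooled weighted mean equals the weighted mean of concatenated visits
  v <- net$movements$visits
  v <- v[v$track_id %in% c("b1_1", "b1_2"), ]
  cnt <- table(v$node)
  hand <- habitat_profile(sc$nmds1[as.integer(names(cnt))], as.numeric(cnt))
  expect_equal(out$profiles$wmean_nmds1[out$profiles$id == "b1"], hand$wmean)
  expect_equal(out$profiles$wsd_nmds1[out$profiles$id == "b1"], hand$wsd)
  # a bird with two identical tracks keeps its mean, doubling the weights
  t2b <- toy_track("b1_2", c(1, 2, 1))
  net2 <- net_from_tracks(list(t1, t2b, t3))
  out2 <- aggregate_to_bird(net2, sc, bm)
  expect_equal(out2$profiles$wmean_nmds1[out2$profiles$id == "b1"],
               trk$wmean_nmds1[trk$id == "b1_1"])
})

test_that("removing then re-adding a track reproduces the full network", {
  set.seed(33)
  tracks <- lapply(1:3, function(i)
    toy_track(paste0("t", i), sample.int(4, 30, replace = TRUE)))
  full <- net_from_tracks(tracks)
  without <- net_from_tracks(tracks[-2])
  readded <- net_from_tracks(c(tracks[-2], tracks[2]))
  el <- function(net) {
    e <- igraph::as_data_frame(net$graph)
    e[order(e$from, e$to), ]
  }
  expect_equal(el(readded), el(full), ignore_attr = TRUE)
  expect_lte(nrow(el(without)), nrow(el(full)))
})
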