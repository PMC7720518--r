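test_that("step extraction collapses runs and respects bursts", {
  out <- extract_steps(toy_track("t1", c(1, 1, 2, 2, 1)))
  expect_equal(out$steps$from, c(1, 2))
  expect_equal(out$steps$to, c(2, 1))
  expect_equal(out$visits$node, c(1, 2, 1))   # node 1: 2 visits, node 2: 1
  expect_equal(out$n_valid_pairs, 4L)
  expect_equal(out$n_moving_pairs, 2L)

  out <- extract_steps(toy_track("t1", c(1, 1, 1)))
  expect_equal(nrow(out$steps), 0)
  expect_equal(out$visits$node, 1)

  # a burst boundary suppresses the step but keeps both visits
  out <- extract_steps(toy_track("t1", c(1, 2), burst = c(1L, 2L)))
  expect_equal(nrow(out$steps), 0)
  expect_equal(out$visits$node, c(1, 2))

  # an unassigned fix breaks the chain
  out <- extract_steps(toy_track("t1", c(1, NA, 2)))
  expect_equal(nrow(out$steps), 0)
  expect_equal(out$visits$node, c(1, 2))
})

test_that("network assembly pools weights and bird-years over tracks", {
  mv <- compile_movements(list(toy_track("t1", c(1, 2)), toy_track("t2", c(1, 2))))
  g <- build_network(mv$steps, mv$visits)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 2L)
  expect_equal(igraph::E(g)$n_birdyears, 2L)
  expect_equal(sort(igraph::V(g)$size), c(2L, 2L))

  # opposite directions are distinct edges
  mv <- compile_movements(list(toy_track("t1", c(1, 2, 1))))
  g <- build_network(mv$steps, mv$visits)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::is_directed(g))

  # empty step list still yields the visited vertices
  mv <- compile_movements(list(toy_track("t1", c(3, 3))))
  g <- build_network(mv$steps, mv$visits)
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::V(g)$name, "3")
})

test_that("total edge weight equals the number of between-node steps", {
  set.seed(14)
  tracks <- lapply(1:4, function(i)
    toy_track(paste0("t", i), sample.int(5, 60, replace = TRUE)))
  mv <- compile_movements(tracks)
  g <- build_network(mv$steps, mv$visits)
  expect_equal(sum(igraph::E(g)$weight), nrow(mv$steps))
})

test_that("network construction is invariant to track order", {
  set.seed(15)
  tracks <- lapply(1:5, function(i)
    toy_track(paste0("t", i), sample.int(6, 40, replace = TRUE)))
  mv1 <- compile_movements(tracks)
  mv2 <- compile_movements(rev(tracks))
  g1 <- build_network(mv1$steps, mv1$visits)
  g2 <- build_network(mv2$steps, mv2$visits)
  el <- function(g) {
    e <- igraph::as_data_frame(g)
    e[order(e$from, e$to), ]
  }
  expect_equal(el(g1), el(g2), ignore_attr = TRUE)
  v1 <- igraph::as_data_frame(g1, "vertices")
  v2 <- igraph::as_data_frame(g2, "vertices")
  expect_equal(v1[order(v1$name), ], v2[order(v2$name), ], ignore_attr = TRUE)
})

test_that("clipping drops out-of-extent nodes and pruning drops isolates", {
  mv <- compile_movements(list(toy_track("t1", c(1, 2, 1, 3))))
  info <- data.frame(node_id = 1:3,
                     lon = c(-80.2, -80.2, -85),   # node 3 outside
                     lat = c(26.5, 26.6, 26.5))
  g <- build_network(mv$steps, mv$visits, info)
  gc <- clip_and_prune(g, c(-80.52, -80, 26.25, 27.5))
  expect_setequal(igraph::V(gc)$name, c("1", "2"))

  # an in-extent node with no edges is pruned
  mv <- compile_movements(list(toy_track("t1", c(1, 2)),
                               toy_track("t2", c(4, 4))))
  info <- data.frame(node_id = c(1, 2, 4), lon = -80.2, lat = 26.5)
  g <- build_network(mv$steps, mv$visits, info)
  gc <- clip_and_prune(g, c(-80.52, -80, 26.25, 27.5))
  expect_setequal(igraph::V(gc)$name, c("1", "2"))

  # a fully connected in-extent network is unchanged
  expect_equal(igraph::vcount(clip_and_prune(g)), 2)
})

test_that("tracks stranded by clipping are reported and filtered", {
  mv <- compile_movements(list(toy_track("t1", c(1, 2, 1)),
                               toy_track("t2", c(3, 4, 3))))
  info <- data.frame(node_id = 1:4,
                     lon = c(-80.2, -80.25, -85, -85),
                     lat = c(26.5, 26.5, 26.5, 26.5),
                     centroid_x = 1:4, centroid_y = 1:4)
  net <- build_habitat_network(mv, info, c(-80.52, -80, 26.25, 27.5))
  expect_equal(net$dropped_tracks, "t2")
  expect_false("t2" %in% net$movements$visits$track_id)
  expect_equal(nrow(net$movements$track_summary), 1)
})
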