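g_from_edges <- function(edges, n = max(edges), directed = TRUE) {
  g <- igraph::make_empty_graph(n, directed = directed)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::E(g)$weight <- 1L
  g
}

test_that("edge density is m / (n (n - 1))", {
  k3 <- g_from_edges(rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  expect_equal(edge_density(k3), 1)
  g <- g_from_edges(rbind(c(1, 2), c(2, 3)), n = 3)
  expect_equal(edge_density(g), 1 / 3)
})

test_that("assortativity is the endpoint-value correlation with variance guard", {
  # two disjoint dyads with values (1,1) and (0,0): perfectly assortative
  g <- g_from_edges(rbind(c(1, 2), c(3, 4)), n = 4)
  expect_equal(assortativity_numeric(g, c(1, 1, 0, 0)), 1)
  # an edge and its reverse between values 0 and 1: perfectly disassortative
  g <- g_from_edges(rbind(c(1, 2), c(2, 1)), n = 2)
  expect_equal(assortativity_numeric(g, c(0, 1)), -1)
  # identical values everywhere: undefined
  g <- g_from_edges(rbind(c(1, 2), c(2, 3)), n = 3)
  expect_true(is.na(assortativity_numeric(g, c(2, 2, 2))))
  # agrees with igraph on a random directed graph
  set.seed(4)
  gr <- igraph::sample_gnp(30, 0.15, directed = TRUE)
  vals <- rnorm(30)
  expect_equal(assortativity_numeric(gr, vals),
               igraph::assortativity(gr, vals, directed = TRUE),
               tolerance = 1e-10)
  # weight expansion replicates edges by their weight
  g <- g_from_edges(rbind(c(1, 2), c(3, 4), c(4, 3)), n = 4)
  igraph::E(g)$weight <- c(10L, 1L, 1L)
  vals <- c(1, 0.9, -1, -0.8)
  el <- rbind(matrix(rep(c(1, 2), 10), ncol = 2, byrow = TRUE),
              c(3, 4), c(4, 3))
  expect_equal(assortativity_numeric(g, vals, weighted = TRUE),
               cor(vals[el[, 1]], vals[el[, 2]]))
})

test_that("module detection recovers planted structure with correct Q", {
  tri2 <- g_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4)))
  md <- detect_modules(tri2)
  expect_equal(md$n_modules, 2)
  expect_equal(md$Q, 0.5)       # 2 * (1/2 - 1/4), hand computation
  # complete graph: no community structure
  k4 <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  md <- detect_modules(g_from_edges(k4))
  expect_equal(md$n_modules, 1)
  expect_lt(abs(md$Q), 1e-12)
  # ring of four 5-cliques with single bridges
  cliq <- do.call(rbind, lapply(0:3, function(b) {
    v <- b * 5 + 1:5
    t(combn(v, 2))
  }))
  bridges <- rbind(c(5, 6), c(10, 11), c(15, 16), c(20, 1))
  ring <- g_from_edges(rbind(cliq, bridges))
  md <- detect_modules(ring)
  expect_equal(md$n_modules, 4)
  expect_equal(canonical_partition(unname(md$membership)),
               rep(1:4, each = 5))
  # single-module partition has Q = 0 exactly
  gu <- igraph::as_undirected(tri2)
  expect_equal(igraph::modularity(gu, rep(1, 6)), 0)
  # alternative methods agree on the clean two-triangle case
  expect_equal(detect_modules(tri2, "edge_betweenness")$n_modules, 2)
  set.seed(1)
  md_sa <- detect_modules(tri2, "annealing")  # largest component only
  expect_equal(md_sa$n_modules, 1)
  expect_equal(length(md_sa$membership), 3)
})

test_that("node metrics match hand-computed values", {
  path <- g_from_edges(rbind(c(1, 2), c(2, 3)), n = 3)
  nm <- node_metrics(path)
  expect_equal(nm$betweenness[nm$node_id == "2"], 0.5)  # 1 / ((n-1)(n-2))
  star <- g_from_edges(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), n = 5)
  nm <- node_metrics(star)
  expect_equal(nm$out_degree[nm$node_id == "1"], 4)
  expect_equal(sum(nm$out_degree), igraph::ecount(star))  # handshake
})

test_that("observed-vs-null comparison reports z-scores and contrasts", {
  obs <- c(m1 = 0.5, m2 = 2)
  null_mat <- cbind(m1 = c(0.4, 0.5, 0.6), m2 = c(1, 1, 1))
  out <- compare_observed_null(obs, null_mat)
  expect_equal(out$z[out$metric == "m1"], 0)
  expect_true(out$z_defined[out$metric == "m1"])
  # zero null SD with a different observed value: flagged undefined
  expect_false(out$z_defined[out$metric == "m2"])
  expect_true(is.na(out$z[out$metric == "m2"]))
})

test_that("per-class assortativity model includes type, class and interaction", {
  set.seed(2)
  cls <- paste0("assort_class_", c("urban", "scrub", "lakes"))
  obs <- setNames(c(0.8, 0.6, 0.4), cls)
  null_mat <- sapply(c(0.3, 0.25, 0.2), function(m) rnorm(20, m, 0.05))
  colnames(null_mat) <- cls
  fit <- class_assortativity_model(obs, null_mat)
  expect_s3_class(fit, "lm")
  expect_true(any(grepl("typesimulated:class", names(coef(fit)))))
})

test_that("node-attribute GLMs scale predictors and recover known effects", {
  set.seed(6)
  n <- 800
  X <- as.data.frame(scale(cbind(nmds1 = rnorm(n), lat = rnorm(n), lon = rnorm(n))))
  eta <- 0.2 + 0.4 * X$nmds1 - 0.3 * X$lat
  y <- rpois(n, exp(eta))
  nm <- data.frame(out_degree = y, size = y, betweenness = exp(rnorm(n, -3)),
                   nmds1 = X$nmds1, lat = X$lat, lon = X$lon)
  fits <- node_attribute_glms(nm)
  expect_equal(unname(colMeans(fits$design)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(fits$design, 2, sd)), rep(1, 5), tolerance = 1e-10)
  cf <- fits$out_degree
  est <- function(term) cf$estimate[cf$term == term]
  se <- function(term) cf$se[cf$term == term]
  expect_lt(abs(est("nmds1") - 0.4), 2 * se("nmds1"))
  expect_lt(abs(est("lat") + 0.3), 2 * se("lat"))
  # constant response: slopes near zero
  nm2 <- nm
  nm2$out_degree <- 5L
  nm2$size <- 5L
  cf2 <- node_attribute_glms(nm2)$out_degree
  expect_lt(max(abs(cf2$estimate[cf2$term != "(Intercept)"])), 1e-6)
})

test_that("module ANOVA matches the sum-of-squares oracle", {
  set.seed(12)
  memb <- rep(1:3, each = 8)
  vals <- rnorm(24, mean = c(0, 1, 2)[memb])
  out <- module_anova(memb, vals)
  expect_equal(out$F, anova_F_oracle(vals, memb))
  expect_false(out$degenerate)
  # zero within-group variance is flagged
  out <- module_anova(c(1, 1, 2, 2), c(0, 0, 1, 1))
  expect_true(out$degenerate)
})
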