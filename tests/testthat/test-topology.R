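tol <- 1e-9

test_that("degrees count distinct neighbors", {
  expect_true(all(degree_sequence(triangle_net()) == 2L))
  deg <- degree_sequence(star_net(3L))
  expect_equal(unname(deg[["hub"]]), 3L)
  expect_true(all(deg[paste0("leaf", 1:3)] == 1L))
})

test_that("local clustering follows 2n/(k(k-1)) with k<2 undefined", {
  expect_equal(node_clustering(triangle_net(), "A"), 1.0)
  expect_equal(node_clustering(star_net(3L), "hub"), 0.0)
  # 4-cycle A-B-C-D-A plus chord A-C: A sits in the triangles ABC and
  # ACD, so 2 of the 3 possible links among its neighbors exist
  net <- net_from_edges(c("A","B", "B","C", "C","D", "D","A", "A","C"))
  expect_equal(node_clustering(net, "B"), 1.0, tolerance = tol)
  expect_equal(node_clustering(net, "A"), 2 / 3, tolerance = tol)
  expect_true(is.na(node_clustering(path_net(2L), "A")))  # degree 1
  expect_error(node_clustering(net, "Z"), "unknown node")
})

test_that("path statistics: distances, characteristic length, diameter", {
  p3 <- path_net(3L)
  d <- shortest_path_lengths(p3)
  expect_equal(d["A", "C"], 2)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  two_edges <- net_from_edges(c("A","B", "C","D"))
  expect_equal(shortest_path_lengths(two_edges)["A", "C"], Inf)

  expect_equal(characteristic_path_length(path_net(2L)), 1.0)
  expect_equal(characteristic_path_length(p3), 4 / 3, tolerance = tol)
  expect_equal(network_diameter(path_net(13L)), 12L)
  expect_equal(network_diameter(triangle_net()), 1L)
  expect_equal(network_diameter(net_from_edges(character(0), nodes = "A")), 0L)
  expect_true(is.na(characteristic_path_length(
    net_from_edges(character(0), nodes = c("A", "B")))))
})

test_that("average neighbors is the mean simple-view degree", {
  expect_equal(average_neighbors(triangle_net()), 2.0)
  expect_equal(average_neighbors(star_net(3L)), 1.5)
  expect_equal(average_neighbors(capacitation_core_fixture()),
               2 * 19 / 17, tolerance = tol)
})

test_that("closeness centrality is 1/mean distance to reachable nodes", {
  cc <- closeness_centrality(path_net(2L))
  expect_true(all(cc$closeness == 1))
  cc3 <- closeness_centrality(path_net(3L))
  val <- stats::setNames(cc3$closeness, cc3$node)
  expect_equal(unname(val[["B"]]), 1.0)
  expect_equal(unname(val[["A"]]), 2 / 3, tolerance = tol)
  iso <- closeness_centrality(net_from_edges(character(0), nodes = "A"))
  expect_equal(iso$closeness, 0)
  expect_equal(iso$reachable_count, 0L)
})

test_that("fit_power_law recovers exact power laws and degenerate input", {
  x <- 1:12
  fit <- fit_power_law(x, 2 * x^-1.5)
  expect_true(fit$fitted)
  expect_equal(fit$exponent_b, -1.5, tolerance = tol)
  expect_equal(fit$prefactor_a, 2, tolerance = tol)
  expect_equal(abs(fit$pearson_r), 1, tolerance = tol)
  expect_equal(fit$r_squared, 1, tolerance = tol)

  two <- fit_power_law(c(1, 2), c(1, 2))
  expect_equal(two$exponent_b, 1, tolerance = tol)
  expect_equal(two$prefactor_a, 1, tolerance = tol)

  expect_false(fit_power_law(1, 1)$fitted)
  expect_false(fit_power_law(c(2, 2), c(1, 3))$fitted)  # vertical
  expect_false(fit_power_law(c(-1, 0, 1), c(1, 1, 1))$fitted)
})

test_that("fit_power_law matches an independent OLS-on-logs oracle on noisy data", {
  for (s in 1:5) {
    pts <- withr::with_seed(s, {
      x <- 1:30
      y <- 3 * x^-2 * exp(stats::rnorm(30, sd = 0.4))
      list(x = x, y = y)
    })
    fit <- fit_power_law(pts$x, pts$y)
    ref <- oracle_loglog_ols(pts$x, pts$y)
    expect_equal(fit$exponent_b, ref$b, tolerance = tol)
    expect_equal(fit$prefactor_a, ref$a, tolerance = tol)
    expect_equal(fit$pearson_r, ref$r, tolerance = tol)
    expect_equal(fit$r_squared, ref$r2, tolerance = tol)
    expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
  }
})

test_that("degree distribution fit handles stars, lattices and PA output", {
  fit <- degree_distribution_fit(star_net(5L))  # points (1,5), (5,1)
  expect_equal(fit$exponent_b, -1, tolerance = tol)
  expect_equal(abs(fit$pearson_r), 1, tolerance = tol)

  ring <- net_from_edges(as.vector(rbind(LETTERS[1:6],
                                         LETTERS[c(2:6, 1)])))
  expect_false(degree_distribution_fit(ring)$fitted)  # single degree value

  pa <- generate_pa_network(500L, 1L, seed = 7L)
  paf <- degree_distribution_fit(pa)
  expect_true(paf$fitted)
  expect_lt(paf$exponent_b, -1)
  expect_gt(paf$r_squared, 0.7)
})

test_that("clustering spectrum fit: degenerate and regular cases", {
  expect_false(clustering_distribution_fit(star_net(5L))$fitted)  # all zero
  expect_false(clustering_distribution_fit(triangle_net())$fitted) # 1 point

  # two triangles sharing node X: spectrum has k=2 (clustering 1)
  # and k=4 (clustering 2*2/(4*3) = 1/3)
  net <- net_from_edges(c("X","A", "X","B", "A","B",
                          "X","C", "X","D", "C","D"))
  fit <- clustering_distribution_fit(net)
  expect_true(fit$fitted)
  ref <- oracle_loglog_ols(c(2, 4), c(1, 1 / 3))
  expect_equal(fit$exponent_b, ref$b, tolerance = tol)
  expect_equal(fit$prefactor_a, ref$a, tolerance = tol)
})

test_that("topology_report matches individually-called statistics", {
  tri <- topology_report(triangle_net())
  expect_equal(tri$n_nodes, 3L)
  expect_equal(tri$n_edges_simple, 3L)
  expect_equal(tri$avg_clustering, 1.0)
  expect_equal(tri$diameter, 1L)
  expect_equal(tri$char_path_length, 1.0)
  expect_equal(tri$avg_neighbors, 2.0)

  net <- random_test_network(20L, seed = 3L, loops = TRUE, parallel = TRUE)
  rep <- topology_report(net)
  expect_equal(rep$n_nodes, n_nodes(net))
  expect_equal(rep$n_edges_simple, n_edges_simple(net))
  expect_equal(rep$n_interactions_raw, n_interactions_raw(net))
  expect_equal(rep$diameter, network_diameter(net))
  expect_equal(rep$avg_neighbors, average_neighbors(net))
  expect_equal(rep$char_path_length, characteristic_path_length(net))
  expect_equal(rep$avg_clustering,
               mean(node_clustering(net), na.rm = TRUE))
  expect_equal(rep$degree_fit, degree_distribution_fit(net))

  fx <- topology_report(capacitation_core_fixture())
  expect_equal(fx$n_nodes, 17L)
  expect_equal(fx$n_edges_simple, 19L)

  zero <- topology_report(star_net(3L), count_degree_lt2_as_zero = TRUE)
  expect_equal(zero$avg_clustering, 0)
})

test_that("clustering and closeness stay within [0, 1]; cpl <= diameter when connected", {
  for (s in 1:8) {
    net <- random_test_network(sample(6:24, 1L), seed = 100 + s)
    cc <- node_clustering(net)
    expect_true(all(is.na(cc) | (cc >= 0 & cc <= 1)))
    cl <- closeness_centrality(net)$closeness
    expect_true(all(cl >= 0 & cl <= 1))
    d <- shortest_path_lengths(net)
    if (all(is.finite(d))) {
      expect_lte(characteristic_path_length(net), network_diameter(net))
    }
  }
})
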