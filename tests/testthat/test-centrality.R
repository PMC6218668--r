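test_that("shared-neighbor score counts common neighbors plus direct links", {
  tri <- make_net(c("a-b", "b-c", "a-c"))
  expect_equal(shared_neighbor_score(tri, "a", "b"), 2)  # share c + edge
  sq <- make_net(c("a-b", "b-c", "c-d", "a-d"))
  expect_equal(shared_neighbor_score(sq, "a", "c"), 2)   # share b and d
  p3 <- make_net(c("a-b", "b-c"))
  expect_equal(shared_neighbor_score(p3, "a", "b"), 1)   # direct link only
  expect_error(shared_neighbor_score(p3, "a", "z"), "not present")
  expect_error(shared_neighbor_score(p3, "a", "a"), "distinct")
})

test_that("topological coefficient matches hand values on reference graphs", {
  tri <- generate_reference_graph("cycle", 3)
  expect_equal(unname(topological_coefficient(tri)), rep(1, 3))
  sq <- generate_reference_graph("cycle", 4)
  expect_equal(topological_coefficient(sq, "a"), 1)
  # any degree-1 node scores zero
  star <- generate_reference_graph("star", 4)
  expect_equal(topological_coefficient(star, "b"), 0)
  p3 <- generate_reference_graph("path", 3)
  expect_equal(unname(topological_coefficient(p3)), c(0, 0, 0))
})

test_that("radiality matches hand values and is per-component", {
  edge <- make_net("a-b")
  expect_equal(unname(radiality(edge)), c(1, 1))
  p3 <- generate_reference_graph("path", 3)
  expect_equal(radiality(p3, "b", normalized = FALSE), 2)
  expect_equal(radiality(p3, "b"), 1)
  expect_equal(radiality(p3, "a", normalized = FALSE), 1.5)
  expect_equal(radiality(p3, "a"), 0.75)
  # disconnected: each component scored on its own size and diameter
  two <- generate_reference_graph("two_component", 5)
  expect_equal(radiality(two, "d"), 1)   # the separate edge
  expect_equal(radiality(two, "a"), 1)   # triangle node
  # singleton components score zero
  iso <- make_net("a-b", isolates = "z")
  expect_equal(radiality(iso, "z"), 0)
})

test_that("betweenness matches hand values with per-component normalization", {
  p3 <- generate_reference_graph("path", 3)
  expect_equal(betweenness_centrality(p3, "b"), 1)
  tri <- generate_reference_graph("cycle", 3)
  expect_equal(unname(betweenness_centrality(tri)), rep(0, 3))
  c4 <- generate_reference_graph("cycle", 4)
  expect_equal(unname(betweenness_centrality(c4)), rep(1 / 6, 4))
  expect_equal(unname(betweenness_centrality(c4, normalized = FALSE)),
               rep(0.5, 4))
})

test_that("path-graph betweenness follows the (i-1)(n-i) closed form", {
  for (n in 2:10) {
    p <- generate_reference_graph("path", n)
    ids <- sort(igraph::V(p)$name)   # letters in path order
    raw <- betweenness_centrality(p, normalized = FALSE)[ids]
    i <- seq_len(n)
    expect_equal(unname(raw), (i - 1) * (n - i))
  }
})

test_that("complete graphs have zero betweenness and unit radiality", {
  for (n in c(3, 5, 8)) {
    k <- generate_reference_graph("complete", n)
    expect_equal(unname(betweenness_centrality(k)), rep(0, n))
    expect_equal(unname(radiality(k)), rep(1, n))
    expect_equal(unname(topological_coefficient(k)), rep(1, n))
  }
})

test_that("centroid value matches the pairwise-advantage definition", {
  edge <- make_net("a-b")
  expect_equal(unname(centroid_value(edge)), c(0, 0))
  star <- generate_reference_graph("star", 4)
  cv <- centroid_value(star)
  expect_gt(cv[["a"]], 0)            # center dominates
  expect_lt(cv[["b"]], 0)            # leaves dominated
  expect_warning(centroid_value(make_net("a-b", isolates = "z"), "z"),
                 "singleton")
  # oracle agreement on a hand-drawn irregular graph
  g <- make_net(c("a-b", "b-c", "c-d", "b-d", "d-e"))
  expect_equal(centroid_value(g), oracle_centroid(g)[sort(names(oracle_centroid(g)))])
})

test_that("centralities agree with brute-force oracles on random graphs", {
  set.seed(421)
  for (rep in 1:40) {
    net <- random_graph(sample(4:8, 1), p = stats::runif(1, 0.25, 0.7))
    ids <- sort(igraph::V(net)$name)
    expect_equal(betweenness_centrality(net, normalized = FALSE)[ids],
                 oracle_betweenness_raw(net)[ids], tolerance = 1e-10)
    expect_equal(topological_coefficient(net)[ids], oracle_tn(net)[ids],
                 tolerance = 1e-12)
    expect_equal(radiality(net, normalized = FALSE)[ids],
                 oracle_radiality(net, normalized = FALSE)[ids],
                 tolerance = 1e-12)
    cv <- suppressWarnings(centroid_value(net))  # may contain singletons
    expect_equal(cv[ids], oracle_centroid(net)[ids])
  }
})

test_that("adding an edge never increases any node's eccentricity", {
  set.seed(77)
  for (rep in 1:20) {
    net <- random_graph(7, p = 0.35, connected = TRUE)
    ecc <- igraph::eccentricity(net)
    ee <- network_edges(net)
    ids <- igraph::V(net)$name
    pairs <- t(utils::combn(ids, 2))
    present <- paste(pairs[, 1], pairs[, 2]) %in% paste(ee$from, ee$to)
    open <- pairs[!present, , drop = FALSE]
    if (!nrow(open)) next
    pick <- open[sample(nrow(open), 1), ]
    net2 <- bio_network(network_nodes(net)[, c("id", "kind", "label")],
                        dplyr::bind_rows(ee, tibble::tibble(from = pick[1],
                                                            to = pick[2])))
    expect_true(all(igraph::eccentricity(net2)[ids] <= ecc[ids]))
  }
})

test_that("centrality table assembles all measures with deterministic order", {
  p3 <- generate_reference_graph("path", 3)
  ct <- centrality_table(p3)
  expect_equal(ct$node_id, c("a", "b", "c"))
  expect_equal(ct$tn, c(0, 0, 0))
  expect_equal(ct$radiality_norm, c(0.75, 1, 0.75))
  expect_equal(ct$betweenness_norm, c(0, 1, 0))
  expect_equal(ct$degree, c(1L, 2L, 1L))
  expect_equal(ct$component_size, rep(3L, 3))
  expect_equal(nrow(centrality_table(make_net(character()))), 0)
})

test_that("tn stays in [0, 1] and vanishes below degree two on generated networks", {
  set.seed(11)
  nets <- c(
    lapply(1:3, function(s) build_network(generate_db(tiny_synth(seed = s)),
                                          "disease_gene")),
    lapply(1:5, function(i) random_graph(sample(3:8, 1), p = stats::runif(1, 0.2, 0.8)))
  )
  for (net in nets) {
    ct <- centrality_table(net, centroid = FALSE)
    expect_true(all(ct$tn >= 0 & ct$tn <= 1))
    expect_true(all(ct$tn[ct$degree < 2] == 0))
    expect_true(all(ct$radiality_norm >= 0 & ct$radiality_norm <= 1))
    expect_true(all(ct$betweenness_norm >= 0 & ct$betweenness_norm <= 1))
  }
})

test_that("clustering and connectivity distributions match hand values", {
  tri <- generate_reference_graph("cycle", 3)
  d <- clustering_connectivity_distributions(tri)
  expect_equal(d$clustering, tibble::tibble(degree = 2L, avg_clustering = 1))
  expect_equal(d$connectivity,
               tibble::tibble(degree = 2L, avg_neighbor_degree = 2))
  star <- generate_reference_graph("star", 4)
  ds <- clustering_connectivity_distributions(star)
  expect_equal(ds$clustering$avg_clustering, c(0, 0))  # degrees 1 and 3
  expect_equal(ds$connectivity$avg_neighbor_degree[ds$connectivity$degree == 1], 3)
  empty <- make_net(character())
  de <- clustering_connectivity_distributions(empty)
  expect_equal(nrow(de$clustering), 0)
  expect_equal(nrow(de$connectivity), 0)
})
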