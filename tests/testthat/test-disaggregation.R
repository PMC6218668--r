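test_that("twins are nodes with identical open neighborhoods", {
  # G1 and G2 both link to D1 and D2 only
  net <- make_net(c("D1-G1", "D2-G1", "D1-G2", "D2-G2", "D2-G3", "D3-G3"))
  expect_equal(node_twins(net, "G1"), "G2")
  expect_equal(node_twins(net, "G2"), "G1")
  expect_length(node_twins(net, "G3"), 0)
  expect_length(node_twins(net, "G1", rule = "none"), 0)
  expect_error(node_twins(net, "zz"), "not present")
})

test_that("removal sets expand to twins and first neighbors only", {
  star <- generate_reference_graph("star", 5)
  expect_setequal(removal_set(star, "a", include_neighbors = TRUE),
                  igraph::V(star)$name)  # whole star
  net <- make_net(c("D1-G1", "D2-G1", "D1-G2", "D2-G2", "x-y"))
  # selecting G1 co-selects its twin G2, then their neighbors
  expect_setequal(removal_set(net, "G1", include_neighbors = TRUE),
                  c("G1", "G2", "D1", "D2"))
  expect_setequal(removal_set(net, "G1", include_neighbors = FALSE),
                  c("G1", "G2"))
  # a disjoint component is never touched
  expect_false(any(c("x", "y") %in% removal_set(net, "G1")))
})

test_that("disaggregating a hub with its neighborhood leaves the rest intact", {
  net <- make_net(c("h-a", "h-b", "h-c", "x-y"))
  d <- disaggregate(net, "h", include_neighbors = TRUE)
  expect_setequal(igraph::V(d$after)$name, c("x", "y"))
  expect_equal(igraph::ecount(d$after), 1)
  rep <- glance(d)
  expect_equal(rep$nodes_before, 6)
  expect_equal(rep$nodes_after, 2)
  expect_equal(rep$edges_after, 1)
  expect_equal(tidy(d)$node_id, sort(c("h", "a", "b", "c")))
})

test_that("removing a leaf drops exactly its degree in edges", {
  net <- build_network(generate_db(tiny_synth(seed = 2)), "disease_gene")
  deg <- igraph::degree(net)
  leaf <- names(deg)[deg == 1][1]
  d <- disaggregate(net, leaf, include_neighbors = FALSE, twin_rule = "none",
                    centroid = FALSE)
  rep <- glance(d)
  expect_equal(rep$edges_before - rep$edges_after, 1)
})

test_that("node bookkeeping is exact on every run, with and without isolate dropping", {
  set.seed(9)
  for (rep_i in 1:10) {
    net <- build_network(generate_db(tiny_synth(seed = rep_i)), "disease_gene")
    target <- sample(igraph::V(net)$name, 1)
    for (drop in c(FALSE, TRUE)) {
      d <- disaggregate(net, target, include_neighbors = TRUE,
                        drop_isolates = drop, centroid = FALSE)
      r <- glance(d)
      expect_equal(r$nodes_after + length(r$removal_set[[1]]) +
                     r$isolates_dropped, r$nodes_before)
      expect_lte(r$edges_after, r$edges_before)
      expect_gte(r$components_after, 0)
      if (drop) {
        expect_equal(sum(igraph::degree(d$after) == 0), 0)
      } else {
        expect_equal(r$nodes_after - r$nodes_after_excl_isolated,
                     r$isolated_after)
      }
    }
  }
})

test_that("disaggregation of disjoint components commutes", {
  net <- make_net(c("a-b", "b-c", "a-c", "p-q", "q-r"))
  one_then_two <- disaggregate(disaggregate(net, "a", centroid = FALSE)$after,
                               "q", centroid = FALSE)$after
  two_then_one <- disaggregate(disaggregate(net, "q", centroid = FALSE)$after,
                               "a", centroid = FALSE)$after
  expect_equal(network_nodes(one_then_two), network_nodes(two_then_one))
  expect_equal(network_edges(one_then_two), network_edges(two_then_one))
})

test_that("subnetwork extraction returns the seed's component", {
  net <- make_net(c("a-b", "b-c", "a-c", "p-q"), isolates = "z")
  tri <- subnetwork_extract(net, "b")
  expect_setequal(igraph::V(tri)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(tri), 3)
  solo <- subnetwork_extract(net, "z")
  expect_equal(igraph::vcount(solo), 1)
  expect_error(subnetwork_extract(net, "nope"), "not present")
  # a gene mappable to an independent subnetwork holding 9 edges
  sub9 <- make_net(c("CLN-a", "CLN-b", "CLN-c", "a-b", "b-c", "a-c",
                     "c-d", "d-e", "e-a", "far-away"))
  comp <- subnetwork_extract(sub9, "CLN")
  expect_equal(igraph::ecount(comp), 9)
  expect_false("far" %in% igraph::V(comp)$name)
})

test_that("mean centroid magnitude shrinks when the dominant hub complex is subtracted", {
  dec <- vapply(1:6, function(s) {
    db <- generate_db(synth_params(n_diseases = 80, n_genes = 200,
                                   n_phenotypes = 50, n_proteins = 400,
                                   genes_per_disease_m = 3, seed = s))
    net <- build_network(db, "disease_gene")
    ct <- centrality_table(net, centroid = FALSE)
    top <- ct$node_id[which.max(ct$betweenness_raw)]
    r <- glance(disaggregate(net, top, include_neighbors = TRUE))
    abs(r$mean_centroid_after) <= abs(r$mean_centroid_before)
  }, logical(1))
  expect_gte(mean(dec), 0.8)
})
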