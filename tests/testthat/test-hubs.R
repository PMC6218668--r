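fake_records <- function(rad) {
  tibble::tibble(node_id = sprintf("g%d", seq_along(rad)),
                 kind = "gene", degree = 2L,
                 component_size = length(rad), tn = 0.5,
                 radiality_raw = rad, radiality_norm = rad,
                 betweenness_raw = 0, betweenness_norm = 0, centroid = 0)
}

test_that("rank_nodes orders by the measure with node-id tie-breaks", {
  rec <- fake_records(c(0.8, 1.0, 0.5))
  top <- rank_nodes(rec, order_by = "radiality", k = 2)
  expect_equal(top$node_id, c("g2", "g1"))
  tied <- rank_nodes(fake_records(c(0.7, 0.7, 0.7)), k = 2)
  expect_equal(tied$node_id, c("g1", "g2"))
  expect_error(rank_nodes(rec, order_by = "eigenvector"),
               class = "retinet_usage_error")
})

test_that("rank_nodes filters by kind and component size and is idempotent", {
  net <- build_network(toy_db(), "disease_gene")
  ct <- centrality_table(net)
  genes_only <- rank_nodes(ct, k = 10, kind = "gene")
  expect_true(all(genes_only$kind == "gene"))
  top <- rank_nodes(ct, k = 3)
  expect_equal(rank_nodes(top, k = 3)$node_id, top$node_id)
  # small-component exclusion drops two-node components
  two <- make_net(c("a-b", "c-d", "d-e"))
  ct2 <- centrality_table(two)
  kept <- rank_nodes(ct2, k = 10, min_component_size = 3)
  expect_false(any(c("a", "b") %in% kept$node_id))
})

test_that("lowering a node's score never improves its rank", {
  set.seed(31)
  rec <- fake_records(stats::runif(8))
  full <- rank_nodes(rec, k = 8)
  for (i in sample(8, 4)) {
    pert <- rec
    pert$radiality_norm[i] <- pert$radiality_norm[i] * 0.5
    pert$radiality_raw[i] <- pert$radiality_norm[i]
    new_rank <- match(rec$node_id[i], rank_nodes(pert, k = 8)$node_id)
    old_rank <- match(rec$node_id[i], full$node_id)
    expect_gte(new_rank, old_rank)
  }
})

test_that("top-table overlap maps proteins to genes, is symmetric and reflexive", {
  db <- toy_db()
  map <- protein_gene_map(db)
  expect_equal(map$label[map$node_id == "P1"], "G2")
  a <- tibble::tibble(node_id = c("G1", "P1"), kind = c("gene", "protein"))
  b <- tibble::tibble(node_id = c("G2", "G3"), kind = "gene")
  expect_equal(top_overlap(a, b, map), "G2")          # via P1 -> G2
  # a pre-existing label column in the table must not shadow the mapping
  a2 <- dplyr::mutate(a, label = "stale")
  expect_equal(top_overlap(a2, b, map), "G2")
  expect_equal(top_overlap(b, a, map), top_overlap(a, b, map))
  expect_setequal(top_overlap(a, a, map), c("G1", "G2"))
  disjoint <- tibble::tibble(node_id = "G9", kind = "gene")
  expect_length(top_overlap(a, disjoint, map), 0)
  # unmapped protein accession excluded with a warning
  c_tab <- tibble::tibble(node_id = "P99", kind = "protein")
  expect_warning(res <- top_overlap(c_tab, b, map), "without gene mapping")
  expect_length(res, 0)
})

test_that("scatter points carry the requested coordinates", {
  p3 <- generate_reference_graph("path", 3)
  ct <- centrality_table(p3)
  pts <- scatter_points(ct, "tn", "radiality")
  expect_equal(pts$node_id, c("a", "b", "c"))
  expect_equal(pts$x, c(0, 0, 0))
  expect_equal(pts$y, c(0.75, 1, 0.75))
  expect_error(scatter_points(ct, "tn", "tn"), class = "retinet_usage_error")
  expect_s3_class(plot_centrality_scatter(ct, highlight = "b"), "ggplot")
})

test_that("degree-threshold classification separates peripheral, hub and superhub", {
  star <- generate_reference_graph("star", 6)  # center + 5 leaves
  cls <- classify_nodes(star)
  expect_equal(as.character(cls$class[cls$node_id == "a"]), "hub")
  expect_true(all(cls$class[cls$node_id != "a"] == "peripheral"))

  # two hubs bridged by a third high-degree node -> the bridge is a superhub
  bridge <- make_net(c("h1-l1", "h1-l2", "h1-l3", "h1-l4", "h1-l5",
                       "h2-m1", "h2-m2", "h2-m3", "h2-m4", "h2-m5",
                       "mid-h1", "mid-h2", "mid-k1", "mid-k2", "mid-k3",
                       "mid-k4"))
  cb <- classify_nodes(bridge)
  expect_equal(as.character(cb$class[cb$node_id == "mid"]), "superhub")
  expect_equal(as.character(cb$class[cb$node_id == "h1"]), "hub")
  expect_true(is.numeric(attr(cb, "hub_threshold")))

  # alternative rules
  abs_cls <- classify_nodes(star, rule = "absolute", value = 5)
  expect_equal(sum(abs_cls$class != "peripheral"), 1)
  q_cls <- classify_nodes(star, rule = "quantile", value = 0.99)
  expect_equal(sum(q_cls$class != "peripheral"), 1)
})

test_that("superhub implies hub implies not peripheral on generated networks", {
  for (s in 1:5) {
    net <- build_network(generate_db(tiny_synth(seed = s)), "disease_gene")
    cls <- classify_nodes(net)
    deg <- igraph::degree(net)[cls$node_id]
    thr <- attr(cls, "hub_threshold")
    expect_true(all((cls$class != "peripheral") == (deg >= thr)))
    sh <- cls$node_id[cls$class == "superhub"]
    hubs <- cls$node_id[cls$class != "peripheral"]
    for (v in sh) {
      nb <- igraph::neighbors(net, v)$name
      expect_gte(sum(nb %in% hubs), 2)
    }
  }
})

test_that("interpretation labels follow the tn extremes", {
  net <- make_net(c("a-b", "b-c", "a-c", "c-d", "d-e", "e-f", "f-d"))
  top <- rank_nodes(centrality_table(net), k = 6)
  expect_true("interpretation" %in% names(top))
  expect_true(all(top$interpretation[top$tn >= 0.9] == "isolated subnetwork"))
})
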