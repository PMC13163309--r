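test_that("network construction thresholds, deduplicates and drops loops", {
  el <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                   combined_score = c(0.9, 0.65))
  net <- build_network(el, 0.700)
  expect_equal(igraph::ecount(net$graph), 1)
  # an edge at exactly the threshold is retained (inclusive)
  at <- build_network(data.frame(node_a = "A", node_b = "B",
                                 combined_score = 0.700), 0.700)
  expect_equal(igraph::ecount(at$graph), 1)
  # duplicate unordered pair collapses to the maximum score
  dup <- build_network(data.frame(node_a = c("A", "B"), node_b = c("B", "A"),
                                  combined_score = c(0.8, 0.9)), 0.7)
  expect_equal(igraph::ecount(dup$graph), 1)
  expect_equal(dup$edges$combined_score, 0.9)
  expect_warning(
    build_network(data.frame(node_a = c("A", "A"), node_b = c("A", "B"),
                             combined_score = c(0.9, 0.9))),
    "self-loop")
  expect_error(build_network(data.frame(node_a = "A", node_b = "B",
                                        combined_score = 1.2)), "\\[0, 1\\]")
  expect_error(build_network(data.frame(node_a = "A", node_b = NA,
                                        combined_score = 0.9)), "malformed")
})

test_that("raising the confidence threshold never adds edges", {
  set.seed(14)
  el <- data.frame(node_a = sprintf("n%02d", sample(1:20, 60, TRUE)),
                   node_b = sprintf("n%02d", sample(1:20, 60, TRUE)),
                   combined_score = runif(60))
  el <- el[el$node_a != el$node_b, ]
  thr <- seq(0, 1, by = 0.1)
  counts <- vapply(thr, function(th)
    igraph::ecount(build_network(el, th)$graph), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("average degree equals 2E/N including the 20-node, 116-edge identity", {
  net <- build_network(graph_20x116())
  expect_equal(igraph::vcount(net$graph), 20)
  expect_equal(igraph::ecount(net$graph), 116)
  expect_equal(average_degree(net), 11.6, tolerance = 1e-12)

  tri <- build_network(data.frame(node_a = c("a", "b", "c"),
                                  node_b = c("b", "c", "a"),
                                  combined_score = 0.9))
  expect_equal(average_degree(tri), 2)
  path3 <- build_network(data.frame(node_a = c("a", "b"),
                                    node_b = c("b", "c"),
                                    combined_score = 0.9))
  expect_equal(average_degree(path3), 4 / 3)
  expect_error(average_degree(build_network(
    data.frame(node_a = character(0), node_b = character(0),
               combined_score = numeric(0)))), "empty")
})

test_that("local clustering matches hand-enumerated cases", {
  tri <- build_network(data.frame(node_a = c("a", "b", "c"),
                                  node_b = c("b", "c", "a"),
                                  combined_score = 0.9))
  expect_equal(avg_clustering(tri), 1)
  star <- build_network(data.frame(node_a = "hub",
                                   node_b = paste0("leaf", 1:4),
                                   combined_score = 0.9))
  expect_equal(avg_clustering(star), 0)
  # 4-cycle plus one diagonal: local coefficients (2/3, 1, 2/3, 1)/... = 5/6
  sq <- build_network(data.frame(node_a = c("a", "b", "c", "d", "a"),
                                 node_b = c("b", "c", "d", "a", "c"),
                                 combined_score = 0.9))
  expect_equal(avg_clustering(sq), 5 / 6, tolerance = 1e-12)
  # exclusion variant drops degree-<2 nodes from the mean
  pend <- build_network(data.frame(node_a = c("a", "b", "c", "c"),
                                   node_b = c("b", "c", "a", "d"),
                                   combined_score = 0.9))
  expect_equal(avg_clustering(pend, include_low_degree = TRUE),
               (1 + 1 + 1 / 3 + 0) / 4)
  expect_equal(avg_clustering(pend, include_low_degree = FALSE),
               (1 + 1 + 1 / 3) / 3)
})

test_that("degree handshake and oracle agreement hold on random graphs", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    adj <- random_adjacency(n)
    net <- adj_to_network(adj)
    deg <- igraph::degree(net$graph)
    expect_equal(sum(deg), 2 * igraph::ecount(net$graph))
    orc <- graph_stats_oracle(adj)
    expect_equal(average_degree(net), orc$avg_degree, tolerance = 1e-12)
    expect_equal(avg_clustering(net), orc$avg_clustering, tolerance = 1e-12)
  }
})

test_that("hub ranking orders by degree with stable ties", {
  star <- build_network(data.frame(node_a = "hub",
                                   node_b = paste0("leaf", 1:4),
                                   combined_score = 0.9))
  hr <- hub_rank(star, 1)
  expect_identical(hr$node, "hub")
  expect_identical(hr$degree, 4L)
  expect_warning(all_nodes <- hub_rank(star, 10), "exceeds")
  expect_identical(nrow(all_nodes), 5L)
  # ties broken by node id ascending
  expect_identical(all_nodes$node[2:5], paste0("leaf", 1:4))
  expect_error(hub_rank(star, 0), "k must be")
})

test_that("planted hubs are recovered in the top-k across 100 seeds", {
  hits <- 0L
  for (s in 1:100) {
    nw <- simulate_network(sim_config(seed = s))
    net <- build_network(nw$edges, min_combined = 0.700)
    top <- hub_rank(net, 5)$node
    hits <- hits + all(nw$truth$hub_node_ids %in% top)
  }
  expect_gte(hits, 95L)
})
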