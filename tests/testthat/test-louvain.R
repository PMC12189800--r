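# Modularity, dQ, local moving, aggregation, the full Louvain loop, and
# the brute-force optimum oracle.

test_that("modularity reproduces hand-derived fixture values exactly", {
  e <- fix_single_edge()
  expect_equal(zganet::modularity(e, c(a = 1, b = 1)), 0, tolerance = 1e-12)
  expect_equal(zganet::modularity(e, c(a = 1, b = 2)), -0.5, tolerance = 1e-12)
  tt <- fix_two_triangles()
  part <- tibble::tibble(node = tt$nodes,
                         community = ifelse(tt$nodes %in% c("a", "b", "c"), 1, 2))
  expect_equal(zganet::modularity(tt, part), 0.5, tolerance = 1e-12)
  # one community on any loop-free graph is 0
  for (s in 1:3) {
    g <- random_weighted_graph(10, 0.4, seed = s)
    expect_equal(zganet::modularity(g, stats::setNames(rep(1, 10), g$nodes)),
                 0, tolerance = 1e-12)
  }
  lonely <- weighted_graph(data.frame(from = character(0), to = character(0),
                                      weight = numeric(0)), nodes = c("a", "b"))
  expect_error(zganet::modularity(lonely, c(a = 1, b = 2)), "total weight 0")
})

test_that("bookkeeping modularity equals the direct double-sum oracle", {
  worst <- 0
  for (s in 1:100) {
    g <- random_weighted_graph(4 + (s %% 9), 0.5, seed = s)
    p <- random_partition(g, k = 1 + (s %% 4), seed = s + 500)
    worst <- max(worst, abs(zganet::modularity(g, p) - modularity_direct(g, p)))
  }
  expect_lt(worst, 1e-10)
})

test_that("modularity agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    g <- random_weighted_graph(12, 0.4, seed = s)
    p <- random_partition(g, 3, seed = s + 77)
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$nodes)
    qi <- igraph::modularity(ig, membership = p[igraph::V(ig)$name],
                             weights = igraph::E(ig)$weight)
    expect_equal(zganet::modularity(g, p), qi, tolerance = 1e-12)
  }
})

test_that("dQ for a single move matches from-scratch recomputation", {
  # documented example: two disjoint unit edges, all singletons, a -> {b}
  g2 <- fix_two_disjoint_edges()
  p0 <- stats::setNames(1:4, g2$nodes)
  expect_equal(delta_q_move(g2, p0, "a", 2), 0.375, tolerance = 1e-12)
  # move into own community is exactly zero
  expect_equal(delta_q_move(g2, p0, "a", 1), 0)
  expect_error(delta_q_move(g2, p0, "a", 99), "does not exist")

  # seeded random moves on random weighted graphs
  worst <- 0
  n_checked <- 0
  for (s in 1:40) {
    g <- random_weighted_graph(4 + (s %% 8), 0.5, seed = s)
    p <- random_partition(g, 3, seed = s + 1000)
    nodes <- withr::with_seed(s + 2000, sample(g$nodes, 5, replace = TRUE))
    for (nd in nodes) {
      targets <- unique(p)
      tgt <- targets[withr::with_seed(s + 3000 + match(nd, g$nodes),
                                      sample.int(length(targets), 1))]
      dq <- delta_q_move(g, p, nd, tgt)
      p_after <- p
      p_after[nd] <- tgt
      dq_direct <- modularity_direct(g, p_after) - modularity_direct(g, p)
      worst <- max(worst, abs(dq - dq_direct))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
  expect_lt(worst, 1e-10)
})

test_that("local moving phase converges greedily and only uphill", {
  # already optimal: two cliques labelled as such -> no move
  tt <- fix_two_triangles()
  opt <- tibble::tibble(node = tt$nodes,
                        community = ifelse(tt$nodes %in% c("a", "b", "c"), 1, 2))
  res <- local_moving_phase(tt, opt, seed = 1)
  expect_false(res$improved)
  expect_equal(zganet::modularity(tt, res$partition), 0.5)

  # from singletons, two triangles resolve to the triangle partition
  singles <- tibble::tibble(node = tt$nodes, community = seq_along(tt$nodes))
  res2 <- local_moving_phase(tt, singles, seed = 3)
  expect_true(res2$improved)
  expect_equal(zganet::modularity(tt, res2$partition), 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res2$partition$community)), 2)

  # single edge from singletons merges (dQ = +0.5)
  e <- fix_single_edge()
  res3 <- local_moving_phase(e, tibble::tibble(node = e$nodes, community = 1:2),
                             seed = 1)
  expect_equal(length(unique(res3$partition$community)), 1)
  expect_equal(zganet::modularity(e, res3$partition), 0)
})

test_that("aggregation preserves modularity exactly", {
  tt <- fix_two_triangles()
  part <- tibble::tibble(node = tt$nodes,
                         community = ifelse(tt$nodes %in% c("a", "b", "c"), 1, 2))
  agg <- aggregate_graph(tt, part)
  expect_equal(length(agg$nodes), 2)
  expect_equal(nrow(agg$edges), 0)
  dag <- node_degrees(agg)
  expect_equal(dag$weighted_degree, c(6, 6))
  expect_equal(graph_total_weight(agg), 6)
  expect_equal(zganet::modularity(agg, stats::setNames(1:2, agg$nodes)),
               0.5, tolerance = 1e-15)

  # singleton partition aggregates to an isomorphic graph
  g <- random_weighted_graph(8, 0.5, seed = 21)
  singles <- stats::setNames(seq_along(g$nodes), g$nodes)
  ag <- aggregate_graph(g, singles)
  expect_equal(length(ag$nodes), length(g$nodes))
  expect_equal(graph_total_weight(ag), graph_total_weight(g))
  expect_equal(sort(node_degrees(ag)$weighted_degree),
               sort(node_degrees(g)$weighted_degree))

  # triangle + pendant collapsed to one community: all weight in one node
  tp <- weighted_graph(data.frame(from = c("a", "b", "c", "c"),
                                  to = c("b", "c", "a", "d")))
  one <- stats::setNames(rep(1, 4), tp$nodes)
  atp <- aggregate_graph(tp, one)
  expect_equal(length(atp$nodes), 1)
  expect_equal(graph_total_weight(atp), 4)
  expect_equal(zganet::modularity(atp, stats::setNames(1, atp$nodes)), 0)

  # exactness on 100 seeded (graph, partition) pairs
  worst <- 0
  for (s in 1:100) {
    g <- random_weighted_graph(4 + (s %% 10), 0.5, seed = s + 40)
    p <- random_partition(g, 1 + (s %% 4), seed = s + 140)
    a <- aggregate_graph(g, p)
    qa <- zganet::modularity(a, stats::setNames(seq_along(a$nodes), a$nodes))
    worst <- max(worst, abs(qa - zganet::modularity(g, p)))
  }
  expect_lt(worst, 1e-12)
})

test_that("run_louvain finds known optima and never beats brute force", {
  tt <- fix_two_triangles()
  for (s in c(0, 1, 7, 42)) {
    res <- run_louvain(tt, seed = s)
    expect_equal(res$n_communities, 2)
    expect_equal(res$modularity, 0.5, tolerance = 1e-12)
  }
  # complete graph: one community, Q = 0, confirmed optimal by enumeration
  k5 <- fix_k5()
  rk5 <- run_louvain(k5, seed = 0)
  expect_equal(rk5$n_communities, 1)
  expect_equal(rk5$modularity, 0)
  expect_equal(brute_force_max_modularity(k5)$q, 0, tolerance = 1e-12)

  for (fx in small_fixture_suite()) {
    bf <- brute_force_max_modularity(fx$g)
    res <- run_louvain(fx$g, seed = 1)
    expect_lte(res$modularity, bf$q + 1e-12)
    if (fx$cliques) {
      expect_equal(res$modularity, bf$q, tolerance = 1e-12,
                   info = fx$name)
    }
  }
  expect_error(run_louvain(weighted_graph(
    data.frame(from = character(0), to = character(0), weight = numeric(0)),
    nodes = "a")), "total weight 0")
})

test_that("run_louvain is deterministic under a seed with monotone Q trajectory", {
  g <- simulate_ppi(ppi_sim_config(block_sizes = c(25, 25, 25), p_in = 0.4,
                                   p_out = 0.02, seed = 5))$graph
  r1 <- run_louvain(g, seed = 11)
  r2 <- run_louvain(g, seed = 11)
  expect_identical(r1$membership, r2$membership)
  expect_identical(r1$q_trajectory, r2$q_trajectory)
  expect_true(all(diff(r1$q_trajectory) >= 0))
  # community ids are 0..K-1 in decreasing size order
  sizes <- table(r1$membership$community)
  expect_equal(names(sizes), as.character(seq_along(sizes) - 1))
  expect_true(all(diff(as.integer(sizes)) <= 0))
  # flat partition modularity equals the reported trajectory end
  expect_equal(zganet::modularity(g, r1$membership),
               r1$q_trajectory[length(r1$q_trajectory)], tolerance = 1e-12)
})

test_that("brute force enumerates set partitions correctly", {
  # 3 nodes -> 5 partitions (Bell number)
  expect_equal(length(zganet:::all_set_partitions(3)), 5)
  expect_equal(length(zganet:::all_set_partitions(5)), 52)
  e <- fix_single_edge()
  bf <- brute_force_max_modularity(e)
  expect_equal(bf$q, 0)
  expect_equal(length(unique(bf$partition$community)), 1)
  p3 <- fix_path3()
  bf3 <- brute_force_max_modularity(p3)
  expect_gte(bf3$q, run_louvain(p3, seed = 2)$modularity - 1e-12)
  big <- random_weighted_graph(9, 0.5, seed = 1)
  expect_error(brute_force_max_modularity(big), "capped at 8")
})

test_that("planted SBM communities are recovered across seeds", {
  skip_if_not_installed("mclust")
  hits <- 0
  for (s in 0:9) {
    sim <- simulate_ppi(ppi_sim_config(block_sizes = c(60, 60), p_in = 0.3,
                                       p_out = 0.01, seed = s))
    res <- run_louvain(sim$graph, seed = s)
    ari <- mclust::adjustedRandIndex(
      res$membership$community,
      sim$truth$block[match(res$membership$node, sim$truth$node)])
    if (ari >= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("tidiers expose membership and summary rows", {
  tt <- fix_two_triangles()
  res <- run_louvain(tt, seed = 1)
  td <- generics::tidy(res)
  expect_equal(nrow(td), 6)
  expect_named(td, c("node", "community"))
  gl <- generics::glance(res)
  expect_equal(gl$n_communities, 2)
  expect_equal(gl$modularity, 0.5, tolerance = 1e-12)
})
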