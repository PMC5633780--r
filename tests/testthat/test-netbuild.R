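test_that("build counts degrees exactly on a hand-checkable graph", {
  net <- toy_ct()
  expect_equal(unname(net$left_degree[c("a", "b")]), c(2L, 1L))
  expect_equal(unname(net$right_degree[c("x", "y")]), c(2L, 1L))
  st <- network_stats(net)
  expect_equal(st$n_left, 2L)
  expect_equal(st$n_right, 2L)
  expect_equal(st$n_edges, 3L)
})

test_that("isolates are excluded by default but tracked, included on demand", {
  el <- edge_list("a", "x", "compound-target")
  net <- build_network(el, left_universe = c("a", "b"),
                       right_universe = c("x", "y"))
  expect_equal(net$left_nodes, "a")
  expect_equal(net$isolates, list(left = "b", right = "y"))
  full <- build_network(el, left_universe = c("a", "b"),
                        right_universe = c("x", "y"),
                        include_isolates = TRUE)
  expect_equal(unname(full$left_degree[c("a", "b")]), c(1L, 0L))

  empty <- build_network(edge_list(character(), character(),
                                   "compound-target"),
                         left_universe = c("a", "b"),
                         right_universe = "x", include_isolates = TRUE)
  expect_true(all(empty$left_degree == 0L))
  expect_equal(network_stats(empty)$n_edges, 0L)

  expect_error(build_network(el, left_universe = c("a", "x"),
                             right_universe = "x"), "disjoint")
})

test_that("degree table is ordered degree-desc then id-asc with exact counts", {
  dt <- degree_table(toy_ct())
  # a and x tie at degree 2; a precedes x lexicographically
  expect_equal(dt$id[1:2], c("a", "x"))
  expect_equal(dt$degree, c(2L, 2L, 1L, 1L))
  # every row's degree equals a brute-force count over the edge list
  net <- build_network(random_edges(6, 8, 30))
  dt2 <- degree_table(net)
  for (i in seq_len(nrow(dt2))) {
    col <- if (dt2$side[i] == "compound") net$edges$left else net$edges$right
    expect_equal(dt2$degree[i], sum(col == dt2$id[i]))
  }
})

test_that("degree sums on both sides equal the edge count (conservation)", {
  set.seed(99)
  for (i in 1:100) {
    net <- build_network(random_edges(sample(2:10, 1), sample(2:10, 1),
                                      sample(1:40, 1)))
    m <- nrow(net$edges)
    expect_equal(sum(net$left_degree), m)
    expect_equal(sum(net$right_degree), m)
    # cross-check the whole stat family against igraph
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
    expect_equal(sort(unname(net$left_degree)),
                 sort(unname(igraph::degree(g)[net$left_nodes])))
    expect_equal(sort(unname(net$right_degree)),
                 sort(unname(igraph::degree(g)[net$right_nodes])))
  }
})

test_that("build is idempotent on a network's own edge dump", {
  set.seed(4)
  net <- build_network(random_edges(7, 9, 35))
  redo <- build_network(edge_list(net$edges$left, net$edges$right, net$kind))
  expect_equal(network_stats(redo), network_stats(net))
  expect_equal(redo$left_degree, net$left_degree)
})

test_that("shared targets require incident compounds spanning both herbs", {
  herb_of <- list(ql = "Huanglian", qq = "Huangqi",
                  both = c("Huanglian", "Huangqi"))
  # t1 hit by one herb only; t2 by both; t3 by a single dual-herb compound
  ct <- build_network(edge_list(c("ql", "ql", "qq", "both"),
                                c("t1", "t2", "t2", "t3"),
                                "compound-target"))
  sh <- shared_targets(ct, herb_of)
  expect_equal(sh, c("t2", "t3"))
  expect_true(all(sh %in% ct$right_nodes))
  expect_error(shared_targets(ct, herb_of["ql"]), "attribution")
})

test_that("generator's planted structure is recovered by the graph module", {
  sim <- generate_dataset(small_spec(seed = 21))
  ds <- sim$dataset
  active <- c(sim$truth$passed, sim$truth$rescued)
  net <- build_network(ds$ct, left_universe = active,
                       right_universe = ds$targets$target_id)
  # hub degree and full degree map match the generator's bookkeeping
  dt <- degree_table(net)
  hubs <- dt$id[dt$side == "compound" & dt$degree == max(sim$truth$ct_degrees)]
  expect_true(all(sim$truth$planted %in% hubs))
  expect_equal(net$left_degree[names(sim$truth$ct_degrees)],
               sim$truth$ct_degrees)
  # shared-target set equals the generator's independent loop
  sh <- shared_targets(net, herb_attribution(ds$ingredients),
                       herbs = ds$herbs)
  expect_equal(sh, sim$truth$shared_targets)
})
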