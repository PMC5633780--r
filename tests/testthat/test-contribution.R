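test_that("network efficacy matches hand evaluation and conventions", {
  ct <- build_network(edge_list(c("j", "j", "k"), c("t1", "t2", "t3"),
                                "compound-target"),
                      left_universe = c("j", "k", "lonely"),
                      right_universe = c("t1", "t2", "t3"))
  tp <- build_network(edge_list(c("t1", "t1", "t1", "t2", "t2"),
                                c("p1", "p2", "p3", "p1", "p4"),
                                "target-pathway"))
  expect_equal(network_efficacy(ct, tp, "j"), 5L)   # 3 + 2
  expect_equal(network_efficacy(ct, tp, "lonely"), 0L)  # no targets
  expect_equal(network_efficacy(ct, tp, "k"), 0L)   # t3 in no pathway
  expect_error(network_efficacy(ct, tp, "nope"), "unknown")
})

test_that("contribution index reproduces hand arithmetic and its symmetries", {
  r <- contribution_index(c(a = 3, b = 1), c(a = 1, b = 1))
  expect_equal(unname(r$ci[c("a", "b")]), c(75, 25))
  r2 <- contribution_index(c(a = 2, b = 2), c(a = 5, b = 5))
  expect_equal(unname(r2$ci[c("a", "b")]), c(50, 50))
  # scale invariance in the literature counts
  r3 <- contribution_index(c(a = 3, b = 1), c(a = 10, b = 10))
  expect_equal(r3$ci, r$ci)
  expect_error(contribution_index(c(a = 0, b = 0), c(a = 1, b = 1)),
               "zero")
  expect_warning(r4 <- contribution_index(c(a = 3, b = 1), c(a = 2)),
                 "weight 0")
  expect_equal(unname(r4$ci[c("a", "b")]), c(100, 0))
})

test_that("CI sums to 100 on 1000 random instances", {
  set.seed(1234)
  for (i in 1:1000) {
    m <- sample(2:12, 1)
    ids <- paste0("i", seq_len(m))
    ne <- setNames(sample(0:20, m, replace = TRUE), ids)
    cc <- setNames(sample(0:50, m, replace = TRUE), ids)
    if (sum(ne * cc) == 0) next
    r <- contribution_index(ne, cc)
    expect_equal(sum(r$ci), 100, tolerance = 1e-9)
    expect_true(all(r$ci[cc == 0 | ne == 0] == 0))
  }
})

test_that("NE and CI agree with the nested-loop oracle on random graphs", {
  set.seed(55)
  for (rep in 1:12) {
    n_c <- sample(3:12, 1); n_t <- sample(3:15, 1); n_p <- sample(2:10, 1)
    ct_el <- random_edges(n_c, n_t, sample(5:40, 1), "compound-target",
                          "c", "t")
    tp_el <- random_edges(n_t, n_p, sample(3:30, 1), "target-pathway",
                          "t", "p")
    ct <- build_network(ct_el)
    tp <- build_network(tp_el)
    ne <- setNames(vapply(ct$left_nodes,
                          function(j) network_efficacy(ct, tp, j),
                          integer(1)), ct$left_nodes)
    for (j in ct$left_nodes) {
      expect_equal(ne[[j]], bf_network_efficacy(ct_el, tp_el, j))
    }
    cc <- setNames(sample(1:30, length(ne), replace = TRUE), names(ne))
    if (sum(cc * ne) == 0) next
    r <- contribution_index(ne, cc)
    expect_equal(r$ci[names(ne)], bf_contribution_index(ne, cc))
  }
})

test_that("increasing an ingredient's literature count never lowers its CI", {
  set.seed(77)
  ne <- setNames(sample(1:20, 8), paste0("i", 1:8))
  cc <- setNames(sample(1:30, 8), names(ne))
  base <- contribution_index(ne, cc)$ci
  for (boost in c(1, 5, 20)) {
    cc2 <- cc
    cc2["i3"] <- cc["i3"] + boost
    expect_gte(contribution_index(ne, cc2)$ci[["i3"]], base[["i3"]])
  }
})

test_that("the top set is the minimal prefix strictly exceeding the threshold", {
  mk <- function(ci_shares) {
    # build an exact CI vector through NE with unit literature counts
    ids <- paste0("i", seq_along(ci_shares))
    contribution_index(setNames(ci_shares, ids),
                       setNames(rep(1, length(ids)), ids))
  }
  top <- top_contributors(mk(c(60, 30, 10)), 85)
  expect_equal(as.character(top), c("i1", "i2"))
  expect_equal(attr(top, "cumulative"), c(60, 90))
  # cumulative exactly 85 does not stop the prefix ("more than 85%")
  top2 <- top_contributors(mk(c(85, 15)), 85)
  expect_equal(as.character(top2), c("i1", "i2"))
  top3 <- top_contributors(mk(100), 99.9)
  expect_equal(as.character(top3), "i1")
  expect_error(top_contributors(mk(c(50, 50)), 0), "threshold")
  expect_error(top_contributors(mk(c(50, 50)), 101), "threshold")
  # ties in CI broken by NE, then id
  r <- contribution_index(setNames(c(4, 2, 2), c("b", "c", "a")),
                          setNames(c(1, 2, 2), c("b", "c", "a")))
  expect_equal(r$ranking, c("b", "a", "c"))
})

test_that("weight sensitivity is deterministic and flags the dominant set", {
  ct <- build_network(edge_list(c("big", "big", "small"),
                                c("t1", "t2", "t3"), "compound-target"))
  tp <- build_network(edge_list(c("t1", "t2", "t3"), c("p1", "p1", "p2"),
                                "target-pathway"))
  lit <- c(big = 500, small = 1)
  f0 <- weight_sensitivity(ct, tp, lit, perturbation = 0, reps = 5,
                           seed = 3)
  expect_true(all(f0 %in% c(0, 1)))
  expect_equal(f0[["big"]], 1)
  f1 <- weight_sensitivity(ct, tp, lit, perturbation = 0.05, reps = 200,
                           seed = 3)
  expect_equal(f1, weight_sensitivity(ct, tp, lit, perturbation = 0.05,
                                      reps = 200, seed = 3))
  expect_equal(f1[["big"]], 1)  # ci share ~0.999 survives 5% noise
  expect_true(all(f1 >= 0 & f1 <= 1))
})
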