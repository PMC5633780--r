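# Shared fixtures and independent brute-force oracles for the suite.
# The oracles deliberately use plain nested loops / igraph, never the
# package's own code paths.

toy_ct <- function() {
  build_network(edge_list(c("a", "a", "b"), c("x", "y", "x"),
                          "compound-target"))
}

# random bipartite edge list with n_l/n_r nodes and m sampled pairs
random_edges <- function(n_l, n_r, m, kind = "compound-target",
                         lprefix = "c", rprefix = "t") {
  left <- paste0(lprefix, sample.int(n_l, m, replace = TRUE))
  right <- paste0(rprefix, sample.int(n_r, m, replace = TRUE))
  edge_list(left, right, kind)
}

# brute-force degree of one id in an edge list column
bf_degree <- function(ids, column) {
  vapply(ids, function(i) sum(column == i), integer(1L))
}

# nested-loop network efficacy: for ingredient j, sum over its distinct
# C-T targets of the target's T-P degree
bf_network_efficacy <- function(ct_edges, tp_edges, j) {
  total <- 0L
  for (t in unique(ct_edges$right[ct_edges$left == j])) {
    d <- 0L
    for (i in seq_len(nrow(tp_edges))) {
      if (tp_edges$left[i] == t) d <- d + 1L
    }
    total <- total + d
  }
  total
}

# nested-loop contribution index in percent
bf_contribution_index <- function(ne, cc) {
  denom <- 0
  for (i in names(ne)) denom <- denom + cc[[i]] * ne[[i]]
  vapply(names(ne), function(j) 100 * cc[[j]] * ne[[j]] / denom, numeric(1L))
}

# small ingredient table builder for screening tests
make_ingredients <- function(ob, dl, rescue = FALSE,
                             ids = sprintf("M%02d", seq_along(ob))) {
  n <- length(ob)
  df <- data.frame(ingredient_id = ids, name = ids,
                   stringsAsFactors = FALSE)
  df$herbs <- rep(list("Huangqi"), n)
  df$mw <- NA_real_; df$clogp <- NA_real_
  df$nhdon <- NA_real_; df$nhacc <- NA_real_
  df$ob <- ob; df$dl <- dl
  df$rescue <- rep_len(rescue, n)
  df
}

small_spec <- function(seed = 1, ...) {
  synthetic_spec(seed = seed, n_herb_a = 30L, n_herb_b = 20L, n_shared = 3L,
                 n_targets = 20L, n_pathways = 12L, n_organs = 10L,
                 ct_max_degree = 10L, pathway_size_range = c(2L, 6L),
                 n_planted = 2L, ...)
}
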