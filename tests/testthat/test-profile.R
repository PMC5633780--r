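ann_toy <- data.frame(
  term_id = c("GO:1", "GO:1", "GO:2", "GO:3"),
  category = c("BP", "BP", "MF", "CC"),
  gene = c("g1", "g2", "g1", "g3"),
  stringsAsFactors = TRUE)  # factors must be tolerated
ann_toy[] <- lapply(ann_toy, as.character)

test_that("category composition counts associations and sums to 100", {
  comp <- category_composition(ann_toy)
  expect_equal(comp$percent[comp$category == "BP"], 50)
  expect_equal(comp$percent[comp$category == "MF"], 25)
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)

  single <- category_composition(ann_toy[ann_toy$category == "BP", ])
  expect_equal(single$percent, 100)
  expect_error(category_composition(ann_toy[0, ]), "empty")

  # brute-force tally on a random table
  set.seed(6)
  big <- data.frame(term_id = paste0("t", sample(1:20, 200, TRUE)),
                    category = sample(c("BP", "MF", "CC"), 200, TRUE),
                    gene = paste0("g", sample(1:30, 200, TRUE)),
                    stringsAsFactors = FALSE)
  comp2 <- category_composition(big)
  dedup <- unique(big)
  for (i in seq_len(nrow(comp2))) {
    n_cat <- 0L
    for (r in seq_len(nrow(dedup))) {
      if (dedup$category[r] == comp2$category[i]) n_cat <- n_cat + 1L
    }
    expect_equal(comp2$n_associations[i], n_cat)
  }
})

test_that("organ distribution reports published-style percentages", {
  # 30 of 50 targets in one organ = 60%; 29 of 50 = 58%
  el <- edge_list(c(sprintf("T-%02d", 1:30), sprintf("T-%02d", 1:29)),
                  c(rep("retina", 30), rep("CD33_myeloid", 29)),
                  "target-organ")
  to <- build_network(el)
  od <- organ_distribution(to, 50)
  expect_equal(od$percent[od$organ == "retina"], 60)
  expect_equal(od$percent[od$organ == "CD33_myeloid"], 58)
  expect_equal(od$organ, c("retina", "CD33_myeloid"))  # count-desc order
  expect_error(organ_distribution(to, 0), "positive")
  expect_error(organ_distribution(to, 10), "smaller")
})

test_that("expression thresholding is exact, warned and nested in the factor", {
  expr <- rbind(t1 = c(10, 1, 1, 1), t2 = c(2, 2, 2, 2), t3 = c(0, 0, 0, 0))
  colnames(expr) <- paste0("o", 1:4)
  expect_warning(el <- threshold_expression(expr, 3), "t3")
  expect_equal(el$left, "t1")
  expect_equal(el$right, "o1")
  # uniform positive row: all organs at factor 1, none at factor 3
  suppressWarnings({
    el1 <- threshold_expression(expr, 1)
  })
  expect_equal(sum(el1$left == "t2"), 4L)
  expect_equal(sum(el$left == "t2"), 0L)

  set.seed(12)
  m <- matrix(rlnorm(200, 2, 1), 20, 10,
              dimnames = list(paste0("t", 1:20), paste0("o", 1:10)))
  pairs <- function(e) paste(e$left, e$right)
  prev <- NULL
  for (f in c(1, 2, 3, 5, 10)) {
    cur <- pairs(threshold_expression(m, f))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(threshold_expression(-m), "negative")
})

test_that("enrichment matches exact combinatorial arithmetic and flags nothing
           for disjoint queries", {
  universe <- paste0("g", 1:50)
  ann <- data.frame(term_id = "T1", category = "BP",
                    gene = paste0("g", 1:5), stringsAsFactors = FALSE)
  res <- enrich(paste0("g", 1:5), ann, universe)
  # P(all 5 draws in the 5-member term when drawing 5 from 50)
  p_exact <- choose(5, 5) * choose(45, 0) / choose(50, 5)
  expect_equal(res$p, p_exact)
  expect_equal(res$overlap, 5L)
  expect_equal(res$fold, (5 / 5) / (5 / 50))

  # multi-term: top term is the fully-overlapping one; zero overlap -> p = 1
  ann2 <- rbind(ann, data.frame(term_id = "T2", category = "BP",
                                gene = paste0("g", 40:45),
                                stringsAsFactors = FALSE))
  res2 <- enrich(paste0("g", 1:5), ann2, universe)
  expect_equal(res2$term_id[1], "T1")
  expect_equal(res2$p[res2$term_id == "T2"], 1)
  expect_false(any(enrich(paste0("g", 30:35), ann, universe)$significant))
  expect_error(enrich("g1", ann, character()), "empty universe")
  expect_error(enrich("zz", ann, universe), "outside")
})

test_that("Benjamini-Hochberg adjustment is monotone and >= raw p", {
  # hand computation: (0.01, 0.02, 0.03) * 3 / (1, 2, 3) -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(3)
  universe <- paste0("g", 1:100)
  ann <- do.call(rbind, lapply(1:15, function(i) {
    data.frame(term_id = paste0("T", i), category = "BP",
               gene = sample(universe, sample(3:20, 1)),
               stringsAsFactors = FALSE)
  }))
  res <- enrich(sample(universe, 20), ann, universe)
  expect_true(all(res$p_adjust >= res$p))
  # sorted by raw p, adjusted p never decreases
  expect_true(all(diff(res$p_adjust[order(res$p)]) >= -1e-12))
})
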