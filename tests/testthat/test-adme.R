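test_that("Tanimoto coefficient matches hand-computed values", {
  expect_equal(tanimoto(c(3, 1, 2, 5), c(3, 1, 2, 5)), 1.0)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0.0)
  # (1*1 + 0*1) / (1 + 2 - 1) = 0.5
  expect_equal(tanimoto(c(1, 0), c(1, 1)), 0.5)
  expect_error(tanimoto(c(1, 2), c(1, 2, 3)), "length")
  expect_error(tanimoto(c(a = 1, b = 0), c(b = 1, a = 0)), "label")
  expect_error(tanimoto(c(0, 0), c(0, 0)), "all-zero")
})

test_that("Tanimoto is symmetric, bounded on non-negative vectors, 1 iff equal", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(4, 0, 10)
    b <- runif(4, 0, 10)
    t_ab <- tanimoto(a, b)
    expect_equal(t_ab, tanimoto(b, a))
    expect_gte(t_ab, 0)
    expect_lte(t_ab, 1)
    expect_equal(tanimoto(a, a), 1.0)
  }
})

test_that("drug-likeness equals brute-force dot-product arithmetic", {
  ref <- drug_reference_mean()
  expect_length(ref, 4L)
  expect_equal(drug_likeness(ref, ref), 1.0)
  expect_equal(drug_likeness(rep(0, 4), ref), 0.0)
  set.seed(9)
  for (i in 1:20) {
    cmp <- setNames(runif(4, 0, 500), names(ref))
    dot <- 0
    for (k in 1:4) dot <- dot + cmp[[k]] * ref[[k]]
    na2 <- sum(cmp^2); nb2 <- sum(ref^2)
    expect_equal(drug_likeness(cmp, ref), dot / (na2 + nb2 - dot))
  }
})

test_that("screen partitions the table-1 fixture exactly as published", {
  ing <- fixture_paper_tables()$ingredients
  sr <- screen_ingredients(ing)
  # the three groups partition the id set
  all_ids <- sort(c(sr$passed, sr$rescued, sr$excluded))
  expect_equal(all_ids, sort(ing$ingredient_id))
  expect_length(intersect(sr$passed, sr$rescued), 0L)
  expect_length(intersect(sr$passed, sr$excluded), 0L)
  # all 43 actives survive: none excluded
  expect_equal(length(sr$passed) + length(sr$rescued), 43L)
  expect_length(sr$excluded, 0L)
  expect_true("M21" %in% sr$passed)     # palmatine 64.60 / 0.65
  expect_true("M98" %in% sr$rescued)    # astragaloside IV 2.20 / 0.15
  expect_true("M171" %in% sr$rescued)   # missing OB/DL, rescue-flagged
  # every passed id genuinely meets both thresholds
  aud <- sr$audit[sr$audit$ingredient_id %in% sr$passed, ]
  expect_true(all(aud$ob >= 30 & aud$dl >= 0.18))
})

test_that("thresholds are inclusive and missing values never pass", {
  ing <- make_ingredients(ob = c(30, 29.999, 30, NA),
                          dl = c(0.18, 0.18, 0.1799, 0.5),
                          rescue = c(FALSE, FALSE, TRUE, FALSE))
  sr <- screen_ingredients(ing)
  expect_equal(sr$passed, "M01")     # exactly at both boundaries
  expect_equal(sr$rescued, "M03")
  expect_equal(sort(sr$excluded), c("M02", "M04"))
})

test_that("raising either threshold never grows the passed set", {
  set.seed(13)
  ing <- make_ingredients(ob = runif(200, 0, 100), dl = runif(200, 0, 1),
                          rescue = runif(200) < 0.3)
  base <- screen_ingredients(ing, 30, 0.18)
  for (ob_min in c(0, 10, 30, 50, 90)) {
    for (dl_min in c(0, 0.18, 0.5, 0.9)) {
      sr <- screen_ingredients(ing, ob_min, dl_min)
      if (ob_min >= 30 && dl_min >= 0.18) {
        expect_true(all(sr$passed %in% base$passed))
      }
      # partition holds at every threshold pair
      expect_equal(length(sr$passed) + length(sr$rescued) +
                     length(sr$excluded), nrow(ing))
    }
  }
  # screen is permutation-invariant over input order
  perm <- ing[sample(nrow(ing)), ]
  sp <- screen_ingredients(perm, 30, 0.18)
  expect_setequal(sp$passed, base$passed)
  expect_setequal(sp$rescued, base$rescued)
})

test_that("Lipinski flags follow the at-most-one-violation rule", {
  ok <- lipinski_flags(list(mw = 350, clogp = 2, nhdon = 2, nhacc = 5))
  expect_true(ok$pass)
  expect_equal(ok$violations, 0L)
  bad <- lipinski_flags(list(mw = 780, clogp = 6.1, nhdon = 8, nhacc = 14))
  expect_false(bad$pass)
  expect_equal(bad$violations, 4L)
  part <- lipinski_flags(list(mw = 780, clogp = NA, nhdon = 2, nhacc = 5))
  expect_true(is.na(part$clogp_ok))
  expect_equal(part$violations, 1L)  # counted over determinate rules
  expect_true(part$pass)
})
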