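test_that("pooled reference proportions match their algebraic identities", {
  one <- matrix(c(2, 3, 5), ncol = 1,
                dimnames = list(c("A", "B", "C"), "s1"))
  expect_equal(unname(estimate_p_r(one)), c(0.2, 0.3, 0.5))

  two <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(unname(estimate_p_r(two)), c(0.5, 0.5))

  set.seed(23)
  m <- matrix(rpois(12, 30), 3, 4,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  # pooled estimate equals the depth-weighted mean of per-sample proportions
  w <- colSums(m) / sum(m)
  per_sample <- sweep(m, 2, colSums(m), "/")
  expect_equal(estimate_p_r(m), drop(per_sample %*% w), tolerance = 1e-12)
  # and is invariant to sample order
  expect_equal(estimate_p_r(m), estimate_p_r(m[, c(3, 1, 4, 2)]))

  expect_error(estimate_p_r(matrix(0, 2, 2)), "all zero")
})

test_that("rarefaction subsamples without replacement to the target depth", {
  m <- matrix(c(8, 4, 2, 20, 10, 10), 3,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  # a sample already at the target depth is returned unchanged
  r <- rarefy(m[, 1, drop = FALSE], depth = 14, reps = 5, seed = 1)
  expect_equal(r[, 1], m[, 1])

  # single repetition: every column sums to the depth exactly
  r1 <- rarefy(m, depth = 10, reps = 1, seed = 2)
  expect_true(all(colSums(r1) == 10))
  expect_true(all(r1 <= m))

  # shallow samples are dropped (depth decides, not the seed)
  expect_message(r2 <- rarefy(m, depth = 20, reps = 1, seed = 3), "dropping")
  expect_equal(colnames(r2), "s2")
  expect_message(r3 <- rarefy(m, depth = 20, reps = 1, seed = 99), "dropping")
  expect_equal(colnames(r3), "s2")

  # reproducible under a fixed seed
  expect_identical(rarefy(m, 10, reps = 3, seed = 7),
                   rarefy(m, 10, reps = 3, seed = 7))

  # averaged counts converge to the hypergeometric mean depth * y_g / N
  y <- c(8, 4, 2)
  ravg <- rarefy(matrix(y, 3, dimnames = list(paste0("t", 1:3), "s1")),
                 depth = 7, reps = 2000, seed = 11)
  expected <- 7 * y / sum(y)
  per_rep_var <- 7 * (y / 14) * (1 - y / 14) * (14 - 7) / (14 - 1)
  se <- sqrt(per_rep_var / 2000)
  expect_true(all(abs(ravg[, 1] - expected) < 4 * se))
})

test_that("depth candidates report minimum and second minimum", {
  m <- matrix(c(5, 8, 2, 1, 40, 60), 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  cand <- rarefaction_depth_candidates(m)
  expect_equal(cand$depth, c(3, 13))
  expect_equal(cand$samples_retained, c(3, 2))
})

test_that("taxonomic aggregation sums counts and preserves column sums", {
  set.seed(29)
  m <- matrix(rpois(20, 10), 5, 4,
              dimnames = list(paste0("otu", 1:5), paste0("s", 1:4)))
  # identity map returns the input
  id <- setNames(rownames(m), rownames(m))
  expect_equal(unname(aggregate_taxa(m, id)), unname(m))

  map <- c(otu1 = "P1", otu2 = "P1", otu3 = "P2")  # otu4, otu5 unmapped
  agg <- aggregate_taxa(m, map)
  expect_equal(rownames(agg), c("P1", "P2", "unclassified"))
  expect_equal(agg["P1", ], m["otu1", ] + m["otu2", ])
  expect_equal(colSums(agg), colSums(m))

  # data-frame form of the map behaves identically
  agg2 <- aggregate_taxa(m, data.frame(taxon = names(map), label = map))
  expect_equal(agg, agg2)
})
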