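test_that("BW statistic matches hand-computed values", {
  # classes (1,2,3) vs (4,5,6): numerator 3(2-3.5)^2 + 3(5-3.5)^2 = 13.5,
  # denominator = total SS about 3.5 = 17.5
  x <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  lab <- rep(c("a", "b"), each = 3)
  expect_equal(bw_statistic(x, lab, 1), 13.5 / 17.5, tolerance = 1e-12)
  expect_equal(bw_statistic(x, lab, 1), oracle_bw(x, lab, 1), tolerance = 1e-12)
})

test_that("degenerate genes score zero", {
  x <- rbind(const = rep(5, 8),
             balanced = c(1, 3, 0, 4, 2, 2, 1, 3))
  lab <- rep(c("a", "b"), each = 4)
  expect_identical(bw_statistic(x, lab, 1), 0)       # constant gene
  # class means equal the grand mean -> zero numerator
  x2 <- rbind(g = c(1, 3, 0, 4))
  lab2 <- c("a", "a", "b", "b")
  expect_identical(bw_statistic(x2, lab2, 1), 0)
})

test_that("vectorized scores equal the scalar oracle gene by gene", {
  set.seed(31)
  x <- matrix(rpois(50 * 40, 8), 50, 40)
  lab <- sample(rep(c("a", "b"), each = 20))
  scores <- select_top_genes(x, lab, p = 50, scale = "raw")$bw_scores
  for (j in seq_len(50))
    expect_equal(scores[j], oracle_bw(x, lab, j), tolerance = 1e-10)
  # three classes, unbalanced
  lab3 <- sample(rep(c("a", "b", "c"), times = c(10, 12, 18)))
  scores3 <- select_top_genes(x, lab3, p = 50, scale = "raw")$bw_scores
  for (j in seq(1, 50, by = 7))
    expect_equal(scores3[j], oracle_bw(x, lab3, j), tolerance = 1e-10)
})

test_that("the within-class denominator option gives the Dudoit-style ratio", {
  set.seed(8)
  x <- matrix(rpois(20 * 30, 6), 20, 30)
  lab <- rep(c("a", "b", "c"), each = 10)
  for (j in c(1, 5, 20)) {
    expect_equal(bw_statistic(x, lab, j, within = TRUE),
                 oracle_bw(x, lab, j, within = TRUE), tolerance = 1e-10)
  }
  # within-SS denominator is smaller, so the ratio is at least as large
  expect_gte(bw_statistic(x, lab, 1, within = TRUE), bw_statistic(x, lab, 1))
})

test_that("BW is invariant to permuting cells and to per-gene affine maps", {
  set.seed(14)
  x <- matrix(rpois(15 * 24, 5), 15, 24)
  lab <- rep(c("a", "b"), each = 12)
  perm <- sample(24)
  s0 <- select_top_genes(x, lab, p = 15, scale = "raw")$bw_scores
  s1 <- select_top_genes(x[, perm], lab[perm], p = 15, scale = "raw")$bw_scores
  expect_equal(s0, s1, tolerance = 1e-12)
  # both numerator and denominator subtract the grand mean, so adding a
  # constant (or rescaling) a gene leaves its score unchanged
  x2 <- x; x2[3, ] <- x2[3, ] + 100
  s2 <- select_top_genes(x2, lab, p = 15, scale = "raw")$bw_scores
  expect_equal(s2[3], s0[3], tolerance = 1e-9)
  x3 <- x; x3[3, ] <- x3[3, ] * 7
  s3 <- select_top_genes(x3, lab, p = 15, scale = "raw")$bw_scores
  expect_equal(s3[3], s0[3], tolerance = 1e-9)
})

test_that("selection returns the top-p genes with stable tie-breaking", {
  set.seed(9)
  x <- matrix(rpois(50 * 40, 10), 50, 40)
  lab <- rep(c("a", "b"), each = 20)
  rk <- select_top_genes(x, lab, p = 10, scale = "raw")
  brute <- vapply(1:50, function(j) oracle_bw(x, lab, j), numeric(1))
  expect_setequal(rk$selected, order(-brute)[1:10])
  expect_true(all(diff(rk$bw_scores[rk$order]) <= 1e-15))
  # p = g: a full permutation
  rk_all <- select_top_genes(x, lab, p = 50, scale = "raw")
  expect_setequal(rk_all$selected, 1:50)
  # ties broken by ascending gene index
  xt <- matrix(2, 4, 6); xt[1, ] <- c(0, 0, 0, 5, 5, 5)
  rkt <- select_top_genes(xt, rep(c("a", "b"), each = 3), p = 4, scale = "raw")
  expect_identical(rkt$order, c(1L, 2L, 3L, 4L))
})

test_that("a single discriminating gene ranks first", {
  x <- matrix(3, 20, 10)
  set.seed(2); x[] <- rpois(200, 3)
  x[7, ] <- rep(c(0, 50), each = 5)
  lab <- rep(c("a", "b"), each = 5)
  rk <- select_top_genes(x, lab, p = 3, scale = "raw")
  expect_identical(rk$selected[1], 7L)
})

test_that("selection rejects invalid p and single-class labels", {
  x <- matrix(1:20, 4, 5)
  expect_error(select_top_genes(x, rep(c("a", "b"), c(2, 3)), p = 5), "p must be")
  expect_error(select_top_genes(x, rep("a", 5), p = 2), "classes")
})

test_that("preprocessing normalizes library size and log-transforms", {
  counts <- matrix(c(10L, 0L, 30L, 20L, 0L, 60L), 3, 2)
  out <- preprocess_counts(counts)
  # second cell has twice the depth; after normalization profiles match
  expect_equal(out[, 1], out[, 2], tolerance = 1e-12)
  expect_equal(exp(out[1, 1]) - 1, 10 / (40 / 60), tolerance = 1e-12)
  # all-zero cells pass through untouched
  counts0 <- cbind(counts, 0L)
  expect_true(all(preprocess_counts(counts0)[, 3] == 0))
})
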