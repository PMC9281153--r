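test_that("simulated counts are non-negative integers with consistent metadata", {
  cfg <- sim_config(n_per_class = c(25, 35), n_genes = 80, de_prop = 0.3,
                    p_zero = 0.15, seed = 7)
  sim <- simulate_counts(cfg)
  expect_identical(dim(sim$counts), c(80L, 60L))
  expect_true(all(sim$counts >= 0))
  expect_identical(storage.mode(sim$counts), "integer")
  expect_identical(length(sim$labels), 60L)
  expect_identical(as.integer(table(sim$labels)), c(25L, 35L))
  expect_identical(length(rownames(sim$counts)), 80L)
})

test_that("the number of DE genes is exactly ceiling(DE * g)", {
  for (case in list(c(g = 100, de = 0.5, exp = 50),
                    c(g = 100, de = 0.333, exp = 34),
                    c(g = 73, de = 0.2, exp = 15),
                    c(g = 50, de = 0, exp = 0),
                    c(g = 50, de = 1, exp = 50))) {
    sim <- simulate_counts(sim_config(n_per_class = c(5, 5),
                                      n_genes = case["g"],
                                      de_prop = case["de"], seed = 1))
    expect_identical(length(sim$de_genes), as.integer(case["exp"]))
    expect_true(all(sim$de_genes >= 1 & sim$de_genes <= case["g"]))
  }
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(n_per_class = c(20, 20), n_genes = 50, de_prop = 0.4,
                    p_zero = 0.3, seed = 123)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$de_genes, s2$de_genes)
  cfg2 <- cfg; cfg2$seed <- 124L
  expect_false(identical(simulate_counts(cfg2)$counts, s1$counts))
})

test_that("the excess-zero mask hits close to p_zero of the entries", {
  # compare zero rates with and without the mask under the same seed;
  # the implied mask rate (z1 - z0) / (1 - z0) estimates p_zero
  base <- sim_config(n_per_class = c(250, 250), n_genes = 100,
                     de_prop = 0.5, p_zero = 0, seed = 99)
  masked <- base; masked$p_zero <- 0.2
  z0 <- mean(simulate_counts(base)$counts == 0)
  z1 <- mean(simulate_counts(masked)$counts == 0)
  pz_hat <- (z1 - z0) / (1 - z0)
  n_eff <- 100 * 500 * (1 - z0)
  se <- sqrt(0.2 * 0.8 / n_eff)
  expect_lt(abs(pz_hat - 0.2), 3 * se)
})

test_that("the zero fraction is monotone in p_zero on average", {
  mean_zero <- function(pz) {
    mean(vapply(1:20, function(s) {
      cfg <- sim_config(n_per_class = c(20, 20), n_genes = 50,
                        de_prop = 0.3, p_zero = pz, seed = 1000 + s)
      mean(simulate_counts(cfg)$counts == 0)
    }, numeric(1)))
  }
  zf <- vapply(c(0, 0.2, 0.4, 0.6), mean_zero, numeric(1))
  expect_true(all(diff(zf) > 0))
})

test_that("with DE = 0 the classes are exchangeable (uniform p-values)", {
  cfg <- sim_config(n_per_class = c(100, 100), n_genes = 200, de_prop = 0,
                    p_zero = 0.1, seed = 5)
  sim <- simulate_counts(cfg)
  x <- preprocess_counts(sim$counts)
  pvals <- apply(x, 1, function(v)
    stats::t.test(v[sim$labels == "class1"], v[sim$labels == "class2"])$p.value)
  # under the null about 5% of genes reach p < 0.05
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
  expect_gt(mean(pvals), 0.4)
})

test_that("study grids follow the factorial designs", {
  g1 <- make_study_grid(1)
  expect_length(g1, 4 * 9)
  expect_true(all(vapply(g1, function(c) c$de_prop == 0.5, logical(1))))
  expect_true(all(vapply(g1, function(c) c$p_zero == 0.2, logical(1))))
  expect_setequal(unique(vapply(g1, function(c) c$n_genes, integer(1))),
                  c(100L, 200L, 300L, 400L))
  expect_true(all(vapply(g1, function(c) c$n_classes == 2L, logical(1))))

  g3 <- make_study_grid(3)
  expect_true(all(vapply(g3, function(c) c$de_prop == 0.4, logical(1))))
  expect_setequal(unique(vapply(g3, function(c) c$p_zero, numeric(1))),
                  seq(0.1, 0.6, by = 0.1))

  g5 <- make_study_grid(5)
  expect_true(all(vapply(g5, function(c) c$n_classes == 3L, logical(1))))
  expect_setequal(unique(vapply(g5, function(c) attr(c, "n"), integer(1))),
                  c(300L, 400L, 500L, 600L))
  # a grid config for n generates 2n cells (train n + test n)
  expect_identical(sum(g5[[1]]$n_per_class), 2L * attr(g5[[1]], "n"))

  expect_error(make_study_grid(7), "study_id")
  expect_identical(attr(make_study_grid(2, scale_factor = 1), "replicates"),
                   1000L)
})

test_that("stratified splits are balanced, seeded and guarded", {
  sim <- tiny_sim(n_per_class = c(100, 100), seed = 11)
  sp <- split_train_test(sim$counts, sim$labels, 100, seed = 3)
  expect_identical(as.integer(table(sp$train$labels)), c(50L, 50L))
  expect_identical(as.integer(table(sp$test$labels)), c(50L, 50L))
  expect_identical(ncol(sp$train$counts), 100L)
  # disjoint and exhaustive
  expect_length(intersect(colnames(sp$train$counts), colnames(sp$test$counts)), 0)
  expect_setequal(c(colnames(sp$train$counts), colnames(sp$test$counts)),
                  colnames(sim$counts))
  # same seed -> identical partition
  sp2 <- split_train_test(sim$counts, sim$labels, 100, seed = 3)
  expect_identical(sp, sp2)
  # unbalanced proportions follow largest remainders
  sim2 <- tiny_sim(n_per_class = c(30, 90), seed = 12)
  sp3 <- split_train_test(sim2$counts, sim2$labels, 40, seed = 1)
  expect_identical(as.integer(table(sp3$train$labels)), c(10L, 30L))
})

test_that("splits that empty a class are rejected by name", {
  counts <- matrix(1L, 5, 6, dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  labels <- factor(c("a", "a", "a", "a", "a", "rare"))
  expect_error(split_train_test(counts, labels, 5, seed = 1), "rare")
  expect_error(split_train_test(counts, labels, 1, seed = 1), "rare")
  expect_error(split_train_test(counts, labels, 6, seed = 1), "n_train")
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_per_class = c(10), n_genes = 5), "classes")
  expect_error(sim_config(n_per_class = c(10, 0)), ">= 1")
  expect_error(sim_config(n_per_class = c(5, 5), de_prop = 1.2), "de_prop")
  expect_error(sim_config(n_per_class = c(5, 5), p_zero = -0.1), "p_zero")
  expect_error(sim_config(n_per_class = c(5, 5), n_genes = 0), "n_genes")
})
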