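test_that("misclassification rate is the fraction of wrong calls", {
  expect_identical(misclassification_rate(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(misclassification_rate(c(1, 1), c(2, 2)), 1)
  expect_equal(misclassification_rate(c(1, 2, 1, 1, 2), c(1, 1, 1, 2, 2)), 0.4)
  expect_identical(misclassification_rate(factor(c("a", "b")), c("a", "b")), 0)
  expect_error(misclassification_rate(1:3, 1:4), "length")
})

test_that("binary AUC matches hand-worked and degenerate cases", {
  probs <- cbind(1 - c(0.1, 0.4, 0.35, 0.8), c(0.1, 0.4, 0.35, 0.8))
  colnames(probs) <- c("neg", "pos")
  truth <- c("neg", "neg", "pos", "pos")
  expect_equal(auc_score(probs, truth)$per_class[["pos"]], 0.75)
  # perfectly separating scores
  sep <- cbind(a = c(0.9, 0.8, 0.1, 0.2), b = c(0.1, 0.2, 0.9, 0.8))
  expect_equal(auc_score(sep, c("a", "a", "b", "b"))$macro, 1)
  # identical scores: everything ties at 1/2
  flat <- matrix(0.5, 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(auc_score(flat, rep(c("a", "b"), 3))$macro, 0.5)
  expect_error(auc_score(sep, rep("a", 4)), "two classes")
})

test_that("rank-based AUC equals exhaustive pairwise concordance, ties included", {
  set.seed(55)
  for (case in 1:200) {
    n <- sample(4:30, 1)
    # discrete scores generate plenty of ties
    scores <- sample(seq(0, 1, by = 0.125), n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(pos) == 0 || sum(pos) == n) next
    probs <- cbind(neg = 1 - scores, pos = scores)
    truth <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    expect_equal(auc_score(probs, truth)$per_class[["pos"]],
                 oracle_auc(scores, pos), tolerance = 1e-12)
  }
})

test_that("rank-based AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  for (k in 1:10) {
    scores <- runif(40)
    truth <- sample(c("a", "b"), 40, replace = TRUE)
    if (length(unique(truth)) < 2) next
    probs <- cbind(a = 1 - scores, b = scores)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c("a", "b"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc_score(probs, truth)$per_class[["b"]], ref,
                 tolerance = 1e-10)
  }
})

test_that("macro AUC averages one-vs-rest class AUCs", {
  set.seed(77)
  n <- 30
  probs <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("x", "y", "z")))
  probs <- probs / rowSums(probs)
  truth <- sample(c("x", "y", "z"), n, replace = TRUE)
  res <- auc_score(probs, truth)
  manual <- vapply(c("x", "y", "z"), function(cl)
    oracle_auc(probs[, cl], truth == cl), numeric(1))
  expect_equal(res$per_class, manual, tolerance = 1e-12)
  expect_equal(res$macro, mean(manual), tolerance = 1e-12)
})

test_that("evaluation reports are internally consistent", {
  sim <- tiny_sim(n_per_class = c(40, 40), de = 0.8, seed = 21)
  sp <- split_train_test(sim$counts, sim$labels, 40, seed = 2)
  rk <- select_top_genes(sp$train$counts, sp$train$labels, p = 20)
  m <- train_model(sp$train$counts, sp$train$labels, rk,
                   tiny_train_config(epochs = 5, seed = 3))
  ev <- evaluate_model(m, sp$test$counts, sp$test$labels)
  expect_identical(ev$n_test, 40L)
  expect_equal(rowSums(ev$confusion),
               as.numeric(table(sp$test$labels)), ignore_attr = TRUE)
  expect_equal(ev$misclassification_rate,
               1 - sum(diag(ev$confusion)) / ev$n_test, tolerance = 1e-12)
  expect_equal(ev$misclassification_rate + ev$accuracy, 1, tolerance = 1e-12)
  expect_true(all(ev$probabilities >= 0 & ev$probabilities <= 1))
  expect_equal(unname(colSums(ev$probabilities)), rep(1, 40), tolerance = 1e-6)
})

test_that("the study harness records replicates deterministically", {
  cfg <- tiny_train_config(epochs = 2, seed = 1)
  st <- run_simulation_study(2, replicates = 2, p_features = 30, config = cfg,
                             base_seed = 5, subset = list(de = 0.2, n = 200))
  expect_identical(nrow(st$results), 2L)
  expect_identical(unique(st$results$de), 0.2)
  expect_identical(unique(st$results$n), 200L)
  expect_true(all(st$results$misclassification >= 0 &
                  st$results$misclassification <= 1))
  expect_identical(nrow(st$summary), 1L)
  expect_gte(st$summary$mean_misclassification,
             min(st$results$misclassification))
  st2 <- run_simulation_study(2, replicates = 2, p_features = 30, config = cfg,
                              base_seed = 5, subset = list(de = 0.2, n = 200))
  expect_identical(st$results, st2$results)
  expect_error(run_simulation_study(2, replicates = 0), "replicates")
  expect_error(run_simulation_study(2, replicates = 1, subset = list(n = 1)),
               "grid")
})

test_that("repeated splits reproduce under a fixed seed and reject bad input", {
  sim <- tiny_sim(n_per_class = c(30, 30), seed = 13)
  cfg <- tiny_train_config(epochs = 2, seed = 1)
  r1 <- run_repeated_splits(sim$counts, sim$labels, 30, repetitions = 1,
                            p_features = 20, config = cfg, base_seed = 9)
  r2 <- run_repeated_splits(sim$counts, sim$labels, 30, repetitions = 1,
                            p_features = 20, config = cfg, base_seed = 9)
  expect_identical(r1$reports[[1]], r2$reports[[1]])
  expect_identical(r1$results, r2$results)
  expect_error(run_repeated_splits(sim$counts, sim$labels, 60,
                                   repetitions = 1, config = cfg), "n_train")
})
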