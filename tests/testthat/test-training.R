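test_that("cross-entropy matches closed forms and the oracle", {
  perfect <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy_loss(perfect, 1:3), 0)
  uniform <- matrix(1 / 4, 5, 4)
  expect_equal(cross_entropy_loss(uniform, rep(2, 5)), log(4), tolerance = 1e-12)
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(cross_entropy_loss(probs, c(1, 2)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_equal(cross_entropy_loss(probs, c(1, 2)),
               oracle_cross_entropy(probs, c(1, 2)), tolerance = 1e-12)
  expect_error(cross_entropy_loss(probs[0, , drop = FALSE], integer(0)),
               "at least one")
})

test_that("the decay schedule hits its closed-form landmarks", {
  sch <- lr_schedule(0.005, 0.001, total_steps = 1000)
  expect_identical(decayed_learning_rate(sch, 0), 0.005)
  expect_equal(decayed_learning_rate(sch, 1000), 0.001, tolerance = 1e-12)
  expect_equal(decayed_learning_rate(sch, 500), sqrt(0.005 * 0.001),
               tolerance = 1e-12)
  # clamped below at min_lr past the end
  expect_identical(decayed_learning_rate(sch, 5000), 0.001)
  for (s in c(0, 17, 311, 999))
    expect_equal(decayed_learning_rate(sch, s),
                 oracle_lr(0.005, 0.001, 1000, s), tolerance = 1e-15)
  expect_error(decayed_learning_rate(sch, -1), "non-negative")
  expect_error(lr_schedule(0.001, 0.005, 10), "min_lr")
})

test_that("gradient clipping rescales by the global norm only above threshold", {
  g <- list(a = c(1, 1), b = sqrt(2))     # global norm 2
  expect_identical(clip_gradients(g, 5), g)
  g2 <- list(v = c(3, 4))                 # norm exactly at the threshold
  expect_identical(clip_gradients(g2, 5), g2)
  g3 <- list(v = c(6, 8))                 # norm 10 -> rescale by 1/2
  expect_equal(clip_gradients(g3, 5)$v, c(3, 4), tolerance = 1e-12)
  # multi-array: norm computed jointly
  g4 <- list(m = matrix(c(2, 0, 0, 2), 2), v = 1)   # norm 3
  expect_equal(clip_gradients(g4, 1.5),
               oracle_clip(g4, 1.5), tolerance = 1e-12)
  expect_error(clip_gradients(g, -1), "positive")
})

test_that("the SGD update is plain theta - eta * grad", {
  par <- list(w = matrix(c(1, 2, 3, 4), 2), b = c(1, 1))
  zero <- list(w = matrix(0, 2, 2), b = c(0, 0))
  expect_identical(mbgd_update(par, zero, 0.1), par)
  g <- list(w = matrix(1, 2, 2), b = c(2, 2))
  expect_identical(mbgd_update(par, g, 0), par)
  upd <- mbgd_update(list(theta = 1), list(theta = 2), 0.1)
  expect_equal(upd$theta, 0.8, tolerance = 1e-15)
  expect_error(mbgd_update(par, list(w = matrix(0, 3, 3), b = c(0, 0)), 0.1),
               "shape")
})

test_that("zero epochs return the seeded initialization bit-exactly", {
  sim <- tiny_sim()
  rk <- select_top_genes(sim$counts, sim$labels, p = 20)
  cfg <- tiny_train_config(epochs = 0, seed = 5)
  m <- train_model(sim$counts, sim$labels, rk, cfg)
  ref <- init_params(p = 20, n_classes = 2, hidden_size = 8, fc1_dim = 8,
                     seed = 5)
  expect_identical(m$params, ref)
  expect_null(m$report)
})

test_that("the first recorded loss starts near log K", {
  sim <- tiny_sim(n_per_class = c(40, 40))
  rk <- select_top_genes(sim$counts, sim$labels, p = 20)
  m <- train_model(sim$counts, sim$labels, rk, tiny_train_config(seed = 2))
  expect_lt(abs(m$report$log$loss[1] - log(2)), 0.1 * log(2))
})

test_that("training is reproducible and its learning rates follow the schedule", {
  sim <- tiny_sim()
  rk <- select_top_genes(sim$counts, sim$labels, p = 15)
  cfg <- tiny_train_config(seed = 8)
  m1 <- train_model(sim$counts, sim$labels, rk, cfg)
  m2 <- train_model(sim$counts, sim$labels, rk, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$report$log, m2$report$log)
  sch <- m1$report$schedule
  expect_equal(m1$report$log$lr,
               decayed_learning_rate(sch, m1$report$log$step),
               tolerance = 1e-15)
  expect_identical(m1$report$log$lr[1], cfg$max_lr)
  expect_true(all(diff(m1$report$log$lr) <= 0))
})

test_that("training is invariant to clipping when gradients stay under the threshold", {
  sim <- tiny_sim()
  rk <- select_top_genes(sim$counts, sim$labels, p = 15)
  m_clip <- train_model(sim$counts, sim$labels, rk,
                        tiny_train_config(seed = 4, grad_clip = 5))
  m_wide <- train_model(sim$counts, sim$labels, rk,
                        tiny_train_config(seed = 4, grad_clip = 1e9))
  expect_lt(max(m_clip$report$log$grad_norm), 5)
  expect_identical(m_clip$params, m_wide$params)
})

test_that("single-batch mode warns and aborting on NaN is reported", {
  sim <- tiny_sim(n_per_class = c(4, 4))
  rk <- select_top_genes(sim$counts, sim$labels, p = 10)
  expect_warning(train_model(sim$counts, sim$labels, rk,
                             tiny_train_config(epochs = 1, seed = 1)),
                 "single-batch")
})

test_that("analytic gradients agree with finite differences on a tiny model", {
  par <- init_params(p = 4, n_classes = 2, hidden_size = 3, fc1_dim = 3,
                     fc2_zero = FALSE, seed = 19)
  set.seed(19)
  X <- matrix(runif(4 * 6), 4, 6)
  y <- rep(1:2, 3)
  res <- gradient_check(par, X, y, tolerance = 1e-4)
  expect_true(res$pass)
  expect_lt(res$max_rel_err, 1e-4)
  # the dropout path, with masks regenerated from the same seed
  res_drop <- gradient_check(par, X, y, tolerance = 1e-4, keep_prob = 0.6,
                             seed = 7)
  expect_true(res_drop$pass)
})

test_that("a corrupted gradient is caught and named", {
  par <- init_params(p = 3, n_classes = 2, hidden_size = 2, fc1_dim = 2,
                     fc2_zero = FALSE, seed = 23)
  set.seed(23)
  X <- matrix(runif(9), 3, 3)
  y <- c(1, 2, 1)
  good <- scDLC:::.cpp_loss_grads(unclass(par), X, y, 1, FALSE, FALSE, FALSE,
                                  0, FALSE)$grads
  bad <- good
  bad$lstm2_Wo[1, 1] <- bad$lstm2_Wo[1, 1] + 0.05
  res <- gradient_check(par, X, y, gradients = bad)
  expect_false(res$pass)
  expect_identical(res$worst_param$name, "lstm2_Wo")
  expect_error(gradient_check(par, X[, 0, drop = FALSE], integer(0)),
               "empty")
})
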