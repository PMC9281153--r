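# Independent scalar reference implementations ("oracles") used to verify
# the package's vectorized/compiled paths. These are deliberately written
# as plain loops over the defining formulas.

oracle_bw <- function(x, labels, j, within = FALSE) {
  labels <- as.factor(labels)
  lv <- levels(labels)
  K <- length(lv)
  class_means <- numeric(K)
  for (k in seq_len(K))
    class_means[k] <- mean(x[j, labels == lv[k]])
  grand <- mean(class_means)
  num <- 0
  den <- 0
  for (k in seq_len(K)) {
    idx <- which(labels == lv[k])
    for (i in idx) {
      num <- num + (class_means[k] - grand)^2
      den <- den + if (within) (x[j, i] - class_means[k])^2
                   else (x[j, i] - grand)^2
    }
  }
  if (den > 0) unname(num / den) else 0
}

oracle_fc_relu <- function(x, W, b) {
  a <- numeric(nrow(W))
  for (r in seq_len(nrow(W))) {
    acc <- b[r]
    for (cc in seq_len(ncol(W))) acc <- acc + W[r, cc] * x[cc]
    a[r] <- max(0, acc)
  }
  a
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

oracle_lstm_step <- function(x_t, h_prev, C_prev, W_f, W_i, W_C, W_o,
                             b_f, b_i, b_C, b_o) {
  u <- c(h_prev, x_t)
  H <- length(h_prev)
  f <- i <- Ct <- o <- C_new <- h_new <- numeric(H)
  for (r in seq_len(H)) {
    f[r] <- oracle_sigmoid(sum(W_f[r, ] * u) + b_f[r])
    i[r] <- oracle_sigmoid(sum(W_i[r, ] * u) + b_i[r])
    Ct[r] <- tanh(sum(W_C[r, ] * u) + b_C[r])
    C_new[r] <- f[r] * C_prev[r] + i[r] * Ct[r]
    o[r] <- oracle_sigmoid(sum(W_o[r, ] * u) + b_o[r])
    h_new[r] <- o[r] * tanh(C_new[r])
  }
  list(h = h_new, C = C_new, f = f, i = i, o = o, Ct = Ct)
}

oracle_softmax <- function(y) exp(y) / sum(exp(y))

oracle_cross_entropy <- function(probs, y) {
  total <- 0
  for (i in seq_along(y)) total <- total - log(max(probs[i, y[i]], 1e-12))
  total / length(y)
}

oracle_auc <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (scores[a] > scores[b]) 1 else if (scores[a] == scores[b]) 0.5 else 0
  s / (length(pos) * length(neg))
}

oracle_lr <- function(max_lr, min_lr, total_steps, s) {
  r <- log(max_lr / min_lr) / total_steps
  max(min_lr, max_lr * exp(-r * s))
}

oracle_clip <- function(gradients, threshold) {
  norm <- sqrt(sum(unlist(lapply(gradients, function(g) sum(g^2)))))
  if (norm > threshold) lapply(gradients, function(g) g * threshold / norm)
  else gradients
}

# Scalar composition of the whole network (no dropout): fc1 relu embedding
# per timestep -> lstm1 -> lstm2 -> fc2 on final h of lstm2 -> softmax.
oracle_forward <- function(x_seq, params) {
  H1 <- length(params$fc1_b)
  H <- length(params$lstm1_bf)
  h1 <- C1 <- rep(0, H)
  h2 <- C2 <- rep(0, H)
  for (t in seq_along(x_seq)) {
    a <- oracle_fc_relu(x_seq[t], matrix(params$fc1_W, ncol = 1), params$fc1_b)
    s1 <- oracle_lstm_step(a, h1, C1, params$lstm1_Wf, params$lstm1_Wi,
                           params$lstm1_Wc, params$lstm1_Wo,
                           params$lstm1_bf, params$lstm1_bi,
                           params$lstm1_bc, params$lstm1_bo)
    h1 <- s1$h; C1 <- s1$C
    s2 <- oracle_lstm_step(h1, h2, C2, params$lstm2_Wf, params$lstm2_Wi,
                           params$lstm2_Wc, params$lstm2_Wo,
                           params$lstm2_bf, params$lstm2_bi,
                           params$lstm2_bc, params$lstm2_bo)
    h2 <- s2$h; C2 <- s2$C
  }
  logits <- as.numeric(params$fc2_W %*% h2 + params$fc2_b)
  oracle_softmax(logits)
}

# Small, quick simulated two-class dataset for pipeline-level tests.
tiny_sim <- function(n_per_class = c(30, 30), g = 40, de = 0.5,
                     p_zero = 0.1, seed = 42) {
  simulate_counts(sim_config(n_per_class = n_per_class, n_genes = g,
                             de_prop = de, p_zero = p_zero, seed = seed))
}

# Reduced training configuration keeping unit tests fast.
tiny_train_config <- function(...) {
  args <- modifyList(list(epochs = 3, hidden_size = 8, fc1_dim = 8),
                     list(...))
  do.call(train_config, args)
}
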