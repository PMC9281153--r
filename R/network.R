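#' Fully connected layer with ReLU activation
#'
#' Computes `a = max(0, W x + b)` elementwise.
#'
#' @param x Input vector.
#' @param W Weight matrix (rows = output units).
#' @param b Bias vector, one per output unit.
#' @return The activation vector.
#' @export
fc_relu <- function(x, W, b) {
  if (ncol(W) != length(x))
    stopf("W has %d columns but x has length %d", ncol(W), length(x))
  if (nrow(W) != length(b))
    stopf("W has %d rows but b has length %d", nrow(W), length(b))
  pmax(0, as.numeric(W %*% x + b))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' One LSTM recurrence step
#'
#' Applies the gated recurrence of a long short-term memory cell to one
#' timestep. With `u = c(h_prev, x_t)` (previous hidden state concatenated
#' with the current input):
#' \deqn{f_t = \sigma(W_f u + b_f),\; i_t = \sigma(W_i u + b_i),\;
#'  \tilde C_t = \tanh(W_C u + b_C),}
#' \deqn{C_t = f_t * C_{t-1} + i_t * \tilde C_t,\;
#'  o_t = \sigma(W_o u + b_o),\; h_t = o_t * \tanh(C_t),}
#' where `*` is elementwise multiplication.
#'
#' @param x_t Input vector at the current timestep.
#' @param state List with `h` (hidden state) and `C` (cell state) from the
#'   previous timestep.
#' @param params List with weight matrices `W_f`, `W_i`, `W_C`, `W_o`
#'   (each `hidden x (hidden + input)`) and bias vectors `b_f`, `b_i`,
#'   `b_C`, `b_o`.
#' @return List with the new `h` and `C`.
#' @export
lstm_step <- function(x_t, state, params) {
  H <- length(state$h)
  u <- c(state$h, x_t)
  for (nm in c("W_f", "W_i", "W_C", "W_o")) {
    W <- params[[nm]]
    if (nrow(W) != H || ncol(W) != length(u))
      stopf("%s must be %d x %d, got %d x %d", nm, H, length(u),
            nrow(W), ncol(W))
  }
  f <- sigmoid(as.numeric(params$W_f %*% u + params$b_f))
  i <- sigmoid(as.numeric(params$W_i %*% u + params$b_i))
  Ct_cand <- tanh(as.numeric(params$W_C %*% u + params$b_C))
  C <- f * state$C + i * Ct_cand
  o <- sigmoid(as.numeric(params$W_o %*% u + params$b_o))
  list(h = o * tanh(C), C = C)
}

#' Softmax probabilities
#'
#' Maps a vector of class scores to a probability vector,
#' `softmax(y)_c = exp(y_c) / sum_j exp(y_j)`, computed with
#' max-subtraction for numerical stability (mathematically identical).
#'
#' @param y Score vector (length >= 1).
#' @return Probability vector summing to 1.
#' @export
softmax_prob <- function(y) {
  if (length(y) == 0) stopf("softmax needs a non-empty score vector")
  e <- exp(y - max(y))
  e / sum(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize network parameters
#'
#' Seeded Glorot-style uniform initialization for all weight matrices;
#' biases start at zero except the forget-gate biases. The forget-gate
#' bias default of 3 starts the forget gates nearly open (sigmoid(3)
#' ~ 0.95), giving the cell state a long initial memory so that genes early
#' in the 100-step input sequence — the strongest, highest-BW genes — can
#' still influence the final-timestep readout; with a bias near 0 the cell
#' state decays with a half-life of a few timesteps and early inputs are
#' unlearnable. The parameter set comprises: `fc1` (shared per-timestep map
#' from the scalar gene expression to a `fc1_dim`-dimensional embedding),
#' two LSTM layers (gate weights on the concatenation `[h, x]`), and `fc2`
#' mapping the final hidden state to one score per class.
#'
#' @param p Number of input genes (sequence length).
#' @param n_classes Number of classes M.
#' @param hidden_size LSTM hidden state size.
#' @param fc1_dim Output dimension of the first fully connected layer.
#' @param forget_bias Initial value of the forget-gate biases.
#' @param fc2_zero Start the output layer at zero. The network then opens
#'   at the exactly uniform prediction (first loss = log M) and the output
#'   layer first learns a linear readout of the initial recurrent features
#'   before gradients flow back into the LSTM; empirically this stabilizes
#'   the early phase of the fixed learning-rate recipe.
#' @param input_mode `"per_gene"` (default): each ranked gene is one
#'   timestep and fc1 is a shared ReLU embedding of its scalar expression
#'   (sequence length p). `"dense"`: fc1 maps the whole p-gene expression
#'   vector to `seq_len * fc1_dim` values reshaped into a `seq_len`-step
#'   sequence (an alternative reading of "map the gene sequence to a larger
#'   dimension").
#' @param seq_len Number of LSTM timesteps in `"dense"` mode.
#' @param seed Integer seed.
#' @return Named list of parameter arrays, class `scdlc_params`.
#' @export
init_params <- function(p, n_classes, hidden_size = 64,
                        fc1_dim = hidden_size, forget_bias = 3,
                        fc2_zero = TRUE,
                        input_mode = c("per_gene", "dense"),
                        seq_len = 2, seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (n_classes < 2) stopf("need at least 2 classes")
  set.seed(seed)
  H <- hidden_size; H1 <- fc1_dim; M <- n_classes
  mk_layer <- function(D) {
    l <- list()
    for (gate in c("f", "i", "c", "o")) {
      l[[paste0("W", gate)]] <- glorot(H, H + D)
      l[[paste0("b", gate)]] <- if (gate == "f") rep(forget_bias, H) else rep(0, H)
    }
    l
  }
  params <- if (input_mode == "dense")
    list(fc1_W = glorot(H1 * seq_len, p), fc1_b = rep(0, H1 * seq_len))
  else
    list(fc1_W = glorot(H1, 1), fc1_b = rep(0, H1))
  l1 <- mk_layer(H1); l2 <- mk_layer(H)
  for (nm in names(l1)) params[[paste0("lstm1_", nm)]] <- l1[[nm]]
  for (nm in names(l2)) params[[paste0("lstm2_", nm)]] <- l2[[nm]]
  params$fc2_W <- glorot(M, H)
  if (isTRUE(fc2_zero)) params$fc2_W[] <- 0
  params$fc2_b <- rep(0, M)
  structure(params, p = as.integer(p), hidden_size = as.integer(H),
            fc1_dim = as.integer(H1), n_classes = as.integer(M),
            input_mode = input_mode,
            seq_len = if (input_mode == "dense") as.integer(seq_len)
                      else as.integer(p),
            class = "scdlc_params")
}

#' @export
print.scdlc_params <- function(x, ...) {
  n_par <- sum(vapply(unclass(x), length, integer(1)))
  cat(sprintf(
    "scDLC parameters: p=%d genes, hidden=%d, fc1_dim=%d, %d classes, %d trainable values\n",
    attr(x, "p"), attr(x, "hidden_size"), attr(x, "fc1_dim"),
    attr(x, "n_classes"), n_par))
  invisible(x)
}

#' Forward pass of the scDLC network
#'
#' Runs one or more expression vectors (already ordered by descending BW
#' score) through the network: each gene is one timestep; the shared fc1
#' ReLU layer embeds the scalar expression into `fc1_dim` dimensions; two
#' stacked LSTM layers process the sequence; fc2 maps the final-timestep
#' hidden state of the second layer to class scores; softmax converts the
#' scores to probabilities. With `training = TRUE`, inverted dropout with
#' the given keep probability is applied to the LSTM outputs (only);
#' evaluation (`training = FALSE`) is deterministic.
#'
#' @param expression Numeric vector of length p, or a p x n matrix (one
#'   column per cell).
#' @param params An `scdlc_params` object.
#' @param keep_prob Dropout keep probability in (0, 1].
#' @param training Apply dropout?
#' @param variational Draw one dropout mask per cell and layer, shared by
#'   all timesteps, instead of a fresh mask per timestep.
#' @param readout_dropout Apply dropout to the second layer's outputs too
#'   (they feed only the fc2 readout); see [train_config()].
#' @param seed Seed for the dropout masks (ignored when not training).
#' @param single Run in single precision (the training default); the
#'   default here is double precision.
#' @return Probability vector over classes (or M x n matrix of column
#'   probability vectors).
#' @export
scdlc_forward <- function(expression, params, keep_prob = 1,
                          training = FALSE, variational = FALSE,
                          readout_dropout = FALSE, seed = 0L,
                          single = FALSE) {
  vec_in <- is.null(dim(expression))
  X <- if (vec_in) matrix(expression, ncol = 1) else as.matrix(expression)
  p <- attr(params, "p")
  if (!is.null(p) && nrow(X) != p)
    stopf("expression has %d genes per cell but the model expects %d",
          nrow(X), p)
  storage.mode(X) <- "double"
  probs <- .cpp_forward(unclass(params), X, keep_prob, training,
                        variational, readout_dropout, as.double(seed), single)
  if (vec_in) as.numeric(probs) else probs
}

#' Predicted class from a probability vector
#'
#' Argmax of the class probabilities; ties are broken by the lowest class
#' index.
#'
#' @param probabilities Probability vector, or an M x n matrix of column
#'   probability vectors.
#' @return Integer class index (or vector of them).
#' @export
predict_class <- function(probabilities) {
  if (is.null(dim(probabilities))) return(which.max(probabilities))
  apply(probabilities, 2, which.max)
}
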