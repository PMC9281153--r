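#' Training configuration
#'
#' Hyperparameters of the mini-batch gradient-descent training recipe. The
#' defaults are the settings used throughout: hidden state size 64, batches
#' of 11 randomly chosen samples, global gradient-norm threshold 5, dropout
#' keep probability 0.3 during training, and a learning rate decaying
#' exponentially from 0.005 down to 0.001 over the course of training.
#'
#' @param hidden_size LSTM hidden state size.
#' @param batch_size Samples per mini-batch.
#' @param grad_clip Global L2-norm threshold for gradient clipping.
#' @param keep_prob Dropout keep probability in (0, 1].
#' @param max_lr Initial (maximum) learning rate.
#' @param min_lr Final (minimum) learning rate; the decay rate is
#'   `log(max_lr / min_lr) / (epochs * n / batch_size)`.
#' @param epochs Number of passes over the training data.
#' @param fc1_dim Output dimension of the first fully connected layer.
#' @param forget_bias Initial forget-gate bias, see [init_params()].
#' @param input_mode,seq_len Input sequence construction, see
#'   [init_params()].
#' @param readout_dropout Also apply dropout to the final-timestep hidden
#'   state that feeds fc2. Off by default: the readout is the only channel
#'   through which class signal reaches the loss, and dropping 70% of it
#'   pins weak-signal runs at the uniform predictor (the optimal logit
#'   scale under mask noise stays near zero, so no gradient ever reaches
#'   the recurrent layers).
#' @param standardize Standardize each selected gene to zero mean and unit
#'   variance on the training set (statistics stored in the model and
#'   reapplied at prediction time). Centering removes the large constant
#'   component of log-scale expression so the recurrent input actually
#'   varies between cells; without it the fixed learning-rate recipe
#'   stalls at the uniform prediction.
#' @param precision `"single"` (default, faster) or `"double"`; both run
#'   the same templated code path.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `scdlc_train_config`.
#' @export
train_config <- function(hidden_size = 64, batch_size = 11, grad_clip = 5,
                         keep_prob = 0.3, max_lr = 0.005, min_lr = 0.001,
                         epochs = 100, fc1_dim = hidden_size,
                         forget_bias = 3, standardize = TRUE,
                         input_mode = c("per_gene", "dense"), seq_len = 2,
                         readout_dropout = FALSE,
                         precision = c("single", "double"), seed = 1L) {
  precision <- match.arg(precision)
  input_mode <- match.arg(input_mode)
  if (min_lr <= 0 || min_lr > max_lr)
    stopf("need 0 < min_lr <= max_lr, got min_lr=%g max_lr=%g",
          min_lr, max_lr)
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (keep_prob <= 0 || keep_prob > 1) stopf("keep_prob must be in (0, 1]")
  if (grad_clip <= 0) stopf("grad_clip must be positive")
  if (epochs < 0) stopf("epochs must be non-negative")
  structure(list(hidden_size = as.integer(hidden_size),
                 batch_size = as.integer(batch_size), grad_clip = grad_clip,
                 keep_prob = keep_prob, max_lr = max_lr, min_lr = min_lr,
                 epochs = as.integer(epochs), fc1_dim = as.integer(fc1_dim),
                 forget_bias = forget_bias,
                 standardize = isTRUE(standardize),
                 input_mode = input_mode, seq_len = as.integer(seq_len),
                 readout_dropout = isTRUE(readout_dropout),
                 precision = precision, seed = as.integer(seed)),
            class = "scdlc_train_config")
}

#' @export
print.scdlc_train_config <- function(x, ...) {
  cat(sprintf(
    "scDLC training config: hidden=%d, batch=%d, clip=%g, keep_prob=%g, lr %g -> %g, epochs=%d (%s precision, seed %d)\n",
    x$hidden_size, x$batch_size, x$grad_clip, x$keep_prob, x$max_lr,
    x$min_lr, x$epochs, x$precision, x$seed))
  invisible(x)
}

#' Mean cross-entropy loss
#'
#' `L = -(1/N) sum_i sum_c y_ic log(p_ic)` with one-hot indicators `y_ic`,
#' natural logarithm, and probabilities floored at 1e-12 before the log.
#'
#' @param predicted_probs N x M matrix, one probability row per sample.
#' @param true_labels Length-N integer class indices (1..M) or factor.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(predicted_probs, true_labels) {
  probs <- as.matrix(predicted_probs)
  y <- if (is.factor(true_labels)) as.integer(true_labels)
       else as.integer(true_labels)
  n <- nrow(probs)
  if (n == 0) stopf("cross-entropy needs at least one sample")
  if (length(y) != n)
    stopf("have %d probability rows but %d labels", n, length(y))
  if (any(y < 1 | y > ncol(probs)))
    stopf("labels must index columns 1..%d", ncol(probs))
  p_true <- probs[cbind(seq_len(n), y)]
  -mean(log(pmax(p_true, 1e-12)))
}

#' Exponential learning-rate decay schedule
#'
#' The learning rate at global step `s` is
#' `max(min_lr, max_lr * exp(-r * s))` with decay rate
#' `r = log(max_lr / min_lr) / total_steps`, so the schedule starts at
#' `max_lr` at step 0 and reaches exactly `min_lr` at `s = total_steps`,
#' the geometric mean of the two at the halfway step.
#'
#' @param max_lr,min_lr Learning-rate bounds (0 < min_lr <= max_lr).
#' @param total_steps Total number of parameter updates,
#'   `epochs * n_train / batch_size` (need not be an integer).
#' @return An object of class `scdlc_lr_schedule` with the decay rate `r`.
#' @export
lr_schedule <- function(max_lr = 0.005, min_lr = 0.001, total_steps) {
  if (min_lr <= 0 || min_lr > max_lr)
    stopf("need 0 < min_lr <= max_lr")
  if (total_steps <= 0) stopf("total_steps must be positive")
  structure(list(max_lr = max_lr, min_lr = min_lr,
                 total_steps = total_steps,
                 decay_rate = log(max_lr / min_lr) / total_steps),
            class = "scdlc_lr_schedule")
}

#' Learning rate after decay at a global step
#'
#' @param schedule An [lr_schedule()].
#' @param step Non-negative global step (cumulative update count; it does
#'   not reset between epochs).
#' @return The decayed learning rate.
#' @export
decayed_learning_rate <- function(schedule, step) {
  if (any(step < 0)) stopf("step must be non-negative")
  pmax(schedule$min_lr,
       schedule$max_lr * exp(-schedule$decay_rate * step))
}

#' Global-norm gradient clipping
#'
#' If the L2 norm of the full gradient (over every parameter array jointly)
#' exceeds `threshold`, every gradient is rescaled by
#' `threshold / norm`; otherwise the gradients are returned unchanged.
#'
#' @param gradients Named list of gradient arrays.
#' @param threshold Positive clipping threshold.
#' @return The (possibly rescaled) gradient list.
#' @export
clip_gradients <- function(gradients, threshold) {
  if (threshold <= 0) stopf("threshold must be positive")
  norm <- sqrt(sum(vapply(gradients, function(g) sum(as.numeric(g)^2),
                          numeric(1))))
  if (is.finite(threshold) && norm > threshold)
    gradients <- lapply(gradients, function(g) g * (threshold / norm))
  gradients
}

#' Mini-batch gradient-descent parameter update
#'
#' Plain SGD without momentum: `theta <- theta - eta * dL/dtheta` applied
#' to every trainable array.
#'
#' @param params Named list of parameter arrays.
#' @param gradients Matching named list of gradients.
#' @param learning_rate Step size eta.
#' @return Updated parameter list (attributes preserved).
#' @export
mbgd_update <- function(params, gradients, learning_rate) {
  nms <- names(unclass(params))
  if (!all(nms %in% names(gradients)))
    stopf("gradients missing entries: %s",
          paste(setdiff(nms, names(gradients)), collapse = ", "))
  out <- params
  for (nm in nms) {
    g <- gradients[[nm]]
    if (!identical(dim(out[[nm]]), dim(g)) ||
        length(out[[nm]]) != length(g))
      stopf("shape mismatch for %s", nm)
    out[[nm]] <- out[[nm]] - learning_rate * g
  }
  out
}

#' Train the scDLC classifier
#'
#' Initializes the parameters (seeded), then for each epoch shuffles the
#' training cells, partitions them into mini-batches (a final short batch
#' is trained on, not dropped), and for each batch runs the forward pass
#' with dropout, computes the cross-entropy loss, backpropagates, clips the
#' gradients by global norm and applies the SGD update at the decayed
#' learning rate. The global step is cumulative across epochs.
#'
#' @param train_counts Genes x cells count matrix (training cells only).
#' @param train_labels Training class labels (factor or coercible).
#' @param ranking A [select_top_genes()] ranking computed on the same
#'   training data; its selected genes, in order, are the network input
#'   sequence.
#' @param config A [train_config()].
#' @return An object of class `scdlc_model`: list with `params`
#'   (`scdlc_params`), `report` (per-step loss, learning rate, gradient
#'   norm; final training accuracy), `ranking`, `config`, and `classes`
#'   (level names).
#' @export
train_model <- function(train_counts, train_labels, ranking, config = train_config()) {
  train_labels <- as.factor(train_labels)
  if (nlevels(train_labels) < 2) stopf("training data must contain >= 2 classes")
  X <- ranked_input(train_counts, ranking)
  n <- ncol(X)
  if (length(train_labels) != n)
    stopf("labels length (%d) does not match cell count (%d)",
          length(train_labels), n)
  y <- as.integer(train_labels)
  M <- nlevels(train_labels)
  if (n < config$batch_size)
    warnf("fewer training samples (%d) than one batch (%d); running in single-batch mode",
          n, config$batch_size)
  if (isTRUE(config$standardize)) {
    center <- unname(rowMeans(X))
    scl <- unname(apply(X, 1, sd))
    scl[scl == 0] <- 1
    X <- (X - center) / scl
  } else {
    center <- rep(0, nrow(X)); scl <- rep(1, nrow(X))
  }
  params0 <- init_params(p = ranking$p, n_classes = M,
                         hidden_size = config$hidden_size,
                         fc1_dim = config$fc1_dim,
                         forget_bias = config$forget_bias %||% 3,
                         input_mode = config$input_mode %||% "dense",
                         seq_len = config$seq_len %||% 2,
                         seed = config$seed)
  total_steps <- config$epochs * n / config$batch_size
  if (config$epochs == 0) {
    model <- structure(list(params = params0, report = NULL,
                            ranking = ranking, config = config,
                            center = center, scale = scl,
                            classes = levels(train_labels)),
                       class = "scdlc_model")
    return(model)
  }
  res <- .cpp_train(unclass(params0), X, y,
                    batch_size = config$batch_size, epochs = config$epochs,
                    max_lr = config$max_lr, min_lr = config$min_lr,
                    grad_clip = config$grad_clip,
                    keep_prob = config$keep_prob,
                    variational = isTRUE(config$variational_dropout),
                    drop_readout = isTRUE(config$readout_dropout),
                    total_steps_r = total_steps,
                    seed = as.double(config$seed),
                    single = config$precision == "single")
  params <- res$params
  attributes(params) <- c(attributes(params),
                          attributes(params0)[c("p", "hidden_size",
                                                "fc1_dim", "n_classes",
                                                "class")])
  steps <- as.integer(res$steps)
  log <- data.frame(step = seq_len(steps) - 1L, epoch = res$epoch,
                    lr = res$lr, loss = res$loss, grad_norm = res$grad_norm)
  train_probs <- .cpp_forward(unclass(params), X, 1, FALSE, FALSE, FALSE, 0,
                              config$precision == "single")
  train_acc <- mean(predict_class(train_probs) == y)
  report <- structure(list(
    log = log,
    schedule = lr_schedule(config$max_lr, config$min_lr, total_steps),
    final_train_accuracy = train_acc,
    epochs_run = config$epochs, steps = steps, n_train = n,
    seed = config$seed), class = "scdlc_train_report")
  structure(list(params = params, report = report, ranking = ranking,
                 config = config, center = center, scale = scl,
                 classes = levels(train_labels)),
            class = "scdlc_model")
}

#' @export
print.scdlc_model <- function(x, ...) {
  cat(sprintf("scDLC model: %d classes (%s), p=%d genes\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$ranking$p))
  if (!is.null(x$report))
    cat(sprintf("  trained %d steps over %d epochs; final training accuracy %.3f\n",
                x$report$steps, x$report$epochs_run,
                x$report$final_train_accuracy))
  else cat("  untrained (0 epochs): parameters at their seeded initialization\n")
  invisible(x)
}

#' Class probabilities or predicted classes for new cells
#'
#' @param object A trained `scdlc_model`.
#' @param counts Genes x cells count matrix on the same gene indexing as
#'   the training data.
#' @param type `"class"` for label predictions, `"prob"` for the M x n
#'   probability matrix.
#' @param ... Unused.
#' @export
predict.scdlc_model <- function(object, counts, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- ranked_input(counts, object$ranking)
  if (!is.null(object$center))
    X <- (X - object$center) / object$scale
  n <- ncol(X)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 512))
  probs <- do.call(cbind, lapply(chunks, function(j)
    .cpp_forward(unclass(object$params), X[, j, drop = FALSE], 1, FALSE,
                 FALSE, FALSE, 0, object$config$precision == "single")))
  rownames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[predict_class(probs)], levels = object$classes)
}

#' Finite-difference gradient check
#'
#' Validates the analytic backpropagation gradients against central finite
#' differences of the loss, parameter by parameter. Intended for small
#' networks (at most a few hundred parameters).
#'
#' @param params An `scdlc_params` object (build a tiny one with
#'   [init_params()]).
#' @param X p x B matrix of input sequences (one column per sample).
#' @param y Integer class labels (1..M) for the batch.
#' @param tolerance Maximum accepted relative error.
#' @param eps Finite-difference step.
#' @param keep_prob Dropout keep probability; with a value below 1 the
#'   dropout masks are regenerated identically from `seed` at every loss
#'   evaluation, so the check covers the dropout path too.
#' @param seed Seed for the dropout masks.
#' @param gradients Optional externally supplied analytic gradients to
#'   check instead of the backpropagation output (used for negative
#'   controls).
#' @return List with `pass`, `max_rel_err`, `worst_param` (name and index
#'   of the worst-agreeing parameter), and a per-array table of maximum
#'   relative errors.
#' @export
gradient_check <- function(params, X, y, tolerance = 1e-4, eps = 1e-5,
                           keep_prob = 1, variational = FALSE,
                           drop_readout = TRUE, seed = 0L,
                           gradients = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.integer(y)
  if (ncol(X) == 0 || length(y) == 0) stopf("empty batch")
  training <- keep_prob < 1
  loss_at <- function(p) {
    probs <- .cpp_forward(p, X, keep_prob, training, variational,
                          drop_readout, as.double(seed), FALSE)
    cross_entropy_loss(t(probs), y)
  }
  if (is.null(gradients)) {
    ag <- .cpp_loss_grads(unclass(params), X, y, keep_prob, training,
                          variational, drop_readout, as.double(seed), FALSE)
    gradients <- ag$grads
  }
  plain <- unclass(params)
  max_rel <- 0; worst <- list(name = NA_character_, index = NA_integer_)
  per_param <- numeric(0)
  for (nm in names(plain)) {
    arr <- plain[[nm]]
    worst_here <- 0
    for (k in seq_along(arr)) {
      pp <- plain; pp[[nm]][k] <- arr[k] + eps
      pm <- plain; pm[[nm]][k] <- arr[k] - eps
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      an <- gradients[[nm]][k]
      rel <- abs(fd - an) / max(abs(fd) + abs(an), 1e-6)
      if (rel > worst_here) worst_here <- rel
      if (rel > max_rel) {
        max_rel <- rel
        worst <- list(name = nm, index = k)
      }
    }
    per_param[nm] <- worst_here
  }
  list(pass = max_rel <= tolerance, max_rel_err = max_rel,
       worst_param = worst, tolerance = tolerance, per_param = per_param)
}
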