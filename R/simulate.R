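#' Simulation configuration for synthetic scRNA-seq counts
#'
#' Describes a hierarchical gamma-Poisson count model with log-normal
#' differential-expression (DE) fold changes and excess zeros, the
#' statistical skeleton of the Splatter-style simulators commonly used to
#' calibrate scRNA-seq classifiers. Per-gene base means are drawn from a
#' gamma prior, a random subset of genes receives per-class multiplicative
#' fold changes (log-normal magnitude, fair-coin up/down direction),
#' per-cell library sizes are log-normal, counts are Poisson, and an
#' independent Bernoulli mask zeroes entries with probability `p_zero`
#' ("excess zeros", emulating dropout events).
#'
#' @param n_classes Number of classes K (>= 2).
#' @param n_per_class Integer vector of K per-class cell counts.
#' @param n_genes Number of genes g.
#' @param de_prop Fraction of genes that are differentially expressed
#'   between classes; exactly `ceiling(de_prop * n_genes)` genes are flagged.
#' @param p_zero Probability that an entry is forced to zero by the
#'   excess-zero mask, independently of its mean.
#' @param base_mean_shape,base_mean_rate Gamma prior on per-gene base means.
#' @param de_factor_location,de_factor_scale Log-normal distribution of DE
#'   fold-change magnitudes (on the log scale).
#' @param library_size_location,library_size_scale Log-normal distribution
#'   of per-cell library sizes (on the log scale).
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#' @return An object of class `scdlc_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_per_class = c(50, 50), n_genes = 100,
#'                   de_prop = 0.5, p_zero = 0.2, seed = 1)
sim_config <- function(n_classes = length(n_per_class), n_per_class,
                       n_genes = 100, de_prop = 0.5, p_zero = 0.2,
                       base_mean_shape = 0.6, base_mean_rate = 0.3,
                       de_factor_location = 0.1, de_factor_scale = 0.4,
                       library_size_location = 11, library_size_scale = 0.2,
                       seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != n_classes)
    stopf("n_per_class has length %d but n_classes is %d",
          length(n_per_class), n_classes)
  if (n_classes < 2) stopf("need at least 2 classes, got %d", n_classes)
  if (any(n_per_class < 1)) stopf("all per-class sample sizes must be >= 1")
  if (n_genes < 1) stopf("n_genes must be positive")
  if (de_prop < 0 || de_prop > 1) stopf("de_prop must be in [0, 1]")
  if (p_zero < 0 || p_zero > 1) stopf("p_zero must be in [0, 1]")
  if (base_mean_shape <= 0 || base_mean_rate <= 0)
    stopf("gamma parameters for base means must be positive")
  structure(list(
    n_classes = as.integer(n_classes), n_per_class = n_per_class,
    n_genes = as.integer(n_genes), de_prop = de_prop, p_zero = p_zero,
    base_mean_shape = base_mean_shape, base_mean_rate = base_mean_rate,
    de_factor_location = de_factor_location,
    de_factor_scale = de_factor_scale,
    library_size_location = library_size_location,
    library_size_scale = library_size_scale,
    seed = as.integer(seed)), class = "scdlc_sim_config")
}

#' @export
print.scdlc_sim_config <- function(x, ...) {
  cat(sprintf(
    "scRNA-seq simulation config: K=%d classes (n = %s), g=%d genes, DE=%.2f, p_zero=%.2f, seed=%d\n",
    x$n_classes, paste(x$n_per_class, collapse = "/"), x$n_genes,
    x$de_prop, x$p_zero, x$seed))
  invisible(x)
}

# Named random streams split from the master seed, so e.g. adding genes
# redraws gene-level quantities without disturbing the cell-level draws.
sim_stream_seed <- function(config, stream) {
  id <- match(stream, c("genes", "cells", "counts", "mask"))
  derive_seed(config$seed, 7919L * id)
}

#' Simulate a synthetic scRNA-seq count matrix with class structure
#'
#' Draws counts from the hierarchical model described in [sim_config()]:
#' per-gene base mean lambda_j ~ Gamma(shape, rate); for each of the
#' `ceiling(DE * g)` DE genes, every non-reference class draws its own
#' log-normal fold change, inverted with probability 1/2 (down-regulation);
#' per-cell library size s_i ~ log-normal; the expected count of gene j in
#' cell i of class k is s_i times the gene's share of its class' total mean
#' (so s_i is an actual library size); counts are Poisson; finally an
#' independent Bernoulli(`p_zero`) mask forces entries to zero.
#'
#' @param config An `scdlc_sim_config`.
#' @return An object of class `scdlc_sim`: a list with `counts` (g x n
#'   integer matrix, genes in rows, with gene/cell dimnames), `labels`
#'   (factor of length n), `de_genes` (integer indices of the truly DE
#'   genes), and `config`.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_per_class = c(30, 30), n_genes = 50,
#'                                   de_prop = 0.4, seed = 7))
#' dim(sim$counts)
#' table(sim$labels)
simulate_counts <- function(config) {
  if (!inherits(config, "scdlc_sim_config"))
    stopf("config must be built with sim_config()")
  g <- config$n_genes
  K <- config$n_classes
  n <- sum(config$n_per_class)

  # gene stream: base means, DE gene subset, per-class fold changes
  set.seed(sim_stream_seed(config, "genes"))
  lambda <- rgamma(g, shape = config$base_mean_shape,
                   rate = config$base_mean_rate)
  n_de <- if (config$de_prop > 0) as.integer(ceiling(config$de_prop * g)) else 0L
  de_genes <- if (n_de > 0) sort(sample.int(g, n_de)) else integer(0)
  factors <- matrix(1, g, K)
  if (n_de > 0) {
    for (k in 2:K) {
      f <- rlnorm(n_de, meanlog = config$de_factor_location,
                  sdlog = config$de_factor_scale)
      down <- runif(n_de) < 0.5
      f[down] <- 1 / f[down]
      factors[de_genes, k] <- f
    }
  }
  class_means <- lambda * factors                       # g x K
  class_props <- sweep(class_means, 2, colSums(class_means), "/")

  # cell stream: library sizes
  set.seed(sim_stream_seed(config, "cells"))
  lib_size <- rlnorm(n, meanlog = config$library_size_location,
                     sdlog = config$library_size_scale)

  labels <- factor(rep(paste0("class", seq_len(K)), config$n_per_class),
                   levels = paste0("class", seq_len(K)))
  mu <- class_props[, as.integer(labels), drop = FALSE] *
    rep(lib_size, each = g)                             # g x n expected counts

  # count stream
  set.seed(sim_stream_seed(config, "counts"))
  counts <- matrix(rpois(g * n, lambda = mu), nrow = g)

  # mask stream: excess zeros
  if (config$p_zero > 0) {
    set.seed(sim_stream_seed(config, "mask"))
    keep <- matrix(runif(g * n) >= config$p_zero, nrow = g)
    counts <- counts * keep
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("gene", seq_len(g)), paste0("cell", seq_len(n)))

  structure(list(counts = counts, labels = labels, de_genes = de_genes,
                 config = config), class = "scdlc_sim")
}

#' @export
print.scdlc_sim <- function(x, ...) {
  cat(sprintf("Simulated scRNA-seq data: %d genes x %d cells, %d classes, %d DE genes, %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$labels),
              length(x$de_genes), 100 * mean(x$counts == 0)))
  invisible(x)
}

even_split <- function(total, K) {
  base <- total %/% K
  extra <- total %% K
  as.integer(base + (seq_len(K) <= extra))
}

#' Factorial simulation-study grids
#'
#' Builds the full factorial grid of simulation configurations for the six
#' calibration studies: Studies 1-3 are binary (K = 2) and vary sample size
#' and gene number, DE proportion, and excess-zero probability respectively;
#' Studies 4-6 repeat the designs with K = 3. Each grid point generates `n`
#' training cells and `n` test cells (`2 * n` cells total, split as evenly
#' as possible across classes); set `n_is_per_class = TRUE` to read `n` as a
#' per-class count instead.
#'
#' @param study_id Integer 1..6.
#' @param scale_factor Fraction in (0, 1] scaling the number of replicates
#'   attached to the grid (full fidelity is 1000 replicates per grid point);
#'   the design grid itself is never scaled.
#' @param n_is_per_class Interpret the sample-size levels as per-class
#'   counts rather than totals per set.
#' @return A list of `scdlc_sim_config` objects; each element carries
#'   attributes `n_train` (cells in the training set), `n`, `g`, `de`,
#'   `p_zero`, `K`; the list carries attribute `replicates`.
#' @export
#' @examples
#' grid <- make_study_grid(2)
#' length(grid)
make_study_grid <- function(study_id, scale_factor = 0.02,
                            n_is_per_class = FALSE) {
  if (!study_id %in% 1:6) stopf("unknown study_id %s; must be 1..6", study_id)
  if (scale_factor <= 0 || scale_factor > 1)
    stopf("scale_factor must be in (0, 1]")
  K <- if (study_id <= 3) 2L else 3L
  base <- switch(((study_id - 1L) %% 3L) + 1L,
    list(g = c(100L, 200L, 300L, 400L), de = 0.5, p_zero = 0.2,
         n = if (K == 2L) seq(100L, 900L, by = 100L)
             else seq(300L, 900L, by = 150L)),
    list(g = 100L, de = seq(0.2, 0.7, by = 0.1), p_zero = 0.2,
         n = if (K == 2L) c(200L, 300L, 400L, 500L)
             else c(300L, 400L, 500L, 600L)),
    list(g = 100L, de = 0.4, p_zero = seq(0.1, 0.6, by = 0.1),
         n = if (K == 2L) c(200L, 300L, 400L, 500L)
             else c(300L, 400L, 500L, 600L)))
  grid <- expand.grid(g = base$g, de = base$de, p_zero = base$p_zero,
                      n = base$n, KEEP.OUT.ATTRS = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n[i]
    total <- if (n_is_per_class) 2L * n * K else 2L * n
    cfg <- sim_config(n_classes = K, n_per_class = even_split(total, K),
                      n_genes = grid$g[i], de_prop = grid$de[i],
                      p_zero = grid$p_zero[i], seed = 0L)
    attr(cfg, "n_train") <- if (n_is_per_class) n * K else n
    attr(cfg, "n") <- n
    attr(cfg, "g") <- grid$g[i]
    attr(cfg, "de") <- grid$de[i]
    attr(cfg, "p_zero") <- grid$p_zero[i]
    attr(cfg, "K") <- K
    cfg
  })
  attr(configs, "replicates") <- max(1L, as.integer(round(1000 * scale_factor)))
  attr(configs, "study_id") <- as.integer(study_id)
  configs
}

#' Stratified train/test split of a count matrix
#'
#' Randomly partitions cells into a training set of `n_train` cells and a
#' test set of the remaining cells, stratified so that each class
#' contributes in proportion to its overall frequency (largest-remainder
#' apportionment). The split is seeded and reproducible.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Factor (or coercible) of class labels, one per cell.
#' @param n_train Number of cells in the training set.
#' @param seed Integer seed.
#' @return A list with `train` and `test`, each a list of `counts` and
#'   `labels`.
#' @export
split_train_test <- function(counts, labels, n_train, seed = 1L) {
  labels <- as.factor(labels)
  n <- ncol(counts)
  if (length(labels) != n)
    stopf("labels length (%d) does not match cell count (%d)",
          length(labels), n)
  if (n_train >= n || n_train < 1)
    stopf("n_train must be in [1, %d), got %s", n, n_train)
  n_k <- table(labels)
  # largest-remainder apportionment of n_train across classes
  quota <- n_train * as.numeric(n_k) / n
  take <- floor(quota)
  rem <- n_train - sum(take)
  if (rem > 0) {
    o <- order(quota - take, decreasing = TRUE)
    take[o[seq_len(rem)]] <- take[o[seq_len(rem)]] + 1
  }
  names(take) <- names(n_k)
  empty <- names(take)[take < 1 | take >= as.numeric(n_k)]
  if (length(empty) > 0)
    stopf("n_train = %d leaves class(es) %s empty in the train or test set",
          n_train, paste(empty, collapse = ", "))
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    train_idx <- c(train_idx, idx[sample.int(length(idx), take[[cl]])])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(
    train = list(counts = counts[, train_idx, drop = FALSE],
                 labels = labels[train_idx]),
    test = list(counts = counts[, test_idx, drop = FALSE],
                labels = labels[test_idx]))
}
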