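#' Library-size normalization and log transform for count input
#'
#' Scales each cell's counts to the median library size of the matrix and
#' applies `log1p`. This is the default expression scale both for BW gene
#' ranking and for the network input, so the ranking and the model see the
#' same values. Cells with zero total counts are left untouched.
#'
#' @param counts Genes x cells count matrix.
#' @return A dense numeric matrix of the same shape.
#' @export
preprocess_counts <- function(counts) {
  lib <- colSums(counts)
  med <- median(lib[lib > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  sf <- ifelse(lib > 0, lib / med, 1)
  log1p(sweep(counts, 2, sf, "/"))
}

bw_scores_matrix <- function(x, labels, within = FALSE) {
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (K < 2) stopf("BW statistic needs at least 2 classes, got %d", K)
  if (length(labels) != ncol(x))
    stopf("labels length (%d) does not match cell count (%d)",
          length(labels), ncol(x))
  n_k <- as.numeric(table(labels))
  # class means: g x K
  cm <- matrix(vapply(levels(labels),
                      function(cl) rowMeans(x[, labels == cl, drop = FALSE]),
                      numeric(nrow(x))),
               nrow = nrow(x), ncol = K)
  grand <- rowMeans(cm)  # unweighted mean of class means
  num <- as.numeric((cm - grand)^2 %*% n_k)
  if (within) {
    den <- numeric(nrow(x))
    for (cl in seq_len(K)) {
      xc <- x[, labels == levels(labels)[cl], drop = FALSE]
      den <- den + rowSums((xc - cm[, cl])^2)
    }
  } else {
    den <- rowSums((x - grand)^2)
  }
  unname(ifelse(den > 0, num / den, 0))
}

#' BW statistic of a single gene
#'
#' The ratio of the between-class sum of squares to the total sum of squares
#' about the grand mean, where the grand mean of gene j is the *unweighted*
#' average of its class means (not the pooled sample mean; the two differ
#' when classes are unbalanced):
#' numerator \eqn{\sum_k \sum_{i=1}^{n_k} (\bar x_{k.j} - \bar x_{..j})^2},
#' denominator \eqn{\sum_k \sum_{i=1}^{n_k} (x_{kij} - \bar x_{..j})^2}.
#' Genes with zero denominator (constant across all cells) score 0.
#'
#' The denominator sums squares about the grand mean; `within = TRUE`
#' substitutes the within-class sum of squares
#' \eqn{\sum_k \sum_i (x_{kij} - \bar x_{k.j})^2} (the classic
#' Dudoit-style BW ratio). The default keeps the grand-mean denominator.
#'
#' @param x Genes x cells expression matrix (any scale).
#' @param labels Class labels, one per cell.
#' @param gene_index Row index of the gene to score.
#' @param within Use the within-class denominator instead of the total sum
#'   of squares.
#' @return A non-negative scalar.
#' @export
#' @examples
#' x <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' bw_statistic(x, rep(c("a", "b"), each = 3), 1)  # 13.5 / 17.5
bw_statistic <- function(x, labels, gene_index, within = FALSE) {
  if (gene_index < 1 || gene_index > nrow(x))
    stopf("gene_index %s out of range 1..%d", gene_index, nrow(x))
  bw_scores_matrix(x[gene_index, , drop = FALSE], labels, within = within)[1]
}

#' Rank genes by the BW statistic and select the top p
#'
#' Scores every gene on the (training) matrix with the BW statistic and
#' returns the `p` highest-scoring genes in descending-score order, ties
#' broken by ascending gene index so the ranking is reproducible. The same
#' ranking object must be applied unchanged to test data.
#'
#' @param counts Genes x cells count matrix of TRAINING cells only.
#' @param labels Training class labels.
#' @param p Number of genes to select (1 <= p <= number of genes).
#' @param scale Expression scale on which to rank: `"preprocessed"` (the
#'   [preprocess_counts()] scale fed to the network; default) or `"raw"`.
#' @param within Passed to the BW denominator choice, see [bw_statistic()].
#' @return An object of class `scdlc_ranking`: list with `bw_scores` (full
#'   length-g vector), `order` (permutation of gene indices by descending
#'   score), `selected` (first `p` of `order`), `gene_ids`, `p`, `scale`,
#'   `within`.
#' @export
select_top_genes <- function(counts, labels, p = 100,
                             scale = c("preprocessed", "raw"),
                             within = FALSE) {
  scale <- match.arg(scale)
  g <- nrow(counts)
  if (p < 1 || p > g)
    stopf("p must be in 1..%d (number of genes), got %s", g, p)
  x <- if (scale == "preprocessed") preprocess_counts(counts) else counts
  bw <- bw_scores_matrix(x, labels, within = within)
  ord <- order(-bw, seq_along(bw))
  structure(list(
    bw_scores = as.numeric(bw),
    order = ord,
    selected = ord[seq_len(p)],
    gene_ids = rownames(counts) %||% as.character(seq_len(g)),
    p = as.integer(p), scale = scale, within = within),
    class = "scdlc_ranking")
}

#' @export
print.scdlc_ranking <- function(x, ...) {
  cat(sprintf("BW gene ranking: %d of %d genes selected (scale = %s)\n",
              x$p, length(x$bw_scores), x$scale))
  top <- head(x$selected, 5)
  cat("  top genes:", paste(x$gene_ids[top], collapse = ", "),
      if (x$p > 5) "..." else "", "\n")
  invisible(x)
}

# Expression matrix (p x n, timestep-ordered) the network consumes.
ranked_input <- function(counts, ranking) {
  if (max(ranking$selected) > nrow(counts))
    stopf("ranking refers to gene index %d but matrix has %d genes",
          max(ranking$selected), nrow(counts))
  x <- if (ranking$scale == "preprocessed") preprocess_counts(counts) else counts
  m <- x[ranking$selected, , drop = FALSE]
  storage.mode(m) <- "double"
  m
}
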