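#' Misclassification rate
#'
#' Fraction of samples whose predicted class differs from the truth.
#'
#' @param predictions,truth Equal-length class vectors (factor or integer).
#' @return Fraction in \[0, 1\].
#' @export
misclassification_rate <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stopf("predictions (%d) and truth (%d) differ in length",
          length(predictions), length(truth))
  if (length(truth) == 0) stopf("need at least one sample")
  mean(as.character(predictions) != as.character(truth))
}

# Binary AUC of `scores` for the positive indicator `pos` via the
# rank-based Mann-Whitney statistic; ties contribute 1/2.
binary_auc <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # average ranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUC scores
#'
#' Per-class one-vs-rest area under the ROC curve computed from the class
#' probability scores with the rank (Mann-Whitney) formulation, ties
#' contributing 1/2; the macro AUC is the unweighted mean over classes.
#' For two classes this reduces to the standard binary AUC of the
#' positive-class score.
#'
#' @param probabilities n x M matrix of class probabilities (rows are
#'   samples) with class names as column names, or an M x n matrix as
#'   produced by [scdlc_forward()] (auto-detected via the labels).
#' @param truth Length-n class labels.
#' @return List with `macro` (mean AUC over classes present in `truth`)
#'   and `per_class` (named vector; classes absent from `truth` are
#'   skipped with a warning).
#' @export
auc_score <- function(probabilities, truth) {
  truth <- as.factor(truth)
  probs <- as.matrix(probabilities)
  if (nrow(probs) != length(truth) && ncol(probs) == length(truth))
    probs <- t(probs)
  if (nrow(probs) != length(truth))
    stopf("probability matrix (%d x %d) does not match %d samples",
          nrow(probs), ncol(probs), length(truth))
  present <- levels(droplevels(truth))
  if (length(present) < 2)
    stopf("AUC needs at least two classes present in truth")
  cls <- colnames(probs) %||% levels(truth)
  if (length(cls) != ncol(probs)) cls <- as.character(seq_len(ncol(probs)))
  skipped <- setdiff(cls, present)
  if (length(skipped) > 0)
    warnf("class(es) absent from truth skipped in AUC: %s",
          paste(skipped, collapse = ", "))
  per <- vapply(which(cls %in% present), function(j)
    binary_auc(probs[, j], as.character(truth) == cls[j]), numeric(1))
  names(per) <- cls[cls %in% present]
  list(macro = mean(per), per_class = per)
}

#' Evaluate a trained model on labelled cells
#'
#' @param model A trained `scdlc_model`.
#' @param counts Genes x cells count matrix of evaluation cells.
#' @param labels True class labels of the evaluation cells.
#' @return An object of class `scdlc_eval`: misclassification rate,
#'   accuracy, macro and per-class one-vs-rest AUC, K x K confusion matrix
#'   (rows = truth), number of cells, predictions and the probability
#'   matrix.
#' @export
evaluate_model <- function(model, counts, labels) {
  labels <- factor(as.character(labels), levels = model$classes)
  if (anyNA(labels))
    stopf("labels contain classes the model was not trained on")
  probs <- predict(model, counts, type = "prob")
  pred <- factor(model$classes[predict_class(probs)], levels = model$classes)
  confusion <- table(truth = labels, predicted = pred)
  auc <- auc_score(t(probs), labels)
  structure(list(
    misclassification_rate = misclassification_rate(pred, labels),
    accuracy = mean(pred == labels),
    auc_macro = auc$macro, per_class_auc = auc$per_class,
    confusion = unclass(confusion), n_test = length(labels),
    predictions = pred, probabilities = probs), class = "scdlc_eval")
}

#' @export
print.scdlc_eval <- function(x, ...) {
  cat(sprintf("scDLC evaluation on %d cells: misclassification %.3f, macro AUC %.3f\n",
              x$n_test, x$misclassification_rate, x$auc_macro))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

# One simulate -> split -> rank -> train -> evaluate replicate.
run_one_replicate <- function(config, n_train, p_features, tconf, seed) {
  cfg <- config
  cfg$seed <- derive_seed(seed, 1L)
  sim <- simulate_counts(cfg)
  sp <- split_train_test(sim$counts, sim$labels, n_train,
                         seed = derive_seed(seed, 2L))
  p <- min(p_features, nrow(sim$counts))
  ranking <- select_top_genes(sp$train$counts, sp$train$labels, p = p)
  tc <- tconf
  tc$seed <- derive_seed(seed, 3L)
  model <- train_model(sp$train$counts, sp$train$labels, ranking, tc)
  ev <- evaluate_model(model, sp$test$counts, sp$test$labels)
  list(eval = ev, model = model)
}

#' Run a (scaled) simulation study
#'
#' For every grid point of the chosen study design (see
#' [make_study_grid()]): simulate counts, split into n training and n test
#' cells, rank genes by BW on the training half, train the classifier, and
#' record the test misclassification rate and macro AUC. Replicate seeds
#' are derived deterministically from `base_seed`, the grid point and the
#' replicate index.
#'
#' @param study_id Integer 1..6.
#' @param replicates Replicates per grid point (the full-fidelity design
#'   uses 1000; scaled runs use fewer).
#' @param p_features Number of BW-selected genes (capped at g).
#' @param config A [train_config()].
#' @param base_seed Integer master seed.
#' @param subset Optional named list restricting the grid, e.g.
#'   `list(n = c(100, 300, 600), g = 100)`; entries match the grid
#'   attributes `n`, `g`, `de`, `p_zero`.
#' @param n_is_per_class Passed to [make_study_grid()].
#' @return An object of class `scdlc_study`: `results` (one row per
#'   replicate per grid point) and `summary` (per grid point mean and SD of
#'   the misclassification rate). A `method` column is reserved so external
#'   baselines can be merged.
#' @export
run_simulation_study <- function(study_id, replicates = 20, p_features = 100,
                                 config = train_config(), base_seed = 1L,
                                 subset = NULL, n_is_per_class = FALSE) {
  if (replicates < 1) stopf("replicates must be >= 1")
  grid <- make_study_grid(study_id, n_is_per_class = n_is_per_class)
  keep <- vapply(grid, function(cfg) {
    ok <- TRUE
    for (nm in names(subset))
      ok <- ok && attr(cfg, nm) %in% subset[[nm]]
    ok
  }, logical(1))
  grid <- grid[keep]
  if (length(grid) == 0) stopf("subset leaves no grid points")
  rows <- list()
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    for (rep in seq_len(replicates)) {
      seed <- derive_seed(base_seed, study_id * 1000L + i, rep)
      res <- tryCatch(
        run_one_replicate(cfg, attr(cfg, "n_train"), p_features, config, seed),
        error = function(e) stopf(
          "study %d grid point %d (n=%d, g=%d, DE=%g, p_zero=%g), replicate %d: %s",
          study_id, i, attr(cfg, "n"), attr(cfg, "g"), attr(cfg, "de"),
          attr(cfg, "p_zero"), rep, conditionMessage(e)))
      rows[[length(rows) + 1]] <- data.frame(
        study = study_id, grid_point = i, K = attr(cfg, "K"),
        g = attr(cfg, "g"), n = attr(cfg, "n"), de = attr(cfg, "de"),
        p_zero = attr(cfg, "p_zero"), replicate = rep, seed = seed,
        misclassification = res$eval$misclassification_rate,
        auc = res$eval$auc_macro,
        train_accuracy = res$model$report$final_train_accuracy,
        method = "scDLC")
    }
  }
  results <- do.call(rbind, rows)
  agg <- aggregate(misclassification ~ study + grid_point + K + g + n + de + p_zero,
                   data = results, FUN = function(v) c(mean(v), stats::sd(v)))
  summary <- cbind(agg[, 1:7],
                   mean_misclassification = agg$misclassification[, 1],
                   sd_misclassification = agg$misclassification[, 2],
                   replicates = replicates)
  structure(list(results = results, summary = summary),
            class = "scdlc_study")
}

#' @export
print.scdlc_study <- function(x, ...) {
  cat("Simulation-study summary (mean test misclassification):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Repeated random train/test splits on one dataset
#'
#' Repeats the full pipeline (stratified split, BW ranking on the training
#' half, training, evaluation on the held-out half) under fresh seeded
#' splits, returning per-repetition evaluation reports suitable for
#' boxplot summaries of the AUC.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Class labels, one per cell.
#' @param n_train Training-set size per repetition.
#' @param repetitions Number of repeated splits.
#' @param p_features Number of BW-selected genes.
#' @param config A [train_config()].
#' @param base_seed Integer master seed.
#' @return List with `reports` (one `scdlc_eval` per repetition) and
#'   `results` (tidy data.frame of misclassification and AUC per
#'   repetition).
#' @export
run_repeated_splits <- function(counts, labels, n_train, repetitions = 100,
                                p_features = 100, config = train_config(),
                                base_seed = 1L) {
  if (repetitions < 1) stopf("repetitions must be >= 1")
  labels <- as.factor(labels)
  reports <- vector("list", repetitions)
  rows <- vector("list", repetitions)
  for (rep in seq_len(repetitions)) {
    seed <- derive_seed(base_seed, rep)
    sp <- split_train_test(counts, labels, n_train,
                           seed = derive_seed(seed, 2L))
    p <- min(p_features, nrow(counts))
    ranking <- select_top_genes(sp$train$counts, sp$train$labels, p = p)
    tc <- config
    tc$seed <- derive_seed(seed, 3L)
    model <- train_model(sp$train$counts, sp$train$labels, ranking, tc)
    ev <- evaluate_model(model, sp$test$counts, sp$test$labels)
    reports[[rep]] <- ev
    rows[[rep]] <- data.frame(repetition = rep, seed = seed,
                              misclassification = ev$misclassification_rate,
                              auc = ev$auc_macro, n_test = ev$n_test)
  }
  list(reports = reports, results = do.call(rbind, rows))
}
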