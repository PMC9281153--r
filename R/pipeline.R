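read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

resolve_pipeline_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_config_file(config)
  if (!is.list(config)) stopf("pipeline config must be a list or a file path")
  if (is.null(config$simulation) && is.null(config$data))
    stopf("pipeline config needs either a 'simulation' block or a 'data' block")
  if (!is.null(config$simulation) && !is.null(config$data))
    stopf("pipeline config must not have both 'simulation' and 'data' blocks")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config$seed <- as.integer(config$seed %||% 1L)
  config$features <- modifyList(list(p = 100, scale = "preprocessed"),
                                as.list(config$features))
  config$train <- as.list(config$train)
  if (!is.null(config$data)) {
    for (nm in c("counts", "labels", "n_train"))
      if (is.null(config$data[[nm]]))
        stopf("pipeline 'data' block is missing '%s'", nm)
  } else {
    if (is.null(config$simulation$n_train))
      stopf("pipeline 'simulation' block is missing 'n_train'")
  }
  config
}

#' Run the full classification pipeline and write its artifacts
#'
#' Executes simulate (or read) -> stratified split -> BW gene selection on
#' the training half -> training -> evaluation on the held-out half, and
#' writes the gene ranking, the model checkpoint, the evaluation report and
#' a run manifest (fully resolved configuration, seed, package version)
#' that allows an exact re-run via [rerun_manifest()].
#'
#' The configuration is a list (or YAML/JSON file) with blocks:
#' * `simulation`: arguments of [sim_config()] plus `n_train` — or
#'   `data`: `counts` path, `labels` path, `n_train`;
#' * `features`: `p` (default 100), `scale`;
#' * `train`: arguments of [train_config()];
#' * `seed`: master seed (all stage seeds derive from it).
#'
#' @param config List or path to a YAML/JSON configuration file.
#' @param out_dir Output directory for the artifacts.
#' @param seed Optional master seed overriding the config entry.
#' @return List with `model`, `eval`, `split`, and `manifest_path`,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- resolve_pipeline_config(config, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master <- config$seed

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    n_train <- sim_args$n_train
    sim_args$n_train <- NULL
    sim_args$seed <- derive_seed(master, 1L)
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_counts(scfg)
    counts <- sim$counts; labels <- sim$labels
  } else {
    counts <- read_counts(config$data$counts)
    lab_df <- read_labels(config$data$labels)
    ds <- bundle_dataset(counts, lab_df)
    counts <- ds$counts; labels <- ds$labels
    n_train <- config$data$n_train
  }

  sp <- split_train_test(counts, labels, n_train,
                         seed = derive_seed(master, 2L))
  ranking <- select_top_genes(sp$train$counts, sp$train$labels,
                              p = min(config$features$p, nrow(counts)),
                              scale = config$features$scale)
  tc_args <- config$train
  tc_args$seed <- derive_seed(master, 3L)
  tconf <- do.call(train_config, tc_args)
  model <- train_model(sp$train$counts, sp$train$labels, ranking, tconf)
  ev <- evaluate_model(model, sp$test$counts, sp$test$labels)

  write_ranking(ranking, file.path(out_dir, "ranking.tsv"))
  save_checkpoint(model, file.path(out_dir, "model.json"))
  jsonlite::write_json(
    list(misclassification_rate = ev$misclassification_rate,
         accuracy = ev$accuracy, auc_macro = ev$auc_macro,
         per_class_auc = as.list(ev$per_class_auc),
         confusion = ev$confusion, n_test = ev$n_test,
         predictions = as.character(ev$predictions)),
    file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = 17)
  manifest <- list(format = "scdlc-manifest", version = 1L,
                   package_version = as.character(utils::packageVersion("scDLC")),
                   r_version = as.character(getRversion()),
                   seed = master, config = config)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = 17)
  invisible(list(model = model, eval = ev, split = sp,
                 manifest_path = manifest_path))
}

#' Re-run a pipeline exactly from its manifest
#'
#' Reads the fully resolved configuration and master seed recorded by
#' [run_pipeline()] and executes the identical pipeline; on a fixed
#' platform the resulting evaluation report is bit-identical to the
#' original run.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory for the re-run artifacts (a temporary
#'   directory by default).
#' @return Same value as [run_pipeline()], invisibly.
#' @export
rerun_manifest <- function(manifest_path,
                           out_dir = tempfile("scdlc_rerun_")) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(man$format, "scdlc-manifest"))
    stopf("%s is not an scDLC run manifest", manifest_path)
  run_pipeline(man$config, out_dir, seed = man$seed)
}
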