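#' Read a count matrix from dense TSV or MatrixMarket files
#'
#' Dense TSV files have genes in rows, a header row of cell identifiers
#' and the gene identifier in the first column. MatrixMarket (`.mtx`)
#' triplet files are read with their `genes.tsv` / `barcodes.tsv` sidecars
#' from the same directory. Entries must be non-negative integers;
#' fractional or negative values are rejected with the offending position.
#'
#' @param path File path (`.tsv`/`.txt`/`.csv` dense, `.mtx` sparse).
#' @param format `"auto"` (from the extension), `"tsv"` or `"mtx"`.
#' @param transpose Set `TRUE` for dense files with cells in rows.
#' @return Integer genes x cells matrix with gene/cell dimnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mtx") "mtx" else "tsv"
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- file.path(dir, "genes.tsv")
    cells <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genes) || !file.exists(cells))
      stopf("MTX sidecars genes.tsv / barcodes.tsv not found next to %s", path)
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(cells)
    counts <- m
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            data.table = FALSE)
    if (ncol(dt) < 2) stopf("count TSV must have a gene-id column plus >= 1 cell")
    ids <- as.character(dt[[1]])
    counts <- as.matrix(dt[, -1, drop = FALSE])
    rownames(counts) <- ids
    if (transpose) counts <- t(counts)
  }
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(as.numeric(counts))))[1]
    stopf("non-numeric count at row %d, column %d",
          (bad - 1) %% nrow(counts) + 1, (bad - 1) %/% nrow(counts) + 1)
  }
  bad <- which(counts < 0 | counts != floor(counts))
  if (length(bad) > 0) {
    r <- (bad[1] - 1) %% nrow(counts) + 1
    co <- (bad[1] - 1) %/% nrow(counts) + 1
    stopf("counts must be non-negative integers; offending value %s at gene %s, cell %s",
          format(counts[bad[1]]), rownames(counts)[r], colnames(counts)[co])
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix
#'
#' @param counts Integer genes x cells matrix with dimnames.
#' @param path Output path; `.mtx` writes a MatrixMarket triplet plus
#'   `genes.tsv` / `barcodes.tsv` sidecars, anything else a dense TSV
#'   (header = cell ids, first column `gene_id`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  } else {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t")
  }
  invisible(path)
}

#' Read per-cell class labels
#'
#' Two-column TSV (`cell_id`, `class_name`), header optional. Class names
#' are mapped to indices in order of first appearance.
#'
#' @param path File path.
#' @return A data.frame with columns `cell_id` and `class_name`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) != 2) stopf("label file must have exactly 2 columns, got %d",
                           ncol(dt))
  if (identical(tolower(as.character(dt[1, ])), c("cell_id", "class_name")))
    dt <- dt[-1, , drop = FALSE]
  data.frame(cell_id = as.character(dt[[1]]),
             class_name = as.character(dt[[2]]))
}

#' Write per-cell class labels
#'
#' @param labels Class labels (factor or character), one per cell.
#' @param cell_ids Matching cell identifiers.
#' @param path Output TSV path.
#' @export
write_labels <- function(labels, cell_ids, path) {
  data.table::fwrite(data.frame(cell_id = cell_ids,
                                class_name = as.character(labels)),
                     path, sep = "\t")
  invisible(path)
}

#' Join a count matrix with its labels into an aligned dataset
#'
#' Cells are matched by identifier (not position); every cell must appear
#' exactly once on both sides. Class indices follow first appearance in
#' the label table.
#'
#' @param counts Genes x cells matrix with cell ids as column names.
#' @param labels A data.frame as returned by [read_labels()], or a vector
#'   of labels named by (or aligned with) the cells.
#' @param provenance Optional list recording where the pieces came from
#'   (source paths, formats), carried along unmodified.
#' @return List of class `scdlc_dataset` with aligned `counts`,
#'   `labels` (factor) and `provenance`.
#' @export
bundle_dataset <- function(counts, labels, provenance = NULL) {
  if (is.null(colnames(counts))) stopf("counts must have cell ids as column names")
  if (!is.data.frame(labels))
    labels <- data.frame(cell_id = names(labels) %||% colnames(counts),
                         class_name = as.character(labels))
  if (anyDuplicated(labels$cell_id))
    stopf("duplicate cell ids in labels: %s",
          paste(unique(labels$cell_id[duplicated(labels$cell_id)]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate cell ids in counts")
  missing_lab <- setdiff(colnames(counts), labels$cell_id)
  missing_cnt <- setdiff(labels$cell_id, colnames(counts))
  if (length(missing_lab) || length(missing_cnt))
    stopf("cells without %s: %s",
          if (length(missing_lab)) "labels" else "counts",
          paste(c(missing_lab, missing_cnt), collapse = ", "))
  lv <- unique(labels$class_name)
  lab <- factor(labels$class_name[match(colnames(counts), labels$cell_id)],
                levels = lv)
  structure(list(counts = counts, labels = lab, provenance = provenance),
            class = "scdlc_dataset")
}

#' Write a simulated dataset to disk
#'
#' Writes the counts (TSV or MTX), the label table, and a JSON metadata
#' sidecar with the configuration echo and the indices of the truly DE
#' genes.
#'
#' @param sim An `scdlc_sim` object.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"mtx"`.
#' @return The directory, invisibly.
#' @export
write_sim <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts,
               file.path(dir, paste0("counts.", format)))
  write_labels(sim$labels, colnames(sim$counts), file.path(dir, "labels.tsv"))
  meta <- list(config = unclass(sim$config), de_genes = sim$de_genes,
               n_genes = nrow(sim$counts), n_cells = ncol(sim$counts))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = 17)
  invisible(dir)
}

#' Write a gene ranking to TSV or JSON
#'
#' One row per gene with its BW score and rank, ordered by rank (TSV), or
#' the full ranking object (JSON, by file extension).
#'
#' @param ranking An `scdlc_ranking`.
#' @param path Output path; `.json` writes JSON, anything else a TSV.
#' @export
write_ranking <- function(ranking, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(unclass(ranking), path, auto_unbox = TRUE,
                         digits = 17)
    return(invisible(path))
  }
  df <- data.frame(gene_id = ranking$gene_ids[ranking$order],
                   gene_index = ranking$order,
                   bw_score = ranking$bw_scores[ranking$order],
                   rank = seq_along(ranking$order),
                   selected = seq_along(ranking$order) <= ranking$p)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

flatten_params <- function(params) {
  lapply(unclass(params), function(a)
    list(dim = dim(a) %||% length(a), data = as.numeric(a)))
}

unflatten_params <- function(flat, meta) {
  params <- lapply(flat, function(e) {
    v <- as.double(e$data)
    if (length(e$dim) == 2) matrix(v, e$dim[1], e$dim[2]) else v
  })
  structure(params, p = meta$p, hidden_size = meta$hidden_size,
            fc1_dim = meta$fc1_dim, n_classes = meta$n_classes,
            class = "scdlc_params")
}

#' Save a trained model to a structured checkpoint file
#'
#' Single JSON checkpoint holding every named parameter array (at full
#' 17-significant-digit precision, so a load round-trip is bit-exact), the
#' training configuration, the gene ranking and the class names.
#'
#' @param model An `scdlc_model`.
#' @param path Output path (conventionally `.json`).
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(
    format = "scdlc-checkpoint", version = 1L,
    classes = model$classes,
    config = unclass(model$config),
    params_meta = list(p = attr(model$params, "p"),
                       hidden_size = attr(model$params, "hidden_size"),
                       fc1_dim = attr(model$params, "fc1_dim"),
                       n_classes = attr(model$params, "n_classes")),
    params = flatten_params(model$params),
    center = model$center, scale = model$scale,
    ranking = unclass(model$ranking))
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = 17)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return An `scdlc_model` (without a training report).
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ck$format, "scdlc-checkpoint"))
    stopf("%s is not an scDLC checkpoint", path)
  config <- do.call(train_config, ck$config[setdiff(names(ck$config), NULL)])
  ranking <- structure(ck$ranking, class = "scdlc_ranking")
  ranking$selected <- as.integer(ranking$selected)
  ranking$order <- as.integer(ranking$order)
  ranking$p <- as.integer(ranking$p)
  params <- unflatten_params(ck$params, ck$params_meta)
  structure(list(params = params, report = NULL, ranking = ranking,
                 config = config, center = as.double(ck$center),
                 scale = as.double(ck$scale), classes = ck$classes),
            class = "scdlc_model")
}
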