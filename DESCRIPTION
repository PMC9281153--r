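Package: scDLC
Title: Deep Learning Classification of Large-Sample Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cell-type classification for large-sample single-cell RNA
    sequencing count data with a two-layer long short-term memory (LSTM)
    recurrent network. Genes are ranked on the training set by the ratio of
    between-class to within-class sums of squares (the BW statistic) and the
    top-ranked genes form the input sequence of the network, which is trained
    by mini-batch gradient descent on the cross-entropy loss with global-norm
    gradient clipping and an exponentially decaying learning rate. Includes a
    gamma-Poisson count simulator with log-normal differential-expression
    fold changes and excess zeros for calibration studies, stratified
    train/test splitting, misclassification-rate and one-vs-rest AUC
    evaluation, simulation-study and repeated-split harnesses, and readers
    and writers for dense TSV and MatrixMarket count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
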