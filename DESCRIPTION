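Package: metabodbn
Title: Deep Belief Network Classification of Metabolomic Peak Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classification of high-dimensional, sparse metabolomic peak
    intensity matrices with a deep belief network (DBN): restricted Boltzmann
    machine (RBM) pretraining by one-step contrastive divergence (CD-1),
    dropout regularisation, a softmax head, and joint fine-tuning by
    full-batch gradient descent or L-BFGS. Includes min-max normalisation
    fitted on training folds, stratified k-fold cross-validation with
    SVM/KNN/BPNN baselines, per-iteration error traces, a synthetic
    peak-matrix generator with planted group structure, and an exact
    log-likelihood gradient oracle for small RBMs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
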