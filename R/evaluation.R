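# Metrics, baseline classifiers, the stratified cross-validation driver,
# comparison tables and the train-size sweep.

#' Classification accuracy as a rounded percentage
#'
#' `100 * matches / n`, rounded half-up to two decimals — the granularity
#' accuracy tables are conventionally printed at (e.g. 32 correct of 34 is
#' 94.12).
#'
#' @param predicted,truth Equal-length label vectors.
#' @return A single numeric percentage.
#' @export
accuracy_percent <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must be non-empty and of equal length.")
  }
  round_half_up(100 * mean(as.character(predicted) == as.character(truth)), 2)
}

#' Mean squared error against one-hot targets
#'
#' Mean over all entries of the squared difference between predicted class
#' probabilities and one-hot targets (the FMSE trace metric).
#'
#' @param probs Probability matrix (rows sum to 1).
#' @param Y One-hot matrix of the same shape.
#' @return A single number in `[0, 1]`.
#' @export
mse_onehot <- function(probs, Y) {
  if (!all(dim(probs) == dim(Y))) abort("`probs` and `Y` must have the same shape.")
  mean((probs - Y)^2)
}

#' Baseline classifier specification
#'
#' Off-the-shelf reference classifiers trained on the normalised
#' intensities: an RBF-kernel SVM (`e1071::svm`, cost 1, "scale" gamma
#' `1 / (p * var(x))`), k-nearest neighbours (`class::knn`, k = 5), or a
#' single-hidden-layer back-propagation network (`nnet::nnet`, width 100;
#' the conventional BPNN baseline).
#'
#' @param method `"svm"`, `"knn"` or `"bpnn"`.
#' @param ... Hyperparameter overrides: `cost`/`gamma` (svm), `k` (knn),
#'   `size`/`maxit`/`decay` (bpnn).
#' @param name Display name; defaults to the upper-cased kind.
#' @return A list of class `baseline_spec`.
#' @export
baseline_spec <- function(method = c("svm", "knn", "bpnn"), ..., name = NULL) {
  kind <- match.arg(method)
  defaults <- switch(kind,
    svm = list(cost = 1, gamma = NULL),
    knn = list(k = 5L),
    bpnn = list(size = 100L, maxit = 200L, decay = 1e-4))
  hyper <- modifyList(defaults, list(...))
  structure(list(kind = kind, hyperparameters = hyper,
                 name = name %||% toupper(kind)),
            class = "baseline_spec")
}

# Fit + predict a baseline on normalised matrices. Returns predicted labels
# for X_test.
baseline_predict <- function(spec, X_train, y_train, X_test, seed) {
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  hp <- spec$hyperparameters
  y <- factor(y_train)
  switch(spec$kind,
    svm = {
      gamma <- hp$gamma %||% {
        v <- var(as.numeric(X_train))
        if (v > 0) 1 / (ncol(X_train) * v) else 1 / ncol(X_train)
      }
      fit <- e1071::svm(X_train, y, kernel = "radial",
                        cost = hp$cost, gamma = gamma, scale = FALSE)
      as.character(predict(fit, X_test))
    },
    knn = as.character(class::knn(X_train, X_test, y, k = hp$k)),
    bpnn = {
      fit <- nnet::nnet(X_train, class.ind2(y), size = hp$size,
                        softmax = TRUE, maxit = hp$maxit, decay = hp$decay,
                        MaxNWts = 1e7, trace = FALSE)
      levels(y)[max.col(predict(fit, X_test), ties.method = "first")]
    })
}

# nnet::class.ind equivalent kept local (one-hot with factor level columns).
class.ind2 <- function(y) {
  one_hot(as.character(y), levels(y))
}

model_name <- function(spec) {
  if (inherits(spec, "mdbn_spec")) spec$name else spec$name
}

#' Stratified k-fold cross-validation of a model
#'
#' Runs the full leakage-free protocol: for each fold the min-max
#' normaliser is fitted on the training fold only, the DBN is pretrained on
#' the training intensities (unlabelled use), the softmax head is trained
#' and the network fine-tuned, and accuracy is measured on the held-out
#' fold. Baseline specs are trained on the same normalised training folds.
#' The report's mean follows table convention: per-fold accuracies rounded
#' half-up to 2 decimals, then their mean rounded the same way.
#'
#' @param data A labelled peaks tibble.
#' @param spec An [mdbn_spec()] or [baseline_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed driving the fold plan and every model fit.
#' @param label Name of the label column.
#' @param fold_plan Optional precomputed [stratified_kfold()] plan, so
#'   several models share identical folds.
#' @return An object of class `cv_report`: per-fold results (tibble
#'   `fold`, `n_train`, `n_test`, `accuracy`), `mean_accuracy`, traces for
#'   DBN models, the fold plan, and a config fingerprint.
#' @seealso [compare_models()], [run_size_sweep()]
#' @export
run_cv <- function(data, spec = mdbn_spec(), k = 5L, seed = 1L,
                   label = "group", fold_plan = NULL) {
  parts <- peaks_split(data, label = label)
  if (is.null(parts$labels)) abort(sprintf("No label column '%s' in `data`.", label))
  plan <- fold_plan %||% stratified_kfold(parts$labels, k, seed)
  stopifnot(inherits(plan, "fold_plan"))
  class_order <- sort(unique(parts$labels))

  rows <- vector("list", plan$k)
  traces <- vector("list", plan$k)
  norm_fps <- character(plan$k)
  for (f in seq_len(plan$k)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(parts$labels), test_idx)
    fold_seed <- derive_seed(seed, 100L + f)
    if (inherits(spec, "mdbn_spec")) {
      model <- mdbn_fit_matrix(parts$X[train_idx, , drop = FALSE],
                               parts$labels[train_idx], spec, class_order,
                               fold_seed,
                               X_test = parts$X[test_idx, , drop = FALSE],
                               y_test = parts$labels[test_idx])
      pred <- mdbn_predict_matrix(model, parts$X[test_idx, , drop = FALSE])
      traces[[f]] <- dplyr::mutate(model$trace, fold = f, .before = 1L)
      norm_fps[f] <- fingerprint(list(min = model$normalizer$min,
                                      max = model$normalizer$max))
    } else if (inherits(spec, "baseline_spec")) {
      state <- structure(
        list(min = apply(parts$X[train_idx, , drop = FALSE], 2, min),
             max = apply(parts$X[train_idx, , drop = FALSE], 2, max),
             variable_ids = parts$variable_ids,
             fitted_on_n = length(train_idx)),
        class = "minmax_normalizer")
      Xn_train <- normalize_matrix(parts$X[train_idx, , drop = FALSE], state)
      Xn_test <- normalize_matrix(parts$X[test_idx, , drop = FALSE], state)
      pred <- baseline_predict(spec, Xn_train, parts$labels[train_idx],
                               Xn_test, fold_seed)
      norm_fps[f] <- fingerprint(list(min = state$min, max = state$max))
    } else {
      abort("`spec` must be an mdbn_spec or a baseline_spec.")
    }
    rows[[f]] <- tibble(fold = f, n_train = length(train_idx),
                        n_test = length(test_idx),
                        accuracy = accuracy_percent(pred,
                                                    parts$labels[test_idx]))
  }
  folds_tbl <- dplyr::bind_rows(rows)
  structure(
    list(model_name = model_name(spec),
         fold_results = folds_tbl,
         mean_accuracy = round_half_up(mean(folds_tbl$accuracy), 2),
         traces = if (inherits(spec, "mdbn_spec")) dplyr::bind_rows(traces),
         normalizer_fingerprints = norm_fps,
         fold_plan = plan,
         config_fingerprint = fingerprint(list(model = model_name(spec),
                                               spec = unclass(spec),
                                               k = plan$k, seed = seed))),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean accuracy %.2f%% over %d folds\n",
              x$model_name, x$mean_accuracy, nrow(x$fold_results)))
  print(x$fold_results)
  invisible(x)
}

#' @describeIn run_cv Per-fold accuracies as a tibble.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::mutate(x$fold_results, model = x$model_name, .before = 1L)
}

#' @describeIn run_cv One-row summary with the mean accuracy.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(model = x$model_name,
         k = nrow(x$fold_results),
         mean_accuracy = x$mean_accuracy,
         min_accuracy = min(x$fold_results$accuracy),
         max_accuracy = max(x$fold_results$accuracy))
}

#' @describeIn run_cv Plot per-fold FMSE/FMR/TMR traces (DBN models only).
#' @param object A `cv_report`.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  if (is.null(object$traces)) {
    abort("No traces stored (baseline reports have none).")
  }
  df <- tidyr::pivot_longer(object$traces, c("fmse", "fmr", "tmr"),
                            names_to = "metric", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fold, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "fine-tuning iteration", y = "error", colour = NULL,
                  title = sprintf("%s cross-validation traces",
                                  object$model_name)) +
    ggplot2::theme_minimal()
}

#' Side-by-side comparison of cross-validation reports
#'
#' Assembles the conventional accuracy table: one row per fold plus a
#' `Mean` row (recomputed from the per-fold cells under the same rounding),
#' one column per model. All reports must share an identical fold plan.
#' The best model per row is recorded in the `best` column.
#'
#' @param reports List of `cv_report` objects from [run_cv()].
#' @return A tibble with columns `group` (fold index or `"Mean"`), one
#'   accuracy column per model, and `best`.
#' @export
compare_models <- function(reports) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "cv_report")))
  fps <- vapply(reports, function(r) r$fold_plan$fingerprint, character(1))
  if (length(unique(fps)) != 1L) {
    abort("Reports do not share the same fold plan; refit with a common `fold_plan`.")
  }
  cols <- lapply(reports, function(r) {
    accs <- r$fold_results$accuracy
    c(accs, round_half_up(mean(accs), 2))
  })
  names(cols) <- vapply(reports, function(r) r$model_name, character(1))
  out <- dplyr::bind_cols(
    tibble(group = c(as.character(seq_len(nrow(reports[[1]]$fold_results))),
                     "Mean")),
    as_tibble(cols))
  acc <- as.matrix(out[-1])
  out$best <- colnames(acc)[max.col(acc, ties.method = "first")]
  out
}

#' Accuracy as a function of training-set size
#'
#' For each requested training size, draws one stratified random split of
#' that size (the complement is the test set), trains each model spec once,
#' and tabulates test accuracy against size — the design used to study how
#' much labelled data each classifier needs (sizes 50, 60, ..., 120 out of
#' 168 in the canonical setup). DBN traces are retained as an attribute.
#'
#' @param data A labelled peaks tibble.
#' @param specs A single spec or list of [mdbn_spec()] / [baseline_spec()].
#' @param train_sizes Integer vector of training-set sizes.
#' @param seed Integer seed.
#' @param label Name of the label column.
#' @return A tibble with columns `train_size`, `test_size`, one accuracy
#'   column per model; per-run DBN traces in `attr(, "traces")`.
#' @export
run_size_sweep <- function(data, specs = list(mdbn_spec()),
                           train_sizes = seq(50L, 120L, by = 10L),
                           seed = 1L, label = "group") {
  if (inherits(specs, c("mdbn_spec", "baseline_spec"))) specs <- list(specs)
  parts <- peaks_split(data, label = label)
  if (is.null(parts$labels)) abort(sprintf("No label column '%s' in `data`.", label))
  n <- length(parts$labels)
  classes <- sort(unique(parts$labels))
  if (any(train_sizes >= n)) abort("Every training size must be < n_samples.")
  if (any(train_sizes < length(classes))) {
    abort("Training sizes too small to represent every class.")
  }
  class_order <- classes

  rows <- list()
  traces <- list()
  for (si in seq_along(train_sizes)) {
    size <- train_sizes[si]
    restore <- .Random.seed_guard(derive_seed(seed, 200L + si))
    # stratified draw: per-class quota proportional to class frequency,
    # remainder to the largest fractional parts
    quota_raw <- size * table(parts$labels)[classes] / n
    quota <- floor(quota_raw)
    rem <- size - sum(quota)
    if (rem > 0) {
      up <- order(quota_raw - quota, decreasing = TRUE)[seq_len(rem)]
      quota[up] <- quota[up] + 1
    }
    train_idx <- unlist(lapply(seq_along(classes), function(ci) {
      sample(which(parts$labels == classes[ci]), quota[ci])
    }))
    restore()
    test_idx <- setdiff(seq_len(n), train_idx)

    acc <- setNames(numeric(length(specs)),
                    vapply(specs, model_name, character(1)))
    for (mi in seq_along(specs)) {
      spec <- specs[[mi]]
      run_seed <- derive_seed(seed, 300L + si * 31L + mi)
      if (inherits(spec, "mdbn_spec")) {
        model <- mdbn_fit_matrix(parts$X[train_idx, , drop = FALSE],
                                 parts$labels[train_idx], spec, class_order,
                                 run_seed,
                                 X_test = parts$X[test_idx, , drop = FALSE],
                                 y_test = parts$labels[test_idx])
        pred <- mdbn_predict_matrix(model, parts$X[test_idx, , drop = FALSE])
        traces[[length(traces) + 1L]] <-
          dplyr::mutate(model$trace, train_size = size,
                        model = spec$name, .before = 1L)
      } else {
        state <- structure(
          list(min = apply(parts$X[train_idx, , drop = FALSE], 2, min),
               max = apply(parts$X[train_idx, , drop = FALSE], 2, max),
               variable_ids = parts$variable_ids,
               fitted_on_n = length(train_idx)),
          class = "minmax_normalizer")
        pred <- baseline_predict(
          spec,
          normalize_matrix(parts$X[train_idx, , drop = FALSE], state),
          parts$labels[train_idx],
          normalize_matrix(parts$X[test_idx, , drop = FALSE], state),
          run_seed)
      }
      acc[mi] <- accuracy_percent(pred, parts$labels[test_idx])
    }
    rows[[si]] <- dplyr::bind_cols(
      tibble(train_size = size, test_size = n - size),
      as_tibble(as.list(acc)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "traces") <- if (length(traces)) dplyr::bind_rows(traces)
  out
}
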