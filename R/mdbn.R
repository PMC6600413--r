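# End-to-end model: min-max normalisation -> greedy RBM pretraining ->
# softmax-head training on frozen features -> joint fine-tuning.

#' Model specification for the DBN + softmax classifier
#'
#' Bundles every tunable of the pipeline. Defaults follow common practice
#' for full-batch training of peak-matrix classifiers: CD-1 pretraining with
#' learning rate 0.1 and Gaussian init scale 0.01, dropout 0.2 during
#' pretraining and 0.5 during fine-tuning, weight decay 1e-4, an L-BFGS
#' budget of 300 iterations (5000 for plain gradient descent).
#'
#' @param hidden Integer vector of hidden-layer widths (e.g. `c(500, 100)`
#'   for a 2889-500-100-3 network on 2889 input variables and 3 classes).
#' @param pretrain_epochs Full-batch CD-1 sweeps per RBM.
#' @param pretrain_rate CD learning rate.
#' @param pretrain_dropout Hidden-unit dropout rate during pretraining.
#' @param weight_init_scale SD of the Gaussian weight initialiser.
#' @param finetune_method `"lbfgs"` or `"gd"`.
#' @param finetune_iterations Fine-tuning iteration cap; `NULL` picks the
#'   conventional budget for the method (300 L-BFGS, 5000 GD).
#' @param learning_rate GD step size.
#' @param weight_decay L2 coefficient on weights.
#' @param finetune_dropout Hidden-unit dropout rate during fine-tuning.
#' @param head_iterations L-BFGS iterations for softmax-head pretraining.
#' @param lbfgs_history,tolerance L-BFGS memory and stopping tolerance.
#' @param trace_every Trace thinning interval (see [finetune_config()]).
#' @param name Display name used in reports; defaults to
#'   `"DBN+L-BFGS+Softmax"` or `"DBN+GD+Softmax"`.
#' @return An object of class `mdbn_spec`.
#' @seealso [mdbn()], [run_cv()]
#' @export
mdbn_spec <- function(hidden = c(32, 16),
                      pretrain_epochs = 100L, pretrain_rate = 0.1,
                      pretrain_dropout = 0.2, weight_init_scale = 0.01,
                      finetune_method = c("lbfgs", "gd"),
                      finetune_iterations = NULL,
                      learning_rate = 0.1, weight_decay = 1e-4,
                      finetune_dropout = 0.5, head_iterations = 100L,
                      lbfgs_history = 20L, tolerance = 1e-6,
                      trace_every = 1L, name = NULL) {
  finetune_method <- match.arg(finetune_method)
  finetune_iterations <- finetune_iterations %||%
    if (finetune_method == "lbfgs") 300L else 5000L
  name <- name %||%
    if (finetune_method == "lbfgs") "DBN+L-BFGS+Softmax" else "DBN+GD+Softmax"
  structure(list(hidden = as.integer(hidden),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_rate = pretrain_rate,
                 pretrain_dropout = pretrain_dropout,
                 weight_init_scale = weight_init_scale,
                 finetune_method = finetune_method,
                 finetune_iterations = as.integer(finetune_iterations),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 finetune_dropout = finetune_dropout,
                 head_iterations = as.integer(head_iterations),
                 lbfgs_history = as.integer(lbfgs_history),
                 tolerance = tolerance,
                 trace_every = as.integer(trace_every),
                 name = name),
            class = "mdbn_spec")
}

#' @export
print.mdbn_spec <- function(x, ...) {
  cat(sprintf("<mdbn_spec> %s, hidden %s, pretrain %d epochs, finetune %d iter\n",
              x$name, paste(x$hidden, collapse = "-"),
              x$pretrain_epochs, x$finetune_iterations))
  invisible(x)
}

# Matrix-level fit shared by mdbn(), run_cv() and run_size_sweep().
# X_* are raw (unnormalised) intensity matrices; the normaliser is fitted
# on the training rows only.
mdbn_fit_matrix <- function(X_train, y_train, spec, class_order, seed,
                            X_test = NULL, y_test = NULL) {
  state <- structure(list(min = apply(X_train, 2, min),
                          max = apply(X_train, 2, max),
                          variable_ids = colnames(X_train),
                          fitted_on_n = nrow(X_train)),
                     class = "minmax_normalizer")
  Xn <- normalize_matrix(X_train, state)
  Y <- one_hot(y_train, class_order)
  Xt <- if (!is.null(X_test)) normalize_matrix(X_test, state)
  Yt <- if (!is.null(y_test)) one_hot(y_test, class_order)

  cd <- cd_config(learning_rate = spec$pretrain_rate,
                  epochs = spec$pretrain_epochs,
                  dropout_rate = spec$pretrain_dropout,
                  seed = derive_seed(seed, 1L),
                  weight_init_scale = spec$weight_init_scale)
  dbn <- dbn_pretrain(Xn, c(ncol(Xn), spec$hidden), cd)

  features <- dbn_forward(dbn, Xn)
  head_par <- train_softmax_head(features, Y, lambda = spec$weight_decay,
                                 iterations = spec$head_iterations,
                                 seed = derive_seed(seed, 2L))
  model <- structure(
    list(dbn = dbn, softmax = head_par, dropout_rate = spec$finetune_dropout,
         class_order = class_order, normalizer = state, spec = spec,
         seed = as.integer(seed), trace = NULL),
    class = "mdbn")

  ft <- finetune_config(method = spec$finetune_method,
                        iterations = spec$finetune_iterations,
                        learning_rate = spec$learning_rate,
                        weight_decay = spec$weight_decay,
                        lbfgs_history = spec$lbfgs_history,
                        tolerance = spec$tolerance,
                        dropout_rate = spec$finetune_dropout,
                        trace_every = spec$trace_every,
                        seed = derive_seed(seed, 3L))
  finetune(model, Xn, Y, Xt, Yt, ft)$model
}

# Inference-mode predictions from a fitted model and a raw intensity matrix.
mdbn_predict_matrix <- function(model, X, type = "class") {
  Xn <- normalize_matrix(X, model$normalizer)
  feats <- dbn_forward(model$dbn, Xn,
                       dropout_spec(model$dropout_rate, "inference"))
  P <- softmax_probs(model$softmax, feats)
  colnames(P) <- model$class_order
  if (type == "prob") return(P)
  model$class_order[max.col(P, ties.method = "first")]
}

#' Fit the DBN + softmax classifier on a peaks tibble
#'
#' Runs the full pipeline on labelled data: fit a per-variable min-max
#' normaliser, pretrain the RBM stack with CD-1 on the (unlabelled)
#' normalised intensities, train the softmax head on the frozen top-layer
#' features, then jointly fine-tune every parameter. When `test_data` is
#' supplied its misclassification rate is traced per iteration (it never
#' influences the fit).
#'
#' @param data A peaks tibble with a label column (see [generate_peaks()] or
#'   [read_peak_matrix()]).
#' @param spec An [mdbn_spec()].
#' @param label Name of the label column.
#' @param class_order Optional class order (defaults to sorted labels);
#'   fixes the softmax column order and the prediction tie-break.
#' @param test_data Optional held-out peaks tibble for the TMR trace.
#' @param seed Integer seed; the whole fit is a pure function of
#'   `(data, spec, seed)`.
#' @return An object of class `mdbn` with the pretrained-and-tuned stack,
#'   softmax head, normaliser, class order and fine-tuning `trace`.
#' @examples
#' \donttest{
#' peaks <- generate_peaks(synthetic_config(n_per_class = 10, n_variables = 40,
#'                                          n_informative = 10, seed = 7))
#' fit <- mdbn(peaks, mdbn_spec(hidden = c(8, 4), pretrain_epochs = 20,
#'                              finetune_iterations = 50), seed = 7)
#' glance(fit)
#' }
#' @export
mdbn <- function(data, spec = mdbn_spec(), label = "group",
                 class_order = NULL, test_data = NULL, seed = 1L) {
  stopifnot(inherits(spec, "mdbn_spec"))
  parts <- peaks_split(data, label = label)
  if (is.null(parts$labels)) abort(sprintf("No label column '%s' in `data`.", label))
  class_order <- class_order %||% sort(unique(parts$labels))
  tp <- if (!is.null(test_data)) peaks_split(test_data, label = label)
  model <- mdbn_fit_matrix(parts$X, parts$labels, spec, class_order, seed,
                           X_test = tp$X, y_test = tp$labels)
  model$label <- label
  model$n_train <- nrow(parts$X)
  model
}

#' @export
print.mdbn <- function(x, ...) {
  cat(sprintf("<mdbn> %s: %s-%d network, classes {%s}\n",
              x$spec$name,
              paste(x$dbn$layer_sizes, collapse = "-"),
              length(x$class_order),
              paste(x$class_order, collapse = ", ")))
  if (!is.null(x$trace) && nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final cost %.4g, training error %.3f after %d iterations\n",
                last$cost, last$fmr, last$iteration))
  }
  invisible(x)
}

#' Predict group labels for new samples
#'
#' Applies the stored normaliser, runs the inference-mode forward pass
#' (dropout compensated by activation scaling, no mask sampling) and takes
#' the per-row argmax of the softmax probabilities, ties broken toward the
#' earliest class in `class_order`.
#'
#' @param object A fitted [mdbn()] model.
#' @param new_data A peaks tibble with the training variables.
#' @param type `"class"` for hard labels, `"prob"` for class probabilities.
#' @param ... Unused.
#' @return A tibble: `sample_id` plus `.pred_class`, or one `.pred_<class>`
#'   probability column per class.
#' @export
predict.mdbn <- function(object, new_data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  parts <- peaks_split(new_data, label = object$label %||% "group")
  if (!identical(parts$variable_ids, object$normalizer$variable_ids)) {
    abort("`new_data` variables do not match the training variables.")
  }
  if (type == "class") {
    tibble(sample_id = parts$sample_ids,
           .pred_class = mdbn_predict_matrix(object, parts$X))
  } else {
    P <- mdbn_predict_matrix(object, parts$X, type = "prob")
    colnames(P) <- paste0(".pred_", object$class_order)
    dplyr::bind_cols(tibble(sample_id = parts$sample_ids), as_tibble(P))
  }
}

#' @describeIn mdbn Tidy the fine-tuning trace into a long tibble
#'   (`iteration`, `metric`, `value`) with metrics `cost`, `fmse` (training
#'   mean squared error), `fmr` (training misclassification rate) and `tmr`
#'   (test misclassification rate).
#' @param x,object A fitted `mdbn` model.
#' @param ... Unused.
#' @method tidy mdbn
#' @export
tidy.mdbn <- function(x, ...) {
  tidyr::pivot_longer(x$trace, -"iteration",
                      names_to = "metric", values_to = "value")
}

#' @describeIn mdbn One-row model summary: architecture, method, iterations
#'   run, final cost and final training/test error rates.
#' @method glance mdbn
#' @export
glance.mdbn <- function(x, ...) {
  last <- if (!is.null(x$trace) && nrow(x$trace)) x$trace[nrow(x$trace), ] else
    tibble(iteration = 0L, cost = NA_real_, fmse = NA_real_,
           fmr = NA_real_, tmr = NA_real_)
  tibble(model = x$spec$name,
         architecture = paste(c(x$dbn$layer_sizes, length(x$class_order)),
                              collapse = "-"),
         method = x$spec$finetune_method,
         iterations = last$iteration,
         final_cost = last$cost, final_fmse = last$fmse,
         final_fmr = last$fmr, final_tmr = last$tmr)
}

#' @describeIn mdbn Plot the fine-tuning trace (FMSE, FMR and TMR against
#'   iteration), the standard convergence diagnostic.
#' @method autoplot mdbn
#' @export
autoplot.mdbn <- function(object, ...) {
  df <- tidy.mdbn(object)
  df <- df[df$metric %in% c("fmse", "fmr", "tmr") & !is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fine-tuning iteration", y = "error",
                  colour = NULL,
                  title = sprintf("%s fine-tuning trace", object$spec$name)) +
    ggplot2::theme_minimal()
}
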