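# Deep belief network: greedy layer-wise pretraining and feed-forward
# feature extraction with dropout.

#' Dropout specification
#'
#' Dropout multiplies a hidden layer's activation vector by a random 0/1
#' unit mask during training; at inference no units are dropped and the
#' activations are scaled by `1 - rate` so their expectation is preserved.
#' Masks are per-unit vectors shared across the batch.
#'
#' @param rate Drop probability in `[0, 1)`.
#' @param mode `"train"` (sample masks) or `"inference"` (scale).
#' @return A list of class `dropout_spec`.
#' @export
dropout_spec <- function(rate = 0, mode = c("inference", "train")) {
  assert_scalar_number(rate, "rate", lower = 0, upper = 1 - 1e-12)
  structure(list(rate = rate, mode = match.arg(mode)), class = "dropout_spec")
}

#' Apply dropout to an activation matrix
#'
#' Train mode: elementwise product with a Bernoulli(`1 - rate`) 0/1 unit
#' mask (one draw per column, shared across rows), consuming the global RNG.
#' Inference mode: multiply by `1 - rate`.
#'
#' @param activations Numeric matrix (rows = samples, columns = units).
#' @param spec A [dropout_spec()].
#' @param mask Optional fixed 0/1 vector overriding the sampled mask.
#' @return The masked (or scaled) matrix; the mask used (if any) is attached
#'   as attribute `"mask"`.
#' @export
apply_dropout_mask <- function(activations, spec, mask = NULL) {
  stopifnot(inherits(spec, "dropout_spec"))
  if (spec$rate == 0) return(activations)
  if (spec$mode == "inference") return(activations * (1 - spec$rate))
  mask <- mask %||% sample_bernoulli(rep(1 - spec$rate, ncol(activations)))
  out <- sweep(activations, 2, mask, "*")
  attr(out, "mask") <- mask
  out
}

#' Greedy layer-wise pretraining of a DBN
#'
#' Trains a stack of RBMs: the first on the (unit-interval) data, each
#' subsequent RBM on the hidden-probability outputs of the one below
#' (mean-field stacking, so every layer sees deterministic inputs). The
#' trained weights initialise the feed-forward network that fine-tuning
#' then optimises. Layer `l`'s RBM is seeded from `config$seed` and the
#' layer index, so the whole stack is reproducible.
#'
#' @param data Matrix in `[0, 1]` (rows = samples) whose column count equals
#'   `layer_sizes[1]`.
#' @param layer_sizes Integer vector: visible dimension followed by the
#'   hidden-layer widths (e.g. `c(2889, 500, 100)`; a softmax head of k
#'   classes is attached separately and is not an RBM).
#' @param config A [cd_config()] used for every layer.
#' @return An object of class `dbn_model`: `layer_sizes`, `rbms` (list of
#'   `rbm_params`), and `traces` (per-layer reconstruction-error tibbles).
#' @seealso [dbn_forward()], [train_rbm()]
#' @export
dbn_pretrain <- function(data, layer_sizes, config = cd_config()) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (length(layer_sizes) < 2L) abort("Need at least one hidden layer.")
  if (any(layer_sizes < 1L)) abort("All layer sizes must be >= 1.")
  if (ncol(data) != layer_sizes[1]) {
    abort(sprintf("Data has %d variables but layer_sizes[1] is %d.",
                  ncol(data), layer_sizes[1]))
  }
  rbms <- vector("list", length(layer_sizes) - 1L)
  traces <- vector("list", length(rbms))
  input <- data
  for (l in seq_along(rbms)) {
    layer_config <- config
    layer_config$seed <- derive_seed(config$seed, l)
    fit <- train_rbm(input, layer_sizes[l + 1L], layer_config)
    rbms[[l]] <- fit$params
    traces[[l]] <- fit$trace
    input <- hidden_probs(fit$params, input)
  }
  structure(list(layer_sizes = as.integer(layer_sizes), rbms = rbms,
                 traces = traces),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("<dbn_model> layers %s (%d RBM(s))\n",
              paste(x$layer_sizes, collapse = "-"), length(x$rbms)))
  invisible(x)
}

#' Feed-forward pass through a DBN
#'
#' Composes [hidden_probs()] through every layer. In train mode each hidden
#' layer's output is multiplied by a fresh per-unit dropout mask; in
#' inference mode activations are scaled by `1 - rate` instead.
#'
#' @param model A `dbn_model`.
#' @param data Matrix whose column count equals the visible dimension.
#' @param dropout A [dropout_spec()]; the default applies no dropout.
#' @param masks Optional list of fixed 0/1 mask vectors, one per hidden
#'   layer (train mode only).
#' @return The top-layer activation matrix (rows = samples).
#' @export
dbn_forward <- function(model, data, dropout = dropout_spec(), masks = NULL) {
  stopifnot(inherits(model, "dbn_model"))
  H <- as_batch(data, model$layer_sizes[1])
  if (ncol(H) != model$layer_sizes[1]) {
    abort(sprintf("Data has %d variables; DBN expects %d.",
                  ncol(H), model$layer_sizes[1]))
  }
  for (l in seq_along(model$rbms)) {
    H <- hidden_probs(model$rbms[[l]], H)
    H <- apply_dropout_mask(H, dropout, mask = if (!is.null(masks)) masks[[l]])
    attr(H, "mask") <- NULL
  }
  H
}
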