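# Versioned JSON serialisation of fitted models. Arrays are stored with
# explicit shapes so files are portable and human-inspectable.

serialize_version <- "1"

mat_to_list <- function(M) list(dim = dim(M), data = as.numeric(M))
list_to_mat <- function(l) matrix(l$data, l$dim[1], l$dim[2])

#' Write a fitted model to a JSON container
#'
#' Stores layer sizes, every RBM's weights and biases, the softmax head,
#' the min-max normaliser, class order and dropout rate, with a format
#' version tag.
#'
#' @param model A fitted [mdbn()] model.
#' @param path Output file path.
#' @return `model`, invisibly.
#' @seealso [read_mdbn()]
#' @export
write_mdbn <- function(model, path) {
  stopifnot(inherits(model, "mdbn"))
  obj <- list(
    format = "metabodbn-model", version = serialize_version,
    layer_sizes = model$dbn$layer_sizes,
    rbms = lapply(model$dbn$rbms, function(r)
      list(W = mat_to_list(r$W), a = r$a, b = r$b)),
    softmax = list(W = mat_to_list(model$softmax$W), b = model$softmax$b),
    dropout_rate = model$dropout_rate,
    class_order = model$class_order,
    label = model$label %||% "group",
    normalizer = list(min = as.numeric(model$normalizer$min),
                      max = as.numeric(model$normalizer$max),
                      variable_ids = model$normalizer$variable_ids,
                      fitted_on_n = model$normalizer$fitted_on_n))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' Read a model written by [write_mdbn()]
#'
#' @param path Path to the JSON container.
#' @return An `mdbn` model usable with [predict.mdbn()].
#' @export
read_mdbn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "metabodbn-model")) {
    abort("Not a metabodbn model container.")
  }
  rbms <- lapply(seq_along(obj$layer_sizes[-1]), function(l) {
    r <- obj$rbms[[l]]
    structure(list(W = list_to_mat(r$W), a = as.numeric(r$a),
                   b = as.numeric(r$b)),
              class = "rbm_params")
  })
  dbn <- structure(list(layer_sizes = as.integer(obj$layer_sizes),
                        rbms = rbms, traces = NULL),
                   class = "dbn_model")
  norm <- structure(list(min = setNames(as.numeric(obj$normalizer$min),
                                        obj$normalizer$variable_ids),
                         max = setNames(as.numeric(obj$normalizer$max),
                                        obj$normalizer$variable_ids),
                         variable_ids = obj$normalizer$variable_ids,
                         fitted_on_n = obj$normalizer$fitted_on_n),
                    class = "minmax_normalizer")
  structure(list(dbn = dbn,
                 softmax = list(W = list_to_mat(obj$softmax$W),
                                b = as.numeric(obj$softmax$b)),
                 dropout_rate = obj$dropout_rate,
                 class_order = obj$class_order,
                 label = obj$label,
                 normalizer = norm,
                 spec = mdbn_spec(hidden = as.integer(obj$layer_sizes[-1])),
                 trace = NULL),
            class = "mdbn")
}
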