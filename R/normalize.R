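#' Fit a per-variable min-max normaliser
#'
#' Records each variable's minimum and maximum over the supplied (training)
#' samples. RBM visible units are sigmoid-valued, so intensities are mapped
#' to the unit interval before pretraining; fitting on training folds only
#' and re-applying to test folds prevents test-set leakage.
#'
#' @param data A peaks tibble (see [read_peak_matrix()]).
#' @param label Name of the label column to ignore, if present.
#' @return An object of class `minmax_normalizer` with fields `min`, `max`
#'   (named numeric vectors over variables) and `fitted_on_n`.
#' @seealso [apply_normalizer()]
#' @export
fit_normalizer <- function(data, label = "group") {
  parts <- peaks_split(data, label = label)
  if (nrow(parts$X) < 1L) abort("Cannot fit a normaliser on an empty matrix.")
  structure(
    list(min = apply(parts$X, 2, min),
         max = apply(parts$X, 2, max),
         variable_ids = parts$variable_ids,
         fitted_on_n = nrow(parts$X)),
    class = "minmax_normalizer")
}

#' Apply a fitted min-max normaliser
#'
#' Maps each intensity to `(x - min_j) / (max_j - min_j)` using the training
#' extremes stored in `state`, then clips to `[0, 1]` so out-of-range test
#' values stay valid sigmoid inputs. Variables constant in training
#' (`max == min`) map to 0.
#'
#' @param data A peaks tibble with the same variables the normaliser was
#'   fitted on.
#' @param state A `minmax_normalizer` from [fit_normalizer()].
#' @param label Name of the label column to pass through untouched.
#' @return A tibble of the same shape with all intensities in `[0, 1]`.
#' @export
apply_normalizer <- function(data, state, label = "group") {
  stopifnot(inherits(state, "minmax_normalizer"))
  parts <- peaks_split(data, label = label)
  if (!identical(parts$variable_ids, state$variable_ids)) {
    if (length(parts$variable_ids) != length(state$variable_ids)) {
      abort(sprintf("Variable count mismatch: data has %d, normaliser was fitted on %d.",
                    length(parts$variable_ids), length(state$variable_ids)))
    }
    abort("Variable IDs do not match the normaliser's training variables.")
  }
  X <- normalize_matrix(parts$X, state)
  peaks_build(X, parts$sample_ids, parts$variable_ids, parts$labels, label)
}

# Matrix-level kernel shared with the CV driver.
normalize_matrix <- function(X, state) {
  rng <- state$max - state$min
  scale <- ifelse(rng > 0, 1 / rng, 0)          # constant variables -> 0
  X <- sweep(X, 2, state$min, "-")
  X <- sweep(X, 2, scale, "*")
  X[X < 0] <- 0
  X[X > 1] <- 1
  X
}

#' @export
print.minmax_normalizer <- function(x, ...) {
  cat(sprintf("<minmax_normalizer> %d variables, fitted on %d samples\n",
              length(x$min), x$fitted_on_n))
  invisible(x)
}
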