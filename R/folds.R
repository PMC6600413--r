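#' Build a stratified k-fold plan
#'
#' Splits sample indices into `k` folds whose sizes differ by at most one and
#' whose per-class counts differ by at most one across folds, so every fold
#' mirrors the overall class balance (56/56/56 for the canonical three-group
#' design: 168 samples split 5-fold gives fold sizes 34, 34, 34, 33, 33 and
#' train/test splits of 134/34 or 135/33). Within each class the members are
#' shuffled with the given seed and dealt out in near-equal chunks; the
#' remainder slots rotate across folds starting from the earliest so the
#' overall fold sizes stay near-equal too.
#'
#' @param labels Character or factor vector of class labels, one per sample.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the plan is a pure function of
#'   `(labels, k, seed)`.
#' @return An object of class `fold_plan`: list with `k`, `folds` (list of
#'   integer index vectors), `seed`, and `fingerprint`.
#' @examples
#' plan <- stratified_kfold(rep(c("CG", "MG", "RG"), each = 56), k = 5, seed = 1)
#' lengths(plan$folds)
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k != round(k)) {
    abort("`k` must be a single integer >= 2.")
  }
  k <- as.integer(k)
  counts <- table(labels)
  short <- names(counts)[counts < k]
  if (length(short)) {
    abort(sprintf("Class '%s' has only %d member(s); need at least k = %d per class.",
                  short[1], counts[[short[1]]], k))
  }
  folds <- vector("list", k)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  offset <- 0L  # rotating start for remainder slots, across classes
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    base <- n_c %/% k
    extra <- n_c %% k
    sizes <- rep(base, k)
    if (extra > 0) {
      take <- ((offset + seq_len(extra) - 1L) %% k) + 1L
      sizes[take] <- sizes[take] + 1L
      offset <- (offset + extra) %% k
    }
    at <- 0L
    for (f in seq_len(k)) {
      if (sizes[f] > 0) {
        folds[[f]] <- c(folds[[f]], idx[at + seq_len(sizes[f])])
        at <- at + sizes[f]
      }
    }
  }
  folds <- lapply(folds, sort)
  structure(
    list(k = k, folds = folds, seed = as.integer(seed),
         fingerprint = fingerprint(list(k = k, seed = seed, n = n,
                                        counts = as.list(counts)))),
    class = "fold_plan")
}

# Seed the global RNG reproducibly and return a restorer.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, seed = %d, fold sizes: %s\n",
              x$k, x$seed, paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}

#' @describeIn stratified_kfold Tidy a fold plan into a tibble with one row
#'   per sample (`sample`, `fold`).
#' @param x A `fold_plan`.
#' @param ... Unused.
#' @method tidy fold_plan
#' @export
tidy.fold_plan <- function(x, ...) {
  tibble(sample = unlist(x$folds),
         fold = rep(seq_len(x$k), lengths(x$folds))) |>
    dplyr::arrange(.data$sample)
}

#' Serialise a fold plan to JSON
#'
#' Writes a mapping from fold index to sample IDs.
#'
#' @param plan A `fold_plan`.
#' @param sample_ids Character vector of sample IDs the fold indices refer to.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when `path` is given).
#' @export
fold_plan_json <- function(plan, sample_ids, path = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  obj <- list(k = plan$k, seed = plan$seed,
              folds = setNames(
                lapply(plan$folds, function(i) sample_ids[i]),
                paste0("fold", seq_len(plan$k))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
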