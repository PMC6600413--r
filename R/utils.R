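# Shared internal helpers: rounding, seeds, fingerprints, matrix <-> tibble.

# Round half away from zero, matching how accuracy tables are conventionally
# printed (94.117... -> 94.12); base round() is round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stream of child seeds from one base seed, each < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 10007) %% 2147483647)
}

# Canonical human-readable fingerprint of a (possibly nested) config list.
fingerprint <- function(x) {
  flat <- unlist(x, use.names = TRUE)
  paste(names(flat), vapply(flat, format, character(1), digits = 15),
        sep = "=", collapse = ";")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Split a peaks tibble into its numeric matrix, labels and identifiers.
# Convention: `sample_id` column (created if absent), one optional label
# column, all remaining columns numeric feature intensities.
peaks_split <- function(data, label = "group") {
  if (!is.data.frame(data)) abort("`data` must be a data frame of peak intensities.")
  data <- as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    data <- dplyr::mutate(data,
      sample_id = sprintf("S%03d", seq_len(nrow(data))), .before = 1L)
  }
  labels <- NULL
  if (!is.null(label) && label %in% names(data)) {
    labels <- as.character(data[[label]])
    feature_cols <- setdiff(names(data), c("sample_id", label))
  } else {
    feature_cols <- setdiff(names(data), "sample_id")
  }
  non_num <- feature_cols[!vapply(data[feature_cols], is.numeric, logical(1))]
  if (length(non_num)) {
    abort(sprintf("Non-numeric feature column(s): %s.",
                  paste(head(non_num, 5), collapse = ", ")))
  }
  X <- as.matrix(data[feature_cols])
  rownames(X) <- data$sample_id
  list(X = X, labels = labels, sample_ids = data$sample_id,
       variable_ids = feature_cols)
}

# Rebuild a peaks tibble from a matrix plus identifiers.
peaks_build <- function(X, sample_ids, variable_ids, labels = NULL,
                        label = "group") {
  out <- as_tibble(as.data.frame(X))
  names(out) <- variable_ids
  out <- dplyr::bind_cols(tibble(sample_id = sample_ids), out)
  if (!is.null(labels)) {
    out <- dplyr::mutate(out, !!label := labels, .after = "sample_id")
  }
  out
}
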