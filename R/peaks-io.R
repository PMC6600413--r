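#' Read a peak intensity matrix from delimited text
#'
#' Reads an aligned LC-MS peak table (CSV or TSV) into a tibble with one row
#' per sample: a `sample_id` column, an optional group-label column, and one
#' numeric column per aligned m/z--retention-time feature. Missing cells are
#' treated as absent peaks and imputed to 0 (the number of imputations is
#' reported via a message).
#'
#' @param path Path to a delimited text file. The delimiter is taken from the
#'   extension (`.tsv`/`.txt` = tab, otherwise comma).
#' @param orientation `"samples_in_rows"` (default; first column = sample IDs,
#'   header = variable IDs) or `"samples_in_columns"` (the transpose: first
#'   column = variable IDs, header = sample IDs). Output is always
#'   samples-in-rows.
#' @param label_column Optional name of the column holding group labels
#'   (e.g. `"group"` with values CG/MG/RG). Only meaningful for
#'   `samples_in_rows`.
#' @param label_set Optional character vector of admissible labels; any label
#'   outside it is an error naming the offending row.
#' @return A tibble with columns `sample_id`, the label column (if any), and
#'   one non-negative numeric column per variable.
#' @seealso [write_peak_matrix()], [generate_peaks()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,group,85.04_1.2,120.10_3.4",
#'              "S1,CG,100,0", "S2,MG,250,3.5"), tf)
#' read_peak_matrix(tf, label_column = "group")
#' @export
read_peak_matrix <- function(path,
                             orientation = c("samples_in_rows",
                                             "samples_in_columns"),
                             label_column = NULL,
                             label_set = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2L) abort("Malformed header: need an ID column plus at least one variable.")

  if (orientation == "samples_in_columns") {
    variable_ids <- as.character(raw[[1]])
    sample_ids <- names(raw)[-1]
    X <- t(as.matrix(raw[-1]))
    colnames(X) <- variable_ids
    data <- peaks_build(X, sample_ids, variable_ids)
    label_column <- NULL
  } else {
    sample_ids <- as.character(raw[[1]])
    data <- raw
    names(data)[1] <- "sample_id"
    data$sample_id <- sample_ids
  }

  if (anyDuplicated(data$sample_id)) {
    dup <- data$sample_id[duplicated(data$sample_id)][1]
    abort(sprintf("Duplicate sample ID: %s", dup))
  }
  feature_cols <- setdiff(names(data), c("sample_id", label_column))
  if (anyDuplicated(feature_cols)) {
    abort(sprintf("Duplicate variable ID: %s",
                  feature_cols[duplicated(feature_cols)][1]))
  }

  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(data)) {
      abort(sprintf("Label column '%s' not found in header.", label_column))
    }
    labels <- as.character(data[[label_column]])
    if (!is.null(label_set)) {
      bad <- which(!labels %in% label_set)
      if (length(bad)) {
        abort(sprintf("Label '%s' in row %d is outside the declared label set {%s}.",
                      labels[bad[1]], bad[1], paste(label_set, collapse = ", ")))
      }
    }
  }

  vals <- data[feature_cols]
  non_num <- feature_cols[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num)) {
    abort(sprintf("Column '%s' is not numeric; peak intensities must be numbers.",
                  non_num[1]))
  }
  n_missing <- sum(vapply(vals, function(v) sum(is.na(v)), integer(1)))
  if (n_missing > 0) {
    data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(feature_cols),
                                              ~ tidyr::replace_na(.x, 0)))
    inform(sprintf("Imputed %d missing cell(s) to 0 (peak absent).", n_missing))
  }
  for (fc in feature_cols) {
    neg <- which(data[[fc]] < 0)
    if (length(neg)) {
      abort(sprintf("Negative intensity at row %d, column '%s'.", neg[1], fc))
    }
  }
  out <- data[c("sample_id", label_column, feature_cols)]
  attr(out, "n_imputed") <- n_missing
  out
}

#' Write a peak matrix tibble to CSV
#'
#' Inverse of [read_peak_matrix()] (samples-in-rows orientation). Intensities
#' are written at full precision so that a read/write round trip reproduces
#' the tibble exactly.
#'
#' @param data A peaks tibble (`sample_id`, optional label column, numeric
#'   feature columns).
#' @param path Output file path (CSV).
#' @return `data`, invisibly (so the call can sit mid-pipe).
#' @export
write_peak_matrix <- function(data, path) {
  stopifnot(is.data.frame(data))
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(data)
}

#' One-hot encode class labels
#'
#' @param labels Character or factor vector of class labels.
#' @param class_order Character vector fixing the column order; defaults to
#'   the sorted unique labels (reproducible column order).
#' @return An `n x k` 0/1 matrix with one 1 per row and columns named by
#'   `class_order`.
#' @examples
#' one_hot(c("CG", "MG", "RG"), c("CG", "MG", "RG"))
#' @export
one_hot <- function(labels, class_order = NULL) {
  labels <- as.character(labels)
  if (is.null(class_order)) class_order <- sort(unique(labels))
  idx <- match(labels, class_order)
  if (anyNA(idx)) {
    abort(sprintf("Label '%s' not in class_order {%s}.",
                  labels[which(is.na(idx))[1]],
                  paste(class_order, collapse = ", ")))
  }
  Y <- matrix(0, nrow = length(labels), ncol = length(class_order),
              dimnames = list(NULL, class_order))
  Y[cbind(seq_along(labels), idx)] <- 1
  Y
}
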