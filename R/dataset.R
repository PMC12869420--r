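#' Expression datasets
#'
#' Container for an n x p sample-by-feature expression matrix with binary
#' labels. Feature names align positionally with the `node_labels` of any
#' paired [feature_graph()].
#'
#' @param x numeric matrix, samples in rows, features in columns. Column
#'   names are used as feature names (generated as `f1..fp` if absent).
#' @param y binary labels (0/1, logical, or a two-level factor), length
#'   `nrow(x)`. Both classes need not be present at construction time but
#'   model fitting requires them.
#' @param feature_names,sample_ids optional identifier overrides.
#' @return An object of class `expression_dataset` with elements `x`, `y`,
#'   `feature_names`, `sample_ids`.
#' @export
expression_dataset <- function(x, y, feature_names = NULL, sample_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (anyNA(x)) stop("x must not contain missing values")
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  feature_names <- feature_names %||% colnames(x) %||%
    paste0("f", seq_len(ncol(x)))
  sample_ids <- sample_ids %||% rownames(x) %||%
    paste0("s", seq_len(nrow(x)))
  if (length(feature_names) != ncol(x)) stop("feature_names length mismatch")
  if (length(sample_ids) != nrow(x)) stop("sample_ids length mismatch")
  dimnames(x) <- list(sample_ids, feature_names)
  structure(list(x = x, y = y, feature_names = as.character(feature_names),
                 sample_ids = as.character(sample_ids)),
            class = "expression_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d features (%d positives)\n",
              nrow(x$x), ncol(x$x), sum(x$y)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$x)

#' Subset an expression dataset by sample rows
#' @param x an [expression_dataset()].
#' @param i row (sample) indices.
#' @param ... ignored.
#' @export
`[.expression_dataset` <- function(x, i, ...) {
  expression_dataset(x$x[i, , drop = FALSE], x$y[i],
                     feature_names = x$feature_names,
                     sample_ids = x$sample_ids[i])
}

#' Per-feature z-score normalization
#'
#' Centers and scales each feature column using statistics computed from a
#' designated subset of rows (by default all rows), so training-split
#' statistics can be reused on held-out samples without leakage. The scale is
#' the population standard deviation (divide by n) with a floor of `1e-8`,
#' so constant features map to all-zero columns.
#'
#' @param x numeric matrix (samples x features) or [expression_dataset()].
#' @param stats_from row indices used to compute the statistics; defaults to
#'   all rows.
#' @param stats optional precomputed list with `center` and `scale` (as
#'   returned by a previous call); when given, `stats_from` is ignored.
#' @return list with `x` (transformed matrix or dataset), `center`, `scale`.
#' @examples
#' zscore_normalize(matrix(c(1, 2, 3), ncol = 1))$x
#' @export
zscore_normalize <- function(x, stats_from = NULL, stats = NULL) {
  ds <- NULL
  if (inherits(x, "expression_dataset")) {
    ds <- x
    x <- ds$x
  }
  if (is.null(stats)) {
    stats_from <- stats_from %||% seq_len(nrow(x))
    if (!length(stats_from)) stop("stats_from must select at least one row")
    xs <- x[stats_from, , drop = FALSE]
    center <- colMeans(xs)
    scale <- sqrt(colMeans(sweep(xs, 2L, center)^2))
    scale <- pmax(scale, 1e-8)
  } else {
    center <- stats$center
    scale <- stats$scale
  }
  z <- sweep(sweep(x, 2L, center), 2L, scale, `/`)
  if (!is.null(ds)) {
    ds$x <- z
    dimnames(ds$x) <- list(ds$sample_ids, ds$feature_names)
    z <- ds
  }
  list(x = z, center = center, scale = scale)
}

#' Read an expression matrix with labels
#'
#' Reads a delimited text file (TSV or CSV, inferred from the extension) with
#' the first column holding sample identifiers and a header row of feature
#' names. Labels come either from a named column of the matrix file or from a
#' separate single-column file aligned by row order.
#'
#' @param path expression matrix file.
#' @param labels either the name of a label column in `path`, or the path of
#'   a single-column label file.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, labels) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE)
  if (labels %in% colnames(tab)) {
    y <- tab[[labels]]
    tab <- tab[, setdiff(colnames(tab), labels), drop = FALSE]
  } else {
    y <- utils::read.table(labels, header = FALSE)[[1L]]
  }
  expression_dataset(as.matrix(tab), y)
}

#' Write an expression dataset to delimited text
#'
#' @param ds an [expression_dataset()].
#' @param path output path (TSV unless it ends in `.csv`); labels are written
#'   as a final `label` column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(sample = ds$sample_ids, ds$x, label = ds$y,
                    check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
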