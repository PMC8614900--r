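#' Expression dataset container
#'
#' Bundles a genes x samples expression matrix with per-sample condition and
#' batch (cohort-of-origin) labels. Every pipeline stage consumes this
#' container. Values are assumed to be on a log-like scale throughout (fold
#' changes are computed as differences of means).
#'
#' @param mat Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique; all values finite.
#' @param condition Character vector of condition labels (e.g. `"AD"`/`"CN"`),
#'   one per sample, either named by sample ID or in column order.
#' @param batch Character vector of batch/dataset labels, one per sample;
#'   defaults to a single batch `"b1"`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `condition`, `batch` (the label vectors are named by sample).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' expression_dataset(m, condition = c("AD", "AD", "CN", "CN"))
#' @export
expression_dataset <- function(mat, condition, batch = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    abort_xdrg("`mat` must be a numeric matrix", "xdrg_invalid_input")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort_xdrg("expression matrix needs gene row names and sample column names",
               "xdrg_invalid_input")
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1]
    abort_xdrg(sprintf("duplicate gene ID: '%s'", dup), "xdrg_invalid_input")
  }
  if (anyDuplicated(colnames(mat))) {
    dup <- colnames(mat)[duplicated(colnames(mat))][1]
    abort_xdrg(sprintf("duplicate sample ID: '%s'", dup), "xdrg_invalid_input")
  }
  if (!all(is.finite(mat))) {
    abort_xdrg("expression matrix contains non-finite values", "xdrg_invalid_input")
  }
  if (is.null(batch)) batch <- rep("b1", ncol(mat))
  condition <- align_labels(condition, colnames(mat), "condition")
  batch <- align_labels(batch, colnames(mat), "batch")
  structure(list(matrix = mat, condition = condition, batch = batch),
            class = "ExpressionDataset")
}

align_labels <- function(x, samples, what) {
  x <- as.character(stats::setNames(x, names(x)))
  if (!is.null(names(x))) {
    missing <- setdiff(samples, names(x))
    if (length(missing)) {
      abort_xdrg(sprintf("sample '%s' has no %s label", missing[1], what),
                 "xdrg_invalid_input")
    }
    x <- x[samples]
  } else {
    if (length(x) != length(samples)) {
      abort_xdrg(sprintf("%s labels: expected %d values, got %d",
                         what, length(samples), length(x)),
                 "xdrg_invalid_input")
    }
    names(x) <- samples
  }
  if (anyNA(x)) abort_xdrg(sprintf("NA in %s labels", what), "xdrg_invalid_input")
  x
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  conditions:", paste(sprintf("%s (%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "), "\n")
  cat("  batches:   ", paste(unique(x$batch), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

#' Subset an expression dataset by genes and/or samples
#'
#' @param x An `ExpressionDataset`.
#' @param genes,samples Character vectors of IDs to keep (default: all).
#' @return An `ExpressionDataset` restricted to the requested IDs, in the
#'   requested order.
#' @export
subset_dataset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionDataset"))
  genes <- genes %||% rownames(x$matrix)
  samples <- samples %||% colnames(x$matrix)
  missing_g <- setdiff(genes, rownames(x$matrix))
  if (length(missing_g)) {
    abort_xdrg(sprintf("gene '%s' not in dataset", missing_g[1]), "xdrg_invalid_input")
  }
  missing_s <- setdiff(samples, colnames(x$matrix))
  if (length(missing_s)) {
    abort_xdrg(sprintf("sample '%s' not in dataset", missing_s[1]), "xdrg_invalid_input")
  }
  expression_dataset(x$matrix[genes, samples, drop = FALSE],
                     condition = x$condition[samples],
                     batch = x$batch[samples])
}
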