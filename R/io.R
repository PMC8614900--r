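#' Read and write expression datasets
#'
#' The on-disk format is a tab-separated matrix (first column gene IDs,
#' header row of sample IDs) plus a companion CSV with columns
#' `sample_id, dataset_id, condition`. Round-tripping preserves values to
#' full precision and row/column order. Gene identity is an opaque,
#' case-sensitive string; no ID-space conversion is performed.
#'
#' @param path Path to the expression TSV.
#' @param meta_path Path to the metadata CSV; defaults to `path` with the
#'   extension replaced by `.meta.csv`.
#' @return `read_expression()` returns an [expression_dataset()];
#'   `write_expression()` invisibly returns the two paths written.
#' @export
read_expression <- function(path, meta_path = default_meta_path(path)) {
  if (!file.exists(path)) abort_xdrg(paste0("no such file: ", path), "xdrg_io_error")
  if (!file.exists(meta_path)) {
    abort_xdrg(paste0("no such metadata file: ", meta_path), "xdrg_io_error")
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) abort_xdrg("expression TSV needs >= 2 columns", "xdrg_parse_error")
  gene_ids <- trimws(tab[[1]])
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    abort_xdrg(sprintf("duplicated gene row: '%s'", dup), "xdrg_parse_error")
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort_xdrg(sprintf("non-numeric cell at gene '%s', sample '%s'",
                       gene_ids[bad[1]], colnames(vals)[bad[2]]),
               "xdrg_parse_error")
  }
  dimnames(num) <- list(gene_ids, trimws(colnames(vals)))

  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "dataset_id", "condition")
  if (!all(need %in% names(meta))) {
    abort_xdrg(sprintf("metadata must have columns %s", paste(need, collapse = ", ")),
               "xdrg_parse_error")
  }
  missing <- setdiff(colnames(num), meta$sample_id)
  if (length(missing)) {
    abort_xdrg(sprintf("sample '%s' missing from metadata", missing[1]),
               "xdrg_parse_error")
  }
  idx <- match(colnames(num), meta$sample_id)
  expression_dataset(num,
                     condition = stats::setNames(meta$condition[idx], colnames(num)),
                     batch = stats::setNames(meta$dataset_id[idx], colnames(num)))
}

default_meta_path <- function(path) sub("\\.[^.]*$", "", path) |> paste0(".meta.csv")

#' @param dataset An `ExpressionDataset`.
#' @rdname read_expression
#' @export
write_expression <- function(dataset, path, meta_path = default_meta_path(path)) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  fmt <- matrix(sprintf("%.17g", dataset$matrix), nrow = nrow(dataset$matrix),
                dimnames = dimnames(dataset$matrix))
  df <- data.frame(gene_id = rownames(fmt), fmt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(dataset$matrix),
                     dataset_id = unname(dataset$batch),
                     condition = unname(dataset$condition),
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, meta_path))
}

#' Read/write gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' IDs are whitespace-trimmed; empty sets and duplicate set names are
#' rejected.
#'
#' @param path Path to a GMT file.
#' @return `read_gmt()`: a named list of character vectors (class
#'   `GeneSetCollection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_xdrg(paste0("no such file: ", path), "xdrg_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3) {
      abort_xdrg(sprintf("malformed GMT line %d: need name, description, >=1 gene", i),
                 "xdrg_parse_error")
    }
    if (parts[1] %in% names(sets)) {
      abort_xdrg(sprintf("duplicate set name '%s' at GMT line %d", parts[1], i),
                 "xdrg_parse_error")
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  structure(sets, class = "GeneSetCollection")
}

#' @param sets Named list of character vectors (gene sets).
#' @param descriptions Optional character vector of per-set descriptions.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets))) {
    abort_xdrg("`sets` must be a non-empty named list", "xdrg_invalid_input")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two- or three-column edge list
#'
#' @param path TSV with two columns (node a, node b), optionally a third
#'   numeric weight column.
#' @param directed Logical; stored as an attribute on the result.
#' @param allow_self_loops Self-edges are rejected by default.
#' @return A data.frame with columns `from`, `to` (and `weight` when present).
#' @export
read_edge_list <- function(path, directed = FALSE, allow_self_loops = FALSE) {
  if (!file.exists(path)) abort_xdrg(paste0("no such file: ", path), "xdrg_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  from <- to <- character(length(lines)); wt <- rep(NA_real_, length(lines))
  has_wt <- FALSE
  for (i in seq_along(lines)) {
    parts <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(parts) < 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
      abort_xdrg(sprintf("malformed edge at line %d", i), "xdrg_parse_error")
    }
    if (!allow_self_loops && parts[1] == parts[2]) {
      abort_xdrg(sprintf("self-loop '%s' at line %d", parts[1], i), "xdrg_parse_error")
    }
    from[i] <- parts[1]; to[i] <- parts[2]
    if (length(parts) >= 3) {
      w <- suppressWarnings(as.numeric(parts[3]))
      if (is.na(w)) abort_xdrg(sprintf("non-numeric weight at line %d", i),
                               "xdrg_parse_error")
      wt[i] <- w; has_wt <- TRUE
    }
  }
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (has_wt) out$weight <- wt
  attr(out, "directed") <- directed
  out
}

#' Read a two-column gene -> value table
#'
#' @param path TSV with gene IDs in column 1 and numeric values in column 2
#'   (e.g. CFG scores or per-gene cis-eSNP counts).
#' @return Named numeric vector.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) abort_xdrg(paste0("no such file: ", path), "xdrg_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  genes <- character(length(lines)); vals <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(parts) < 2 || !nzchar(parts[1])) {
      abort_xdrg(sprintf("malformed gene-table line %d", i), "xdrg_parse_error")
    }
    v <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(v)) abort_xdrg(sprintf("non-numeric value at line %d", i),
                             "xdrg_parse_error")
    genes[i] <- parts[1]; vals[i] <- v
  }
  if (anyDuplicated(genes)) {
    abort_xdrg(sprintf("duplicated gene '%s' in table", genes[duplicated(genes)][1]),
               "xdrg_parse_error")
  }
  stats::setNames(vals, genes)
}

#' @rdname read_gene_table
#' @param values Named numeric vector to write.
#' @export
write_gene_table <- function(values, path) {
  writeLines(paste(names(values), format(values, trim = TRUE, scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}
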