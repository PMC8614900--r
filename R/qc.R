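#' Merge cohorts and adjust batch effects by location/scale alignment
#'
#' Restricts all cohorts to their common gene universe, concatenates the
#' samples, and aligns each gene within each batch to the pooled reference:
#' batch values are centred and rescaled so that, after adjustment, every
#' batch has the same per-gene mean (the pooled mean) and the same per-gene
#' SD (the root-mean of the per-batch variances). This is the location/scale
#' core of empirical-Bayes batch correction without the shrinkage step; the
#' adjustment is a per-(gene, batch) affine map, so standardised within-batch
#' contrasts (e.g. case-vs-control effect in SD units) are preserved exactly.
#'
#' @param datasets A list of [expression_dataset()] objects (or a single one).
#' @return A single merged, adjusted `ExpressionDataset` covering the common
#'   genes; original batch labels are retained.
#' @export
adjust_batches <- function(datasets) {
  if (inherits(datasets, "ExpressionDataset")) datasets <- list(datasets)
  if (!length(datasets)) abort_xdrg("need >= 1 dataset", "xdrg_invalid_input")
  stopifnot(all(vapply(datasets, inherits, logical(1), "ExpressionDataset")))

  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$matrix)))
  if (!length(common)) abort_xdrg("empty gene intersection across datasets",
                                  "xdrg_invalid_input")
  mats <- lapply(datasets, function(d) d$matrix[common, , drop = FALSE])
  mat <- do.call(cbind, mats)
  condition <- do.call(c, lapply(datasets, function(d) d$condition))
  batch <- do.call(c, lapply(datasets, function(d) d$batch))
  if (anyDuplicated(colnames(mat))) {
    abort_xdrg(sprintf("duplicate sample ID across datasets: '%s'",
                       colnames(mat)[duplicated(colnames(mat))][1]),
               "xdrg_invalid_input")
  }

  batches <- unique(batch)
  if (length(batches) > 1) {
    pooled_mean <- rowMeans(mat)
    bm <- vapply(batches, function(b) rowMeans(mat[, batch == b, drop = FALSE]),
                 numeric(nrow(mat)))
    bv <- vapply(batches, function(b) {
      m <- mat[, batch == b, drop = FALSE]
      rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
    }, numeric(nrow(mat)))
    target_sd <- sqrt(rowMeans(bv))
    for (j in seq_along(batches)) {
      idx <- batch == batches[j]
      scale <- ifelse(bv[, j] > 0, target_sd / sqrt(bv[, j]), 1)
      mat[, idx] <- (mat[, idx, drop = FALSE] - bm[, j]) * scale + pooled_mean
    }
  }
  expression_dataset(mat, condition = condition, batch = batch)
}

#' Per-gene fold changes between two conditions
#'
#' Difference of per-condition means (data assumed log-scale), optionally
#' restricted to samples of one batch.
#'
#' @param dataset An `ExpressionDataset`.
#' @param conditions Length-2 character vector `(a, b)`; FC = mean(a) - mean(b).
#' @param batch Optional single batch label to restrict to.
#' @return Named numeric vector of fold changes per gene.
#' @export
fold_changes <- function(dataset, conditions = NULL, batch = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  keep <- if (is.null(batch)) rep(TRUE, ncol(dataset$matrix)) else dataset$batch == batch
  cond <- dataset$condition[keep]
  m <- dataset$matrix[, keep, drop = FALSE]
  conditions <- conditions %||% sort(unique(cond))[1:2]
  if (length(conditions) != 2 || !all(conditions %in% cond)) {
    abort_xdrg("need two conditions present in the (restricted) samples",
               "xdrg_invalid_input")
  }
  rowMeans(m[, cond == conditions[1], drop = FALSE]) -
    rowMeans(m[, cond == conditions[2], drop = FALSE])
}

#' Built-in quality-index provider for subset scoring
#'
#' Returns a provider function usable with [score_subsets()]. Two indices are
#' built in, both oriented so that higher = better:
#' * `internal`: Spearman correlation of a member dataset's within-batch
#'   gene-wise fold-change vector with the pooled fold-change vector of the
#'   other subset members (cross-cohort signal consistency).
#' * `external` (only when `pathways` is supplied): -log10 hypergeometric
#'   upper-tail p of the member's top-`top_n` absolute-FC genes against the
#'   union of the supplied pathway gene sets (agreement with external
#'   knowledge).
#'
#' @param pathways Optional named list of pathway gene sets.
#' @param conditions Length-2 condition pair used for fold changes; default:
#'   first two sorted condition labels in the merged subset.
#' @param top_n Number of top absolute-FC genes for the external index.
#' @return A function `(merged, members) -> matrix` (members x indices) with
#'   an `orientation` attribute (`"higher"` per index).
#' @export
quality_indices <- function(pathways = NULL, conditions = NULL, top_n = 100) {
  index_names <- c("internal", if (!is.null(pathways)) "external")
  provider <- function(merged, members) {
    out <- matrix(NA_real_, length(members), length(index_names),
                  dimnames = list(members, index_names))
    for (b in members) {
      fc_self <- fold_changes(merged, conditions = conditions, batch = b)
      others <- merged$batch != b
      pooled <- subset_dataset(merged, samples = colnames(merged$matrix)[others])
      fc_pool <- fold_changes(pooled, conditions = conditions)
      out[b, "internal"] <- stats::cor(fc_self, fc_pool, method = "spearman")
      if (!is.null(pathways)) {
        universe <- rownames(merged$matrix)
        top <- names(sort(abs(fc_self), decreasing = TRUE))[
          seq_len(min(top_n, length(fc_self)))]
        hit_pool <- intersect(unique(unlist(pathways)), universe)
        p <- hypergeom_p(N = length(universe), M = length(hit_pool),
                         n = length(top), m = length(intersect(top, hit_pool)))
        out[b, "external"] <- -log10(p)
      }
    }
    out
  }
  attr(provider, "orientation") <- stats::setNames(
    rep("higher", length(index_names)), index_names)
  provider
}

#' Score every k-subset of candidate datasets with quality indices
#'
#' Iterates over all `choose(n, k)` subsets of the `n` candidate cohorts,
#' re-runs batch adjustment inside each subset, and asks the index provider
#' for one value per (member dataset, quality index). Each dataset therefore
#' accumulates `choose(n-1, k-1)` values per index; their means form the
#' quality report aggregated by [aggregate_smr()].
#'
#' @param datasets Named list of `ExpressionDataset` cohorts.
#' @param k Subset size, `1 <= k <= n`.
#' @param index_provider Function `(merged_subset, member_ids) -> matrix`
#'   (members x indices); see [quality_indices()]. Its optional `orientation`
#'   attribute declares per-index direction (`"higher"` or `"lower"` = better).
#' @return An object of class `QualityReport`: list with
#'   `per_dataset_index_means` (datasets x indices matrix), `values` (list of
#'   per-dataset matrices of accrued values), `n_subsets_per_dataset`,
#'   `n_subsets_total`, `orientation`.
#' @export
score_subsets <- function(datasets, k, index_provider = quality_indices()) {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    abort_xdrg("`datasets` must be a named list", "xdrg_invalid_input")
  }
  n <- length(datasets)
  if (k < 1 || k > n) abort_xdrg(sprintf("k = %d out of range [1, %d]", k, n),
                                 "xdrg_invalid_input")
  ids <- names(datasets)
  subsets <- utils::combn(ids, k, simplify = FALSE)
  acc <- stats::setNames(vector("list", n), ids)

  for (s in subsets) {
    merged <- adjust_batches(datasets[s])
    vals <- tryCatch(index_provider(merged, s), error = function(e) {
      abort_xdrg(sprintf("index provider failed on subset {%s}: %s",
                         paste(s, collapse = ", "), conditionMessage(e)),
                 "xdrg_provider_error")
    })
    vals <- as.matrix(vals)
    if (is.null(rownames(vals))) rownames(vals) <- s
    for (b in s) acc[[b]] <- rbind(acc[[b]], vals[b, , drop = FALSE])
  }

  means <- do.call(rbind, lapply(ids, function(b) colMeans(acc[[b]])))
  rownames(means) <- ids
  structure(list(per_dataset_index_means = means,
                 values = acc,
                 n_subsets_per_dataset = choose(n - 1, k - 1),
                 n_subsets_total = length(subsets),
                 orientation = attr(index_provider, "orientation") %||%
                   stats::setNames(rep("higher", ncol(means)), colnames(means))),
            class = "QualityReport")
}

#' @export
print.QualityReport <- function(x, ...) {
  cat(sprintf("QualityReport: %d datasets, %d indices, %d values each\n",
              nrow(x$per_dataset_index_means), ncol(x$per_dataset_index_means),
              x$n_subsets_per_dataset))
  print(round(x$per_dataset_index_means, 4))
  invisible(x)
}

#' Aggregate a quality report into the standardized mean rank (SMR)
#'
#' For each quality index, datasets are ranked (rank 1 = best according to the
#' index's declared orientation; ties receive average ranks). A dataset's SMR
#' is the mean of its per-index ranks; lower SMR = higher quality. Datasets
#' with tied SMR are ordered lexicographically by ID so the output is
#' deterministic.
#'
#' @param report A `QualityReport` from [score_subsets()].
#' @return A data.frame with columns `dataset`, per-index rank columns, and
#'   `smr`, sorted ascending by SMR.
#' @export
aggregate_smr <- function(report) {
  stopifnot(inherits(report, "QualityReport"))
  means <- report$per_dataset_index_means
  if (!ncol(means)) abort_xdrg("quality report has no indices", "xdrg_invalid_input")
  ranks <- vapply(colnames(means), function(ix) {
    v <- means[, ix]
    if (identical(report$orientation[[ix]], "lower")) rank(v, ties.method = "average")
    else rank(-v, ties.method = "average")
  }, numeric(nrow(means)))
  ranks <- matrix(ranks, nrow = nrow(means),
                  dimnames = list(rownames(means), colnames(means)))
  smr <- rowMeans(ranks)
  out <- data.frame(dataset = rownames(means), ranks, smr = smr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$smr, out$dataset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-quality datasets by SMR
#'
#' @param ranked Output of [aggregate_smr()] (or a character vector already
#'   in rank order).
#' @param t Number of datasets to keep (default 3); `1 <= t <= n`.
#' @return Character vector of the `t` best dataset IDs (ascending SMR).
#' @export
select_top <- function(ranked, t = 3) {
  ids <- if (is.character(ranked)) ranked else ranked$dataset
  if (t < 1 || t > length(ids)) {
    abort_xdrg(sprintf("t = %d out of range [1, %d]", t, length(ids)),
               "xdrg_invalid_input")
  }
  ids[seq_len(t)]
}

#' Cross-dataset fold-change concordance
#'
#' Spearman correlation of two gene-wise fold-change vectors over their
#' shared (optionally restricted) genes, with a one-sided permutation
#' p-value for positive concordance obtained by permuting one vector.
#'
#' @param fc_a,fc_b Named numeric fold-change vectors, or `DEResult` objects
#'   (their `log_fc` column is used).
#' @param genes Optional gene set to restrict the comparison to.
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed RNG seed for the permutations.
#' @return A list with `rho`, `p_perm`, and `n_genes` used.
#' @export
fc_concordance <- function(fc_a, fc_b, genes = NULL, n_perm = 1000, seed = 1) {
  as_fc <- function(x) {
    if (inherits(x, "DEResult")) stats::setNames(x$log_fc, x$gene) else x
  }
  fc_a <- as_fc(fc_a); fc_b <- as_fc(fc_b)
  shared <- intersect(names(fc_a), names(fc_b))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3) abort_xdrg("need >= 3 shared genes", "xdrg_invalid_input")
  a <- fc_a[shared]; b <- fc_b[shared]
  rho <- stats::cor(a, b, method = "spearman")
  perm <- with_stream(seed, "fc_concordance", {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(a, sample(b), method = "spearman")
    }, numeric(1))
  })
  list(rho = rho, p_perm = (1 + sum(perm >= rho)) / (n_perm + 1),
       n_genes = length(shared))
}
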