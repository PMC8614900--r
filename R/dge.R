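#' Differential expression between two or three conditions
#'
#' Per-gene tests on the (already log-scale) merged expression matrix.
#' Two conditions: Welch t-test, with log fold change = difference of group
#' means (first listed condition minus second). Three conditions: one-way
#' ANOVA F across the three groups; the omnibus p-value is used for DEG
#' calling, and all pairwise log fold changes are reported for downstream
#' concordance analyses. P-values are Benjamini-Hochberg adjusted across all
#' tested genes.
#'
#' Genes with zero variance in every group have no defined statistic; they
#' are kept with `p = 1`, `statistic = NA` and flagged in the `degenerate`
#' column rather than dropped.
#'
#' @param dataset An `ExpressionDataset`.
#' @param conditions Ordered character vector of 2 or 3 condition labels.
#' @return A `DEResult`: data.frame with columns `gene`, `log_fc` (for three
#'   groups, the first-vs-last pair; all pairs in attribute `pairwise_fc`),
#'   `statistic`, `p`, `p_adj`, `degenerate`.
#' @export
differential_expression <- function(dataset, conditions) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!length(conditions) %in% 2:3) {
    abort_xdrg("`conditions` must list 2 or 3 labels", "xdrg_invalid_input")
  }
  cond <- dataset$condition
  for (cd in conditions) {
    if (sum(cond == cd) < 2) {
      abort_xdrg(sprintf("condition '%s' has < 2 samples", cd), "xdrg_invalid_input")
    }
  }
  keep <- cond %in% conditions
  m <- dataset$matrix[, keep, drop = FALSE]
  cond <- factor(cond[keep], levels = conditions)
  groups <- lapply(conditions, function(cd) m[, cond == cd, drop = FALSE])

  n_genes <- nrow(m)
  stat <- p <- rep(NA_real_, n_genes)
  degenerate <- logical(n_genes)

  if (length(conditions) == 2) {
    log_fc <- rowMeans(groups[[1]]) - rowMeans(groups[[2]])
    for (i in seq_len(n_genes)) {
      a <- groups[[1]][i, ]; b <- groups[[2]][i, ]
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        degenerate[i] <- TRUE
        stat[i] <- if (mean(a) == mean(b)) 0 else NA_real_
        p[i] <- 1
      } else {
        tt <- stats::t.test(a, b)
        stat[i] <- unname(tt$statistic); p[i] <- tt$p.value
      }
    }
  } else {
    log_fc <- rowMeans(groups[[1]]) - rowMeans(groups[[3]])
    pairs <- utils::combn(conditions, 2, simplify = FALSE)
    pairwise_fc <- do.call(cbind, lapply(pairs, function(pr) {
      rowMeans(m[, cond == pr[1], drop = FALSE]) -
        rowMeans(m[, cond == pr[2], drop = FALSE])
    }))
    colnames(pairwise_fc) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    rownames(pairwise_fc) <- rownames(m)
    for (i in seq_len(n_genes)) {
      y <- m[i, ]
      if (all(vapply(groups, function(g) stats::var(g[i, ]) == 0, logical(1)))) {
        degenerate[i] <- TRUE
        gm <- vapply(groups, function(g) mean(g[i, ]), numeric(1))
        stat[i] <- if (max(gm) == min(gm)) 0 else NA_real_
        p[i] <- 1
      } else {
        ft <- stats::oneway.test(y ~ cond, var.equal = TRUE)
        stat[i] <- unname(ft$statistic); p[i] <- ft$p.value
      }
    }
  }

  if (any(degenerate)) {
    message(sprintf("%d gene(s) with zero within-group variance flagged (p set to 1)",
                    sum(degenerate)))
  }
  out <- data.frame(gene = rownames(m), log_fc = unname(log_fc),
                    statistic = stat, p = p, p_adj = bh_adjust(p),
                    degenerate = degenerate, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "conditions") <- conditions
  if (length(conditions) == 3) attr(out, "pairwise_fc") <- pairwise_fc
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input. Thin
#' validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort_xdrg("`p` must be numeric", "xdrg_invalid_input")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_xdrg("p-values must lie in [0, 1]", "xdrg_invalid_input")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at an FDR threshold
#'
#' @param de A `DEResult`.
#' @param alpha FDR threshold; genes with `p_adj < alpha` (strict) are kept.
#' @param disease Disease label attached to the resulting set.
#' @return A [candidate_gene_set()] tagged `"DEG"`.
#' @export
select_deg <- function(de, alpha = 0.05, disease = "disease") {
  stopifnot(inherits(de, "DEResult"))
  candidate_gene_set("DEG", de$gene[de$p_adj < alpha], disease = disease)
}

#' @export
print.DEResult <- function(x, ...) {
  cat(sprintf("DEResult: %d genes tested (%s); %d at FDR < 0.05\n",
              nrow(x), paste(attr(x, "conditions"), collapse = " vs "),
              sum(x$p_adj < 0.05)))
  print.data.frame(utils::head(x[order(x$p_adj), ], 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more genes\n", nrow(x) - 6))
  invisible(x)
}
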