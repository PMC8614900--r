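#' Hypergeometric upper-tail enrichment probability
#'
#' Probability of observing at least `m` common genes when drawing `n` genes
#' from a universe of `N` that contains `M` marked genes:
#' `p = sum_{k=m}^{min(M,n)} C(M,k) C(N-M,n-k) / C(N,n)`.
#' Evaluated via the log-space-stable upper tail of the hypergeometric
#' distribution.
#'
#' @param N Background universe size.
#' @param M Marked genes (e.g. pathway members) in the universe.
#' @param n Query set size.
#' @param m Observed overlap.
#' @return The upper-tail probability in `(0, 1]`; `m = 0` gives exactly 1.
#' @export
hypergeom_p <- function(N, M, n, m) {
  for (v in list(N = N, M = M, n = n, m = m)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      abort_xdrg("hypergeometric arguments must be non-negative integers",
                 "xdrg_invalid_input")
    }
  }
  if (M > N || n > N || m > min(M, n)) {
    abort_xdrg(sprintf(
      "invalid hypergeometric bounds: N=%d, M=%d, n=%d, m=%d", N, M, n, m),
      "xdrg_invalid_input")
  }
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Pathway enrichment of a candidate gene set
#'
#' One hypergeometric upper-tail test per pathway, with pathways restricted
#' to the background universe before counting and Benjamini-Hochberg
#' adjustment across all tested pathways. Pathways with no gene in the
#' universe are skipped with a warning.
#'
#' @param query A `CandidateGeneSet` (or character vector); must be a subset
#'   of `universe`.
#' @param pathways Named list of pathway gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene universe (genes measured in the integrated
#'   expression dataset).
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Data.frame with columns `pathway`, `N`, `M`, `n`, `m`, `p`,
#'   `p_adj`, `significant`.
#' @export
pathway_enrichment <- function(query, pathways, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  q <- as_gene_vector(query)
  extra <- setdiff(q, universe)
  if (length(extra)) {
    abort_xdrg(sprintf("query gene '%s' not in universe", extra[1]),
               "xdrg_invalid_input")
  }
  restricted <- lapply(pathways, intersect, universe)
  empty <- lengths(restricted) == 0
  if (any(empty)) {
    warning(sprintf("%d pathway(s) with no gene in the universe skipped",
                    sum(empty)))
    restricted <- restricted[!empty]
  }
  if (!length(restricted)) {
    return(data.frame(pathway = character(), N = integer(), M = integer(),
                      n = integer(), m = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  }
  rows <- lapply(names(restricted), function(nm) {
    pw <- restricted[[nm]]
    m <- length(intersect(q, pw))
    data.frame(pathway = nm, N = length(universe), M = length(pw),
               n = length(q), m = m,
               p = hypergeom_p(length(universe), length(pw), length(q), m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out
}

#' One-sided Fisher exact test for enrichment
#'
#' Exact upper-tail p-value for the top-left cell of a 2x2 contingency table
#' with fixed margins (the `greater` alternative), as used to compare a
#' candidate gene set against a cell-type-specific DEG list.
#'
#' @param table 2x2 matrix of non-negative integer counts;
#'   `table[1, 1]` is the overlap cell.
#' @return The one-sided p-value.
#' @export
fisher_greater <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != floor(table))) {
    abort_xdrg("`table` must be a 2x2 matrix of non-negative integers",
               "xdrg_invalid_input")
  }
  stats::fisher.test(table, alternative = "greater")$p.value
}

#' Concordance of a blood gene set with cell-type-specific DEG lists
#'
#' For each cell-type list (restricted to the universe), tests enrichment of
#' the blood-derived candidate set via the one-sided Fisher exact test on the
#' 2x2 membership table, BH-adjusts across the whole comparison family, and
#' tallies the number of significant lists per candidate set. When several
#' candidate sets are supplied, the set(s) significant in the most lists are
#' flagged as concordance winners (ties: all flagged).
#'
#' @param blood_sets A `CandidateGeneSet` or list of them.
#' @param cell_lists Named list of cell-type DEG lists.
#' @param universe Background gene universe.
#' @param alpha Threshold on the adjusted p-value.
#' @return List with `results` (data.frame: `set`, `cell_list`, `m`, `p`,
#'   `p_adj`, `significant`), `tally` (named integer: significant lists per
#'   set), and `winners` (character).
#' @export
single_cell_concordance <- function(blood_sets, cell_lists, universe,
                                    alpha = 0.05) {
  if (inherits(blood_sets, "CandidateGeneSet")) blood_sets <- list(blood_sets)
  universe <- unique(as.character(universe))
  restricted <- lapply(cell_lists, intersect, universe)
  empty <- lengths(restricted) == 0
  if (any(empty)) {
    warning(sprintf("%d cell-type list(s) empty after restriction skipped",
                    sum(empty)))
    restricted <- restricted[!empty]
  }
  rows <- list()
  for (s in blood_sets) {
    q <- intersect(as_gene_vector(s), universe)
    for (nm in names(restricted)) {
      cl <- restricted[[nm]]
      m <- length(intersect(q, cl))
      tab <- matrix(c(m, length(q) - m,
                      length(cl) - m,
                      length(universe) - length(q) - length(cl) + m), 2, 2)
      rows[[length(rows) + 1]] <- data.frame(
        set = s$name, cell_list = nm, m = m, p = fisher_greater(tab),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  tally <- tapply(res$significant, res$set, sum)
  tally <- stats::setNames(as.integer(tally), names(tally))
  winners <- names(tally)[tally == max(tally)]
  list(results = res, tally = tally, winners = winners)
}
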