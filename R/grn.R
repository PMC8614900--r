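#' Infer regulator -> target importance weights with tree ensembles
#'
#' For each target gene, a regression-forest is fitted predicting the
#' target's expression from the expression of the declared regulators
#' (excluding the target itself when it is a regulator). The weight of a
#' regulator for that target is its impurity importance — the summed variance
#' reduction over all splits on it, the importance the original tree-ensemble
#' network-inference method uses — normalised per target to sum to one.
#' Candidate splits per node are drawn from `floor(sqrt(K))` regulators.
#'
#' The ensemble backend is pluggable via `engine`; the default uses
#' `ranger` regression forests with a fixed seed and one thread, so results
#' are deterministic.
#'
#' @param expr An `ExpressionDataset` (genes x samples); >= 5 samples.
#' @param regulators Character vector of regulator genes (must be measured).
#' @param n_trees Trees per target ensemble (default 1000).
#' @param seed Seed; one sub-seed is derived per target.
#' @param engine Function `(x, y, n_trees, mtry, seed) -> named importance
#'   vector` replacing the default forest backend.
#' @return Data.frame of class `WeightedEdgeList` with columns `regulator`,
#'   `target`, `weight` (weight >= 0; self-edges absent).
#' @export
infer_weights <- function(expr, regulators, n_trees = 1000, seed = 1,
                          engine = NULL) {
  stopifnot(inherits(expr, "ExpressionDataset"))
  regulators <- unique(as.character(regulators))
  if (!length(regulators)) abort_xdrg("empty regulator list", "xdrg_invalid_input")
  missing <- setdiff(regulators, rownames(expr$matrix))
  if (length(missing)) {
    abort_xdrg(sprintf("regulator '%s' not measured", missing[1]),
               "xdrg_invalid_input")
  }
  if (ncol(expr$matrix) < 5) abort_xdrg(">= 5 samples required", "xdrg_invalid_input")
  engine <- engine %||% ranger_importance
  genes <- rownames(expr$matrix)
  mat <- expr$matrix

  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    target <- genes[gi]
    preds <- setdiff(regulators, target)
    if (!length(preds)) next
    x <- t(mat[preds, , drop = FALSE])
    y <- mat[target, ]
    if (stats::var(y) == 0) {
      imp <- stats::setNames(rep(0, length(preds)), preds)
    } else {
      imp <- engine(x, y, n_trees = n_trees,
                    mtry = max(1L, floor(sqrt(length(preds)))),
                    seed = stream_seed(seed, paste0("grn_", target)))
    }
    imp[imp < 0] <- 0
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    rows[[gi]] <- data.frame(regulator = preds, target = target,
                             weight = unname(imp[preds]),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("WeightedEdgeList", "data.frame")
  out
}

ranger_importance <- function(x, y, n_trees, mtry, seed) {
  df <- data.frame(y = y, x, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = "y", data = df,
    num.trees = n_trees, mtry = mtry, importance = "impurity",
    seed = seed, num.threads = 1, respect.unordered.factors = FALSE)
  fit$variable.importance[colnames(x)]
}

#' Threshold importance edges at mean plus two standard deviations
#'
#' Keeps edges whose weight strictly exceeds `mean(w) + 2 * sd_pop(w)`,
#' where both moments are computed over all candidate edge weights of the
#' network and the SD is the population SD. Computed per network.
#'
#' @param edges A `WeightedEdgeList` (>= 2 edges).
#' @return The surviving subset, same class.
#' @export
threshold_edges <- function(edges) {
  if (nrow(edges) < 2) abort_xdrg(">= 2 edges required", "xdrg_invalid_input")
  w <- edges$weight
  keep <- w > mean(w) + 2 * pop_sd(w)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient edges with cis-eSNP anchors
#'
#' Applies the four direction rules to a thresholded edge list:
#' \enumerate{
#'   \item edges whose regulator has 0 cis-eSNPs while the target has >= 1
#'     are removed (a gene without local genetic variation cannot be
#'     anchored as the parent of one with it);
#'   \item when both genes have >= 1 eSNP and unequal counts, only the
#'     direction from the gene with more eSNPs survives (a lone edge
#'     pointing the other way is dropped, not flipped);
#'   \item equal positive eSNP counts in a bidirectional pair: the
#'     higher-weight direction is kept;
#'   \item both genes without eSNPs in a bidirectional pair: the
#'     higher-weight direction is kept.
#' }
#' Exact weight ties in a bidirectional pair keep the direction whose
#' regulator sorts first lexicographically (deterministic). Genes missing
#' from `esnp_counts` are treated as having 0 eSNPs (with a message).
#'
#' @param edges A thresholded `WeightedEdgeList`.
#' @param esnp_counts Named non-negative integer vector, gene -> eSNP count.
#' @return A `DirectedGRN`: list with `edges` (regulator, target, weight),
#'   `nodes`, and `child_count` (distinct children per parent). The result
#'   contains no bidirectional pair and no 0-eSNP -> >=1-eSNP edge.
#' @export
resolve_directions <- function(edges, esnp_counts) {
  cnt <- function(g) {
    v <- esnp_counts[g]
    v[is.na(v)] <- 0
    unname(v)
  }
  miss <- setdiff(unique(c(edges$regulator, edges$target)), names(esnp_counts))
  if (length(miss)) {
    message(sprintf("%d gene(s) missing from eSNP table treated as 0 eSNPs",
                    length(miss)))
  }
  e <- edges
  # rule 1: no 0-eSNP parent of a >=1-eSNP child
  e <- e[!(cnt(e$regulator) == 0 & cnt(e$target) >= 1), , drop = FALSE]
  # rule 2 (count ordering): both >=1 and unequal -> only larger-count parent
  both_pos <- cnt(e$regulator) >= 1 & cnt(e$target) >= 1
  wrong_way <- both_pos & cnt(e$regulator) < cnt(e$target)
  e <- e[!wrong_way, , drop = FALSE]
  # rules 3-4: resolve remaining bidirectional pairs by weight
  if (nrow(e)) {
    key <- paste(pmin(e$regulator, e$target), pmax(e$regulator, e$target))
    drop <- logical(nrow(e))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      if (length(idx) < 2) next
      w <- e$weight[idx]
      best <- idx[order(-w, e$regulator[idx])][1]
      drop[setdiff(idx, best)] <- TRUE
    }
    e <- e[!drop, , drop = FALSE]
  }
  rownames(e) <- NULL
  nodes <- unique(c(e$regulator, e$target))
  cc <- if (nrow(e)) {
    tapply(e$target, e$regulator, function(t) length(unique(t)))
  } else NULL
  child_count <- stats::setNames(as.integer(cc), names(cc))
  structure(list(edges = e, nodes = nodes, child_count = child_count),
            class = "DirectedGRN")
}

#' @export
print.DirectedGRN <- function(x, ...) {
  cat(sprintf("DirectedGRN: %d edges, %d nodes, %d parents\n",
              nrow(x$edges), length(x$nodes), length(x$child_count)))
  invisible(x)
}

#' Per-parent child-count difference between disease and control networks
#'
#' @param disease,control `DirectedGRN` objects.
#' @param parents Character vector: the declared regulator list. Parents
#'   absent from a network contribute 0 children there.
#' @return Named integer vector `d = children_disease - children_control`.
#' @export
child_count_diff <- function(disease, control, parents) {
  get_cc <- function(net, g) {
    v <- net$child_count[g]
    v[is.na(v)] <- 0L
    unname(v)
  }
  stats::setNames(get_cc(disease, parents) - get_cc(control, parents), parents)
}

#' Flag dysregulated regulators against a resampling null
#'
#' Builds a null distribution for the child-count differences by repeatedly
#' drawing `ceiling(fraction * n_parents)` of the observed `d` values without
#' replacement and recording the resample mean. Each parent's z-score is
#' `(d - null_mean) / null_sd`; parents with `|z| >= z_cut` are flagged as
#' dysregulated. When all `d` are identical the null is degenerate: all
#' z-scores are set to 0, nothing is flagged, and the result is marked.
#'
#' @param diffs Named numeric vector of child-count differences (>= 5
#'   parents).
#' @param n_resamples Number of resamples (default 1000).
#' @param fraction Fraction of parents per resample (default 0.2).
#' @param z_cut Flagging threshold on `|z|` (default 1.96).
#' @param statistic Resample statistic: `"mean"` (default; size-stable null
#'   moments) or `"sum"`.
#' @param seed RNG seed.
#' @return A `DysregulationResult`: data.frame with columns `parent`, `d`,
#'   `z`, `dysregulated`, plus attributes `null_mean`, `null_sd`,
#'   `degenerate`.
#' @export
dysregulation_z <- function(diffs, n_resamples = 1000, fraction = 0.2,
                            z_cut = 1.96, statistic = c("mean", "sum"),
                            seed = 1) {
  statistic <- match.arg(statistic)
  if (length(diffs) < 5) abort_xdrg(">= 5 parents required", "xdrg_invalid_input")
  if (is.null(names(diffs))) abort_xdrg("`diffs` must be named by parent",
                                        "xdrg_invalid_input")
  n_draw <- ceiling(fraction * length(diffs))
  stat_fun <- if (statistic == "mean") mean else sum
  null <- with_stream(seed, "dysregulation_null", {
    vapply(seq_len(n_resamples), function(i) stat_fun(sample(diffs, n_draw)),
           numeric(1))
  })
  null_mean <- mean(null); null_sd <- stats::sd(null)
  if (null_sd == 0) {
    z <- stats::setNames(rep(0, length(diffs)), names(diffs))
    degenerate <- TRUE
  } else {
    z <- (diffs - null_mean) / null_sd
    degenerate <- FALSE
  }
  out <- data.frame(parent = names(diffs), d = unname(diffs), z = unname(z),
                    dysregulated = unname(abs(z) >= z_cut & !degenerate),
                    stringsAsFactors = FALSE)
  attr(out, "null_mean") <- null_mean
  attr(out, "null_sd") <- null_sd
  attr(out, "degenerate") <- degenerate
  attr(out, "z_cut") <- z_cut
  class(out) <- c("DysregulationResult", "data.frame")
  out
}

#' Regulators dysregulated in both diseases
#'
#' Intersection of the flagged parents of two dysregulation results, with
#' the sign of the child-count change in each disease (a negative `d` means
#' the regulator lost children in the disease network).
#'
#' @param res_a,res_b `DysregulationResult` objects.
#' @return Data.frame with columns `parent`, `d_a`, `d_b`, `direction_a`,
#'   `direction_b`.
#' @export
common_dysregulated <- function(res_a, res_b) {
  fa <- res_a$parent[res_a$dysregulated]
  fb <- res_b$parent[res_b$dysregulated]
  common <- intersect(fa, fb)
  da <- res_a$d[match(common, res_a$parent)]
  db <- res_b$d[match(common, res_b$parent)]
  dir_lab <- function(d) ifelse(d < 0, "decreased edges",
                                ifelse(d > 0, "increased edges", "unchanged"))
  data.frame(parent = common, d_a = da, d_b = db,
             direction_a = dir_lab(da), direction_b = dir_lab(db),
             stringsAsFactors = FALSE)
}

#' Build a directed GRN from expression in one condition
#'
#' Convenience wrapper: restricts the dataset to the requested condition's
#' samples and the supplied gene background, infers tree-ensemble weights
#' with the TF regulators, thresholds at mean + 2 SD, and orients edges with
#' the eSNP rules.
#'
#' @param dataset An `ExpressionDataset`.
#' @param genes Background genes for the network (e.g. a winning candidate
#'   set); intersected with the measured genes.
#' @param regulators TF regulator list (intersected with `genes`).
#' @param esnp_counts Named eSNP counts for direction resolution.
#' @param condition Condition label selecting the samples.
#' @param n_trees,seed Passed to [infer_weights()].
#' @return A `DirectedGRN`.
#' @export
build_grn <- function(dataset, genes, regulators, esnp_counts, condition,
                      n_trees = 1000, seed = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  samples <- colnames(dataset$matrix)[dataset$condition == condition]
  if (length(samples) < 5) {
    abort_xdrg(sprintf("condition '%s' has < 5 samples", condition),
               "xdrg_invalid_input")
  }
  genes <- intersect(as_gene_vector(genes), rownames(dataset$matrix))
  regulators <- intersect(as_gene_vector(regulators), genes)
  if (!length(regulators)) abort_xdrg("no regulator among the background genes",
                                      "xdrg_invalid_input")
  sub <- subset_dataset(dataset, genes = genes, samples = samples)
  w <- infer_weights(sub, regulators, n_trees = n_trees, seed = seed)
  resolve_directions(threshold_edges(w), esnp_counts)
}
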