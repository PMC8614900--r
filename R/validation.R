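#' Stratified train/test split of a dataset's samples
#'
#' Splits each class 0.7/0.3 (by default) into train and test, rounding the
#' train count half-up ("toward train") and clamping so both partitions keep
#' at least one sample per class. Stratification guarantees both classes are
#' present on both sides even at small n.
#'
#' @param labels Named vector of class labels (names = sample IDs), or an
#'   `ExpressionDataset` (its condition labels are used).
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return List with character vectors `train` and `test` of sample IDs.
#' @export
paired_split <- function(labels, train_fraction = 0.7, seed = 1) {
  if (inherits(labels, "ExpressionDataset")) labels <- labels$condition
  if (is.null(names(labels))) abort_xdrg("labels must be named by sample",
                                         "xdrg_invalid_input")
  classes <- unique(labels)
  for (cl in classes) {
    if (sum(labels == cl) < 2) {
      abort_xdrg(sprintf("class '%s' has < 2 samples", cl), "xdrg_invalid_input")
    }
  }
  with_stream(seed, "paired_split", {
    train <- character()
    for (cl in classes) {
      ids <- names(labels)[labels == cl]
      n_tr <- floor(train_fraction * length(ids) + 0.5)
      n_tr <- max(1L, min(length(ids) - 1L, n_tr))
      train <- c(train, sample(ids, n_tr))
    }
    list(train = train, test = setdiff(names(labels), train))
  })
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive sample outscores a randomly
#' chosen negative one, with ties counting one half.
#'
#' @param scores Numeric decision values, higher = more positive.
#' @param labels Logical (or two-level) vector; `TRUE`/second level =
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  if (!is.logical(labels)) {
    lv <- unique(labels)
    if (length(lv) > 2) abort_xdrg("labels must be binary", "xdrg_invalid_input")
    labels <- labels == sort(as.character(lv))[length(lv)]
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort_xdrg("both classes required to compute an AUC", "xdrg_invalid_input")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Draw a size-matched random gene set
#'
#' Uniform sample without replacement from the full measured universe.
#' Candidate genes are not excluded from the draw (switch with
#' `exclude`).
#'
#' @param size Number of genes to draw.
#' @param universe Character vector of genes to draw from.
#' @param exclude Optional genes removed from the universe before drawing.
#' @param seed Optional seed; when `NULL` the ambient RNG state is used (the
#'   harness derives a fresh stream per iteration).
#' @return Character vector of `size` genes.
#' @export
matched_random_set <- function(size, universe, exclude = NULL, seed = NULL) {
  universe <- setdiff(unique(as.character(universe)), exclude)
  if (size > length(universe)) {
    abort_xdrg(sprintf("size %d exceeds universe of %d", size, length(universe)),
               "xdrg_invalid_input")
  }
  if (is.null(seed)) sample(universe, size)
  else with_stream(seed, "matched_random_set", sample(universe, size))
}

#' Classifier contracts for the validation harness
#'
#' A classifier is a list with `fit(x, y) -> model` and
#' `score(model, x) -> numeric` where `x` is a samples x features matrix and
#' `y` a logical vector (`TRUE` = positive class); higher scores mean more
#' positive. The harness z-scores features using train-set statistics only
#' before calling `fit`/`score`.
#'
#' `classifier_centroid()` scores a sample by the difference of its Euclidean
#' distances to the two training class centroids — fast, parameter-free, and
#' the default for simulation-scale work. `classifier_svm()` wraps a
#' support-vector machine with its default settings (RBF kernel, C = 1;
#' requires the `e1071` package), mirroring the usual default-SVM
#' configuration for this kind of harness.
#'
#' @return A classifier list.
#' @export
classifier_centroid <- function() {
  list(
    name = "centroid",
    fit = function(x, y) {
      list(mu_pos = colMeans(x[y, , drop = FALSE]),
           mu_neg = colMeans(x[!y, , drop = FALSE]))
    },
    score = function(model, x) {
      d_pos <- sqrt(rowSums((x - matrix(model$mu_pos, nrow(x), ncol(x),
                                        byrow = TRUE))^2))
      d_neg <- sqrt(rowSums((x - matrix(model$mu_neg, nrow(x), ncol(x),
                                        byrow = TRUE))^2))
      d_neg - d_pos
    }
  )
}

#' @rdname classifier_centroid
#' @export
classifier_svm <- function() {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    abort_xdrg("classifier_svm() requires the e1071 package", "xdrg_invalid_input")
  }
  list(
    name = "svm",
    fit = function(x, y) {
      fit <- e1071::svm(x, factor(y, levels = c(FALSE, TRUE)))
      # orient decision values so that higher = positive class
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")[, 1]
      sgn <- if (mean(dv[y]) >= mean(dv[!y])) 1 else -1
      list(fit = fit, sgn = sgn)
    },
    score = function(model, x) {
      dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
                 "decision.values")[, 1]
      model$sgn * dv
    }
  )
}

#' Matched-random gene-set classification validation
#'
#' The core validation harness: for each evaluation dataset and iteration, a
#' stratified 0.7/0.3 split is drawn once and shared; the classifier is
#' trained on the candidate genes and, on the *same* split, on a freshly
#' drawn size-matched random gene set; the two test-set AUCs are recorded as
#' a pair. After all iterations, a paired t-test compares the pooled AUC
#' pairs, and the candidate is declared significant when
#' `p < alpha_family / n_sets` (Bonferroni; 0.05/8 = 0.00625 by default) and
#' the candidate's mean AUC exceeds the random mean.
#'
#' Features are z-scored with train-set statistics only (no leakage). The
#' first condition label in each dataset (sorted) is the negative class.
#'
#' @param candidate A `CandidateGeneSet` (or character vector of genes).
#' @param eval_datasets List of `ExpressionDataset`s (binary condition each);
#'   datasets where fewer than 2 candidate genes are measured are skipped
#'   with a warning.
#' @param n_iterations Iterations per dataset (default 1000).
#' @param classifier A classifier contract; see [classifier_centroid()].
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param n_sets Number of candidate sets in the family (default 8).
#' @param train_fraction Train fraction per class.
#' @param mode `"pooled"` tests all dataset x iteration pairs together
#'   (default); `"per_dataset"` additionally reports a paired test per
#'   dataset.
#' @param seed Seed; all splits and random gene sets derive from it.
#' @return A `ValidationResult`: list with `auc_candidate`, `auc_random`
#'   (numeric vectors of length n_datasets x n_iterations), `t_statistic`,
#'   `p`, `significant`, `threshold`, `n_iterations`, `n_datasets`,
#'   `split_signatures` (per-iteration checksums proving the shared split),
#'   and optionally `per_dataset` summaries.
#' @export
run_validation <- function(candidate, eval_datasets, n_iterations = 1000,
                           classifier = classifier_centroid(),
                           alpha_family = 0.05, n_sets = 8,
                           train_fraction = 0.7, mode = c("pooled", "per_dataset"),
                           seed = 1) {
  mode <- match.arg(mode)
  genes <- as_gene_vector(candidate)
  if (inherits(eval_datasets, "ExpressionDataset")) eval_datasets <- list(eval_datasets)
  used <- list()
  for (i in seq_along(eval_datasets)) {
    ds <- eval_datasets[[i]]
    present <- intersect(genes, rownames(ds$matrix))
    if (length(present) < 2) {
      warning(sprintf("dataset %d skipped: < 2 candidate genes measured", i))
      next
    }
    used[[length(used) + 1]] <- list(ds = ds, genes = present, index = i)
  }
  if (!length(used)) abort_xdrg("no evaluation dataset retains >= 2 candidate genes",
                                "xdrg_invalid_input")

  auc_c <- auc_r <- numeric(0)
  sig <- character(0)
  which_ds <- integer(0)
  for (u in used) {
    ds <- u$ds
    labels <- ds$condition
    pos_class <- sort(unique(labels))[length(unique(labels))]
    y_all <- labels == pos_class
    universe <- rownames(ds$matrix)
    for (it in seq_len(n_iterations)) {
      it_seed <- stream_seed(seed, sprintf("val_d%d_i%d", u$index, it))
      split <- paired_split(labels, train_fraction, seed = it_seed)
      rnd <- with_stream(it_seed, "random_set",
                         matched_random_set(length(u$genes), universe))
      a_c <- fit_score_auc(ds, u$genes, split, y_all, classifier)
      a_r <- fit_score_auc(ds, rnd, split, y_all, classifier)
      auc_c <- c(auc_c, a_c); auc_r <- c(auc_r, a_r)
      which_ds <- c(which_ds, u$index)
      sig <- c(sig, paste(sort(split$train), collapse = "|"))
    }
  }
  pt <- paired_t(auc_c, auc_r)
  threshold <- alpha_family / n_sets
  res <- list(auc_candidate = auc_c, auc_random = auc_r,
              dataset = which_ds,
              t_statistic = pt$t, p = pt$p,
              significant = (pt$p < threshold) && (mean(auc_c) > mean(auc_r)),
              threshold = threshold,
              n_iterations = n_iterations, n_datasets = length(used),
              split_signatures = sig)
  if (mode == "per_dataset") {
    res$per_dataset <- lapply(unique(which_ds), function(d) {
      i <- which_ds == d
      pd <- paired_t(auc_c[i], auc_r[i])
      list(dataset = d, t = pd$t, p = pd$p,
           significant = (pd$p < threshold) && (mean(auc_c[i]) > mean(auc_r[i])))
    })
  }
  class(res) <- "ValidationResult"
  res
}

# train on `genes` features under a fixed split; returns the test-set AUC.
# z-scoring uses train statistics only.
fit_score_auc <- function(ds, genes, split, y_all, classifier) {
  x_tr <- t(ds$matrix[genes, split$train, drop = FALSE])
  x_te <- t(ds$matrix[genes, split$test, drop = FALSE])
  mu <- colMeans(x_tr)
  sd <- apply(x_tr, 2, stats::sd)
  sd[sd == 0] <- 1
  x_tr <- sweep(sweep(x_tr, 2, mu), 2, sd, "/")
  x_te <- sweep(sweep(x_te, 2, mu), 2, sd, "/")
  model <- classifier$fit(x_tr, y_all[split$train])
  auc_rank(classifier$score(model, x_te), y_all[split$test])
}

#' @export
print.ValidationResult <- function(x, ...) {
  cat(sprintf(
    "ValidationResult: %d AUC pairs (%d datasets x %d iterations)\n",
    length(x$auc_candidate), x$n_datasets, x$n_iterations))
  cat(sprintf("  mean AUC candidate %.3f vs random %.3f; paired t = %.2f, p = %.3g\n",
              mean(x$auc_candidate), mean(x$auc_random), x$t_statistic, x$p))
  cat(sprintf("  significant at %g: %s\n", x$threshold, x$significant))
  invisible(x)
}

#' Paired t-test on AUC pairs
#'
#' Classical paired t on the differences, two-sided. Degenerate inputs
#' (all differences identical) are flagged: `p = 1` when all differences are
#' zero, `p = 0` when the constant difference is non-zero.
#'
#' @param a,b Paired numeric vectors (e.g. candidate and random AUCs), or a
#'   two-column matrix in `a` with `b` missing.
#' @return List with `t`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(a, b = NULL) {
  if (is.null(b)) { b <- a[, 2]; a <- a[, 1] }
  if (length(a) != length(b) || length(a) < 2) {
    abort_xdrg("need >= 2 pairs of equal length", "xdrg_invalid_input")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = if (all(d == 0)) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       degenerate = FALSE)
}
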