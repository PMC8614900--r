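# Shared fixture builders and independent oracles.

# small handmade expression dataset with two conditions
tiny_dataset <- function(n_genes = 5, n_per_class = 3, batch = "b1",
                         seed = 1, shift_genes = character(), shift = 0) {
  set.seed(seed)
  samples <- sprintf("%s_s%d", batch, seq_len(2 * n_per_class))
  m <- matrix(rnorm(n_genes * 2 * n_per_class), n_genes, 2 * n_per_class,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)), samples))
  condition <- rep(c("case", "control"), each = n_per_class)
  m[shift_genes, condition == "case"] <- m[shift_genes, condition == "case"] + shift
  expression_dataset(m, condition = condition,
                     batch = rep(batch, length(samples)))
}

# a named list of small random cohorts sharing one gene universe
tiny_cohorts <- function(n_datasets, n_genes = 10, n_per_class = 3, seed = 1) {
  out <- lapply(seq_len(n_datasets), function(d) {
    tiny_dataset(n_genes, n_per_class, batch = paste0("d", d), seed = seed + d)
  })
  stats::setNames(out, paste0("d", seq_len(n_datasets)))
}

# index provider that counts its invocations and returns deterministic values
counting_provider <- function(n_indices = 2) {
  counter <- new.env()
  counter$n_calls <- 0L
  f <- function(merged, members) {
    counter$n_calls <- counter$n_calls + 1L
    matrix(seq_len(length(members) * n_indices),
           nrow = length(members),
           dimnames = list(members, paste0("ix", seq_len(n_indices))))
  }
  attr(f, "orientation") <- stats::setNames(rep("higher", n_indices),
                                            paste0("ix", seq_len(n_indices)))
  attr(f, "counter") <- counter
  f
}

# brute-force Benjamini-Hochberg step-up from its definition:
# adj_i = min(1, min_{j : p_(j) >= p_i over the ordered tail} m * p_(j) / j)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# exhaustive hypergeometric upper tail from the counting definition
hyper_brute <- function(N, M, n, m) {
  ks <- m:min(M, n)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# trapezoidal ROC integral for tie-free scores
auc_trapezoid <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  labels <- labels[o]
  tpr <- c(0, cumsum(labels) / sum(labels))
  fpr <- c(0, cumsum(!labels) / sum(!labels))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# edge list giving gene `g` exactly `k` distinct neighbours
edges_with_degree <- function(g, k, prefix = "N") {
  data.frame(from = g, to = sprintf("%s_%s_%02d", prefix, g, seq_len(k)),
             stringsAsFactors = FALSE)
}

# classifier that records the training-set row names it sees
spy_classifier <- function() {
  log <- new.env(); log$train_rows <- list()
  inner <- classifier_centroid()
  f <- list(
    name = "spy",
    fit = function(x, y) {
      log$train_rows[[length(log$train_rows) + 1]] <- sort(rownames(x))
      inner$fit(x, y)
    },
    score = inner$score
  )
  attr(f, "log") <- log
  f
}
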