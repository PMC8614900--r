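test_that("a pure location shift between batches is removed", {
  a <- tiny_dataset(6, 4, batch = "d1", seed = 1)
  b_mat <- tiny_dataset(6, 4, batch = "d2", seed = 2)$matrix + 5
  b <- expression_dataset(b_mat, condition = rep(c("case", "control"), each = 4),
                          batch = rep("d2", 8))
  merged <- adjust_batches(list(a, b))
  for (g in rownames(merged$matrix)) {
    m1 <- mean(merged$matrix[g, merged$batch == "d1"])
    m2 <- mean(merged$matrix[g, merged$batch == "d2"])
    expect_equal(m1, m2, tolerance = 1e-12)
    s1 <- sd(merged$matrix[g, merged$batch == "d1"])
    s2 <- sd(merged$matrix[g, merged$batch == "d2"])
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("a single dataset passes through batch adjustment unchanged", {
  a <- tiny_dataset(5, 3, seed = 9)
  merged <- adjust_batches(list(a))
  expect_equal(merged$matrix, a$matrix, tolerance = 1e-12)
})

test_that("standardised within-batch case-control contrasts survive adjustment", {
  cfg <- sim_config(n_datasets = 3, samples_per_dataset = 15, n_genes = 40,
                    n_planted_deg = 8, effect_size = 1.5, batch_shift_sd = 2,
                    n_tf = 0, n_regulatory_edges = 0, seed = 21)
  sim <- generate_cohorts(cfg)
  merged <- adjust_batches(sim$datasets)
  std_contrast <- function(ds_mat, cond) {
    d <- rowMeans(ds_mat[, cond == "case", drop = FALSE]) -
      rowMeans(ds_mat[, cond == "control", drop = FALSE])
    d / apply(ds_mat, 1, sd)
  }
  for (b in unique(merged$batch)) {
    pre <- sim$datasets[[b]]
    idx <- merged$batch == b
    before <- std_contrast(pre$matrix[rownames(merged$matrix), ], pre$condition)
    after <- std_contrast(merged$matrix[, idx], merged$condition[idx])
    expect_equal(after, before, tolerance = 1e-6)
  }
})

test_that("empty gene intersection across cohorts is an error", {
  a <- tiny_dataset(4, 2, seed = 1)
  b <- tiny_dataset(4, 2, batch = "d2", seed = 2)
  rownames(b$matrix) <- paste0("X", rownames(b$matrix))
  expect_error(adjust_batches(list(a, b)), "intersection")
})

test_that("subset scoring visits every k-subset exactly once", {
  for (n in 2:6) {
    datasets <- tiny_cohorts(n, n_genes = 6, n_per_class = 2, seed = 100 + n)
    for (k in 1:n) {
      prov <- counting_provider()
      rep <- score_subsets(datasets, k, prov)
      expect_identical(attr(prov, "counter")$n_calls, as.integer(choose(n, k)))
      expect_equal(rep$n_subsets_total, choose(n, k))
      expect_equal(rep$n_subsets_per_dataset, choose(n - 1, k - 1))
      for (d in names(datasets)) {
        expect_identical(nrow(rep$values[[d]]), as.integer(choose(n - 1, k - 1)))
      }
    }
  }
  expect_error(score_subsets(tiny_cohorts(3), 4), "out of range")
})

test_that("SMR ranks aggregate per-index ranks with average-rank ties", {
  # means chosen to give index ranks A:(1,3), B:(2,1), C:(3,2)
  rep <- structure(list(
    per_dataset_index_means = matrix(c(10, 5, 1, 1, 3, 2), nrow = 3,
                                     dimnames = list(c("A", "B", "C"),
                                                     c("ix1", "ix2"))),
    values = list(), n_subsets_per_dataset = 1, n_subsets_total = 1,
    orientation = c(ix1 = "higher", ix2 = "higher")), class = "QualityReport")
  out <- aggregate_smr(rep)
  expect_identical(out$dataset, c("B", "A", "C"))
  expect_equal(out$smr, c(1.5, 2.0, 2.5))

  # symmetric two-index report: tie broken lexicographically
  rep$per_dataset_index_means <- matrix(c(2, 1, 1, 2), nrow = 2,
                                        dimnames = list(c("B2", "A2"),
                                                        c("ix1", "ix2")))
  out <- aggregate_smr(rep)
  expect_equal(out$smr, c(1.5, 1.5))
  expect_identical(out$dataset, c("A2", "B2"))

  # single index: SMR equals that index's ranks
  rep$per_dataset_index_means <- matrix(c(9, 5, 2), nrow = 3,
                                        dimnames = list(c("A", "B", "C"), "ix1"))
  rep$orientation <- c(ix1 = "higher")
  out <- aggregate_smr(rep)
  expect_equal(out$smr, c(1, 2, 3))
  expect_identical(out$dataset, c("A", "B", "C"))
})

test_that("SMR is invariant to monotone transformation of one index", {
  means <- matrix(runif(8), nrow = 4,
                  dimnames = list(paste0("d", 1:4), c("ix1", "ix2")))
  rep <- structure(list(per_dataset_index_means = means, values = list(),
                        n_subsets_per_dataset = 1, n_subsets_total = 1,
                        orientation = c(ix1 = "higher", ix2 = "higher")),
                   class = "QualityReport")
  base <- aggregate_smr(rep)
  rep$per_dataset_index_means[, "ix2"] <- exp(3 * means[, "ix2"]) + 7
  expect_identical(aggregate_smr(rep), base)
})

test_that("a label-shuffled outlier cohort ranks last by SMR", {
  last <- vapply(1:10, function(s) {
    cfg <- sim_config(n_datasets = 4, samples_per_dataset = 12, n_genes = 80,
                      n_planted_deg = 20, effect_size = 1.5, n_tf = 0,
                      n_regulatory_edges = 0, seed = 300 + s)
    sim <- generate_cohorts(cfg)
    bad <- sim$datasets[[4]]
    set.seed(1000 + s)
    bad$condition[] <- sample(bad$condition)
    datasets <- c(sim$datasets[1:3], list(d4 = bad))
    rep <- score_subsets(datasets, k = 3, quality_indices())
    out <- aggregate_smr(rep)
    out$dataset[nrow(out)] == "d4"
  }, logical(1))
  expect_gte(mean(last), 0.8)
})

test_that("select_top takes the ascending-SMR prefix and validates t", {
  ranked <- data.frame(dataset = c("b", "a", "c"), smr = c(1, 2, 3))
  expect_identical(select_top(ranked, 2), c("b", "a"))
  expect_identical(select_top(ranked, 3), c("b", "a", "c"))
  expect_error(select_top(ranked, 0), "out of range")
  expect_error(select_top(ranked, 4), "out of range")
})

test_that("fold-change concordance matches hand-computed Spearman values", {
  fc1 <- c(A = 1, B = 2, C = 3)
  expect_equal(fc_concordance(fc1, fc1, n_perm = 200)$rho, 1)
  expect_equal(fc_concordance(fc1, c(A = 3, B = 2, C = 1), n_perm = 200)$rho, -1)
  expect_equal(fc_concordance(fc1, c(A = 1, B = 3, C = 2), n_perm = 200)$rho, 0.5)
  expect_error(fc_concordance(fc1, c(A = 1, B = 2)), ">= 3")
})

test_that("concordance permutation p detects genuine shared signal", {
  set.seed(42)
  x <- rnorm(100)
  fc_a <- setNames(x + rnorm(100, sd = 0.3), paste0("G", 1:100))
  fc_b <- setNames(x + rnorm(100, sd = 0.3), paste0("G", 1:100))
  res <- fc_concordance(fc_a, fc_b, n_perm = 1000, seed = 5)
  expect_gt(res$rho, 0.7)
  expect_lt(res$p_perm, 0.01)
  # unrelated vectors: p should be unremarkable
  res0 <- fc_concordance(fc_a, setNames(rnorm(100), paste0("G", 1:100)),
                         n_perm = 1000, seed = 6)
  expect_gt(res0$p_perm, 0.01)
})
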