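test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  cfg <- sim_config(n_datasets = 2, samples_per_dataset = 5, n_genes = 40,
                    n_planted_deg = 8, n_tf = 5, n_regulatory_edges = 3, seed = 7)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(lapply(a$datasets, `[[`, "matrix"),
                   lapply(b$datasets, `[[`, "matrix"))
  expect_identical(a$truth$planted_deg, b$truth$planted_deg)
  expect_identical(a$truth$planted_edges, b$truth$planted_edges)
  expect_identical(generate_annotations(cfg, a$truth, 0.5),
                   generate_annotations(cfg, b$truth, 0.5))
})

test_that("ground truth satisfies its structural invariants", {
  cfg <- sim_config(n_datasets = 2, samples_per_dataset = 6, n_genes = 60,
                    n_planted_deg = 12, n_tf = 8, n_regulatory_edges = 6,
                    esnp_rate = 0.4, seed = 3)
  sim <- generate_cohorts(cfg)
  tr <- sim$truth
  expect_true(all(tr$planted_edges$parent %in% tr$tf_genes))
  expect_true(all(names(tr$esnp_counts) %in% tr$genes))
  expect_true(all(tr$esnp_counts >= 0))
  expect_length(tr$planted_deg, 12)
  expect_length(tr$tf_genes, 8)
  # regulatory children are distinct and never planted DEGs (their expression
  # is overwritten by the parent dependency)
  expect_false(anyDuplicated(tr$planted_edges$child) > 0)
  expect_length(intersect(tr$planted_edges$child, tr$planted_deg), 0)
  for (ds in sim$datasets) {
    expect_setequal(unique(ds$condition), c("case", "control"))
    expect_equal(sum(ds$condition == "case"), 6)
  }
})

test_that("planted case-control shift equals the configured effect size", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 400, n_genes = 50,
                    n_planted_deg = 10, effect_size = 1.5, noise_sd = 1,
                    n_tf = 0, n_regulatory_edges = 0, seed = 11)
  sim <- generate_cohorts(cfg)
  fc <- fold_changes(sim$datasets[[1]], c("case", "control"))
  # 400/group: SE of a mean difference is ~0.07
  expect_equal(mean(fc[sim$truth$planted_deg]), 1.5, tolerance = 0.1)
  expect_equal(mean(fc[setdiff(names(fc), sim$truth$planted_deg)]), 0,
               tolerance = 0.1)
})

test_that("null simulation (zero effect) gives ~5% raw false positives", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 20, n_genes = 600,
                    n_planted_deg = 30, effect_size = 0, n_tf = 0,
                    n_regulatory_edges = 0, seed = 5)
  sim <- generate_cohorts(cfg)
  de <- differential_expression(sim$datasets[[1]], c("case", "control"))
  frac <- mean(de$p < 0.05)
  # binomial bounds: 0.05 +/- 4 * sqrt(0.05 * 0.95 / 600)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 600))
})

test_that("planted DEGs are recovered at FDR < 0.05 with the stated power", {
  hits <- vapply(1:3, function(s) {
    cfg <- sim_config(n_datasets = 1, samples_per_dataset = 30, n_genes = 200,
                      n_planted_deg = 20, effect_size = 1.5, noise_sd = 1,
                      n_tf = 0, n_regulatory_edges = 0, seed = s)
    sim <- generate_cohorts(cfg)
    de <- differential_expression(sim$datasets[[1]], c("case", "control"))
    deg <- select_deg(de)
    mean(sim$truth$planted_deg %in% deg$genes)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("regulatory children track their parent with the configured slope", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 100, n_genes = 30,
                    n_planted_deg = 0, n_tf = 4, n_regulatory_edges = 5,
                    regulatory_coefficient = 0.8, noise_sd = 1, seed = 13)
  sim <- generate_cohorts(cfg)
  m <- sim$datasets[[1]]$matrix
  for (i in seq_len(nrow(sim$truth$planted_edges))) {
    pa <- sim$truth$planted_edges$parent[i]
    ch <- sim$truth$planted_edges$child[i]
    slope <- unname(stats::coef(stats::lm(m[ch, ] ~ m[pa, ]))[2])
    expect_equal(slope, 0.8, tolerance = 0.35)
  }
})

test_that("rewired mode plants the dependency only in case samples", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 80, n_genes = 30,
                    n_planted_deg = 0, n_tf = 4, n_regulatory_edges = 4,
                    regulatory_coefficient = 0.9, seed = 17)
  sim <- generate_cohorts(cfg, regulatory_mode = "case_only")
  ds <- sim$datasets[[1]]
  pa <- sim$truth$planted_edges$parent[1]
  ch <- sim$truth$planted_edges$child[1]
  r_case <- stats::cor(ds$matrix[pa, ds$condition == "case"],
                       ds$matrix[ch, ds$condition == "case"])
  r_ctrl <- stats::cor(ds$matrix[pa, ds$condition == "control"],
                       ds$matrix[ch, ds$condition == "control"])
  expect_gt(r_case, 0.5)
  expect_lt(abs(r_ctrl), 0.4)
})

test_that("rewired mode switches each child between distinct condition-specific parents", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 80, n_genes = 30,
                    n_planted_deg = 0, n_tf = 6, n_regulatory_edges = 5,
                    regulatory_coefficient = 0.9, seed = 19)
  sim <- generate_cohorts(cfg, regulatory_mode = "rewired")
  tr <- sim$truth
  expect_identical(tr$planted_edges$child, tr$control_edges$child)
  expect_length(intersect(unique(tr$planted_edges$parent),
                          unique(tr$control_edges$parent)), 0)
  expect_setequal(tr$rewired_parents,
                  c(tr$planted_edges$parent, tr$control_edges$parent))
  # parents carry eSNP counts at least matching their children
  for (i in seq_len(nrow(tr$planted_edges))) {
    expect_gte(tr$esnp_counts[tr$planted_edges$parent[i]],
               max(1, tr$esnp_counts[tr$planted_edges$child[i]]))
  }
  ds <- sim$datasets[[1]]
  pa_d <- tr$planted_edges$parent[1]; pa_c <- tr$control_edges$parent[1]
  ch <- tr$planted_edges$child[1]
  r_dis <- cor(ds$matrix[pa_d, ds$condition == "case"],
               ds$matrix[ch, ds$condition == "case"])
  r_ctl <- cor(ds$matrix[pa_c, ds$condition == "control"],
               ds$matrix[ch, ds$condition == "control"])
  expect_gt(r_dis, 0.5)
  expect_gt(r_ctl, 0.5)
})

test_that("annotation lists overlap the planted signal as configured", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 5, n_genes = 200,
                    n_planted_deg = 30, n_tf = 10, n_regulatory_edges = 0, seed = 23)
  sim <- generate_cohorts(cfg)
  ann0 <- generate_annotations(cfg, sim$truth, overlap = 0)
  for (nm in c("digsee", "alzgene", "cvddb", "mtcvd", "gwas")) {
    expect_length(intersect(ann0[[nm]], sim$truth$planted_deg), 0)
  }
  ann1 <- generate_annotations(cfg, sim$truth, overlap = 1)
  expect_true(all(sim$truth$planted_deg %in% names(ann1$cfg_scores)))
  expect_true(all(ann1$cfg_scores[sim$truth$planted_deg] >= 3))
  expect_true(all(ann1$cfg_scores >= 0 & ann1$cfg_scores <= 5))
  expect_true(all(ann1$esnp_counts >= 0))
  # skewed PPI: some genes reach hub degree
  deg_tab <- table(c(ann1$ppi$from, ann1$ppi$to))
  expect_gt(sum(deg_tab >= 10), 0)
  expect_error(generate_annotations(cfg, sim$truth, overlap = 1.2), "overlap")
})

test_that("with full CFG overlap the DEG+CFG set recovers the DE-passing planted genes", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 30, n_genes = 150,
                    n_planted_deg = 15, effect_size = 1.5, n_tf = 6,
                    n_regulatory_edges = 0, seed = 31)
  sim <- generate_cohorts(cfg)
  ann <- generate_annotations(cfg, sim$truth, overlap = 1)
  de <- differential_expression(sim$datasets[[1]], c("case", "control"))
  deg <- select_deg(de)
  got <- filter_cfg(deg, ann$cfg_scores)
  expect_setequal(got$genes, intersect(deg$genes, sim$truth$planted_deg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = -1), "non-negative")
  expect_error(sim_config(n_planted_deg = 11, n_genes = 10), "exceeds")
  expect_error(sim_config(n_tf = 11, n_genes = 10), "exceeds")
  expect_error(sim_config(esnp_rate = 1.5), "esnp_rate")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(samples_per_dataset = 1), ">=")
})
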