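mk_edges <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(regulator = r[[1]], target = r[[2]], weight = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("WeightedEdgeList", "data.frame")
  out
}

test_that("edge thresholding keeps weights strictly above mean + 2 population SD", {
  e <- mk_edges(list("R1", "T1", 2.0), list("R1", "T2", 2.1))
  e <- rbind(e, do.call(rbind, lapply(1:8, function(i) {
    data.frame(regulator = "R2", target = paste0("X", i), weight = 0.1)
  })))
  kept <- threshold_edges(e)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$weight, 2.1)

  eq <- mk_edges(list("a", "b", 1), list("b", "c", 1), list("c", "d", 1))
  expect_identical(nrow(threshold_edges(eq)), 0L)

  shifted <- e; shifted$weight <- shifted$weight + 3.7
  expect_identical(threshold_edges(shifted)$target, kept$target)

  perm <- e[sample(nrow(e)), ]
  expect_setequal(paste(threshold_edges(perm)$regulator, threshold_edges(perm)$target),
                  paste(kept$regulator, kept$target))
  expect_error(threshold_edges(e[1, ]), ">= 2 edges")
})

test_that("the four eSNP direction rules resolve their canonical cases", {
  # rule 1: 0-eSNP parent of an eSNP-bearing child is removed
  g <- resolve_directions(mk_edges(list("A", "B", 0.9)), c(A = 0, B = 3))
  expect_identical(nrow(g$edges), 0L)

  # rule 2: larger eSNP count wins regardless of weight
  g <- resolve_directions(mk_edges(list("A", "B", 0.1), list("B", "A", 0.9)),
                          c(A = 5, B = 2))
  expect_identical(g$edges$regulator, "A")
  expect_identical(g$edges$target, "B")

  # rule 2 extension: a lone wrong-way edge is dropped, not flipped
  g <- resolve_directions(mk_edges(list("B", "A", 0.9)), c(A = 5, B = 2))
  expect_identical(nrow(g$edges), 0L)

  # rule 3: equal positive counts resolved by weight
  g <- resolve_directions(mk_edges(list("A", "B", 0.8), list("B", "A", 0.6)),
                          c(A = 2, B = 2))
  expect_identical(g$edges$regulator, "A")

  # rule 4: both zero counts resolved by weight
  g <- resolve_directions(mk_edges(list("A", "B", 0.5), list("B", "A", 0.7)),
                          c(A = 0, B = 0))
  expect_identical(g$edges$regulator, "B")

  # missing gene treated as zero eSNPs
  expect_message(
    g <- resolve_directions(mk_edges(list("A", "B", 0.5)), c(B = 1)),
    "missing")
  expect_identical(nrow(g$edges), 0L)
})

test_that("direction rules verified on the exhaustive (eSNP, topology, weight) grid", {
  for (ea in 0:2) for (eb in 0:2) {
    esnp <- c(A = ea, B = eb)
    for (topo in c("ab", "ba", "bi")) {
      for (w_ab in c(0.8, 0.4)) {
        w_ba <- 0.6
        edges <- switch(topo,
          ab = mk_edges(list("A", "B", w_ab)),
          ba = mk_edges(list("B", "A", w_ba)),
          bi = mk_edges(list("A", "B", w_ab), list("B", "A", w_ba)))
        g <- resolve_directions(edges, esnp)
        kept <- paste0(g$edges$regulator, g$edges$target)

        # independent statement of the rules:
        ok_dir <- function(pa, ch, w_this, w_other, present_other) {
          if (esnp[pa] == 0 && esnp[ch] >= 1) return(FALSE)        # rule 1
          if (esnp[pa] >= 1 && esnp[ch] >= 1) {
            if (esnp[pa] < esnp[ch]) return(FALSE)                 # rule 2
            if (esnp[pa] > esnp[ch]) return(TRUE)
          }
          if (!present_other) return(TRUE)
          # bidirectional with equal status: higher weight wins (rules 3-4),
          # but only if the opposite direction is itself admissible
          opp_ok <- !(esnp[ch] == 0 && esnp[pa] >= 1) &&
            !(esnp[ch] >= 1 && esnp[pa] >= 1 && esnp[ch] < esnp[pa])
          if (!opp_ok) return(TRUE)
          w_this > w_other
        }
        expected <- character()
        if (topo %in% c("ab", "bi") &&
            ok_dir("A", "B", w_ab, w_ba, topo == "bi")) expected <- c(expected, "AB")
        if (topo %in% c("ba", "bi") &&
            ok_dir("B", "A", w_ba, w_ab, topo == "bi")) expected <- c(expected, "BA")
        expect_setequal(kept, expected)
      }
    }
  }
})

test_that("no bidirectional pair or 0->eSNP edge survives on random networks", {
  set.seed(77)
  for (i in 1:1000) {
    n_nodes <- sample(4:10, 1)
    nodes <- paste0("N", seq_len(n_nodes))
    n_edges <- sample(3:20, 1)
    e <- data.frame(regulator = sample(nodes, n_edges, replace = TRUE),
                    target = sample(nodes, n_edges, replace = TRUE),
                    weight = runif(n_edges), stringsAsFactors = FALSE)
    e <- e[e$regulator != e$target, , drop = FALSE]
    e <- e[!duplicated(paste(e$regulator, e$target)), , drop = FALSE]
    if (nrow(e) < 1) next
    esnp <- setNames(rpois(n_nodes, 1), nodes)
    g <- suppressMessages(resolve_directions(e, esnp))
    if (nrow(g$edges)) {
      key_fwd <- paste(g$edges$regulator, g$edges$target)
      key_rev <- paste(g$edges$target, g$edges$regulator)
      expect_length(intersect(key_fwd, key_rev), 0)
      expect_false(any(esnp[g$edges$regulator] == 0 & esnp[g$edges$target] >= 1))
    }
  }
})

test_that("a target copying a regulator gets its weight concentrated there", {
  set.seed(6)
  n <- 40
  regs <- paste0("R", 1:5)
  m <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(c(regs, "T1"), paste0("s", 1:n)))
  m["T1", ] <- m["R1", ]  # exact copy, zero noise
  ds <- expression_dataset(m, condition = rep(c("case", "control"), n / 2))
  for (s in 1:3) {
    w <- infer_weights(ds, regs, n_trees = 100, seed = s)
    wt <- w[w$target == "T1", ]
    expect_identical(wt$regulator[which.max(wt$weight)], "R1")
    expect_gt(max(wt$weight), 0.5)
  }
})

test_that("a pure-noise target spreads weight without spurious concentration", {
  hits <- vapply(1:50, function(s) {
    set.seed(9000 + s)
    n <- 50
    regs <- paste0("R", 1:10)
    m <- matrix(rnorm(11 * n), 11, n,
                dimnames = list(c(regs, "T1"), paste0("s", 1:n)))
    ds <- expression_dataset(m, condition = rep("case", n))
    w <- infer_weights(subset_dataset(ds, genes = c(regs, "T1")), regs,
                       n_trees = 100, seed = s)
    wt <- w$weight[w$target == "T1"]
    max(wt) < 3 * mean(wt)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("planted linear edges are ranked far above the background", {
  cfg <- sim_config(n_datasets = 1, samples_per_dataset = 40, n_genes = 30,
                    n_planted_deg = 0, n_tf = 6, n_regulatory_edges = 8,
                    regulatory_coefficient = 0.8, noise_sd = 1, seed = 99)
  sim <- generate_cohorts(cfg)
  w <- infer_weights(sim$datasets[[1]], sim$truth$tf_genes, n_trees = 200, seed = 4)
  truth_keys <- paste(sim$truth$planted_edges$parent, sim$truth$planted_edges$child)
  labels <- paste(w$regulator, w$target) %in% truth_keys
  o <- order(-w$weight)
  lab <- labels[o]
  prec <- cumsum(lab) / seq_along(lab)
  rec <- cumsum(lab) / sum(lab)
  aupr <- sum(diff(c(0, rec)) * prec)
  expect_gte(aupr, 5 * mean(labels))
})

test_that("child-count differences follow simple arithmetic", {
  net <- function(...) {
    e <- mk_edges(...)
    cc <- tapply(e$target, e$regulator, function(t) length(unique(t)))
    structure(list(edges = e, nodes = unique(c(e$regulator, e$target)),
                   child_count = setNames(as.integer(cc), names(cc))),
              class = "DirectedGRN")
  }
  dis <- net(list("P1", "a", 1), list("P1", "b", 1), list("P1", "c", 1),
             list("P2", "a", 1))
  ctl <- net(list("P1", "a", 1), list("P3", "a", 1), list("P3", "b", 1),
             list("P3", "c", 1), list("P3", "d", 1))
  d <- child_count_diff(dis, ctl, c("P1", "P2", "P3"))
  expect_identical(d, c(P1 = 2L, P2 = 1L, P3 = -4L))
  expect_identical(child_count_diff(dis, dis, c("P1", "P2")), c(P1 = 0L, P2 = 0L))
})

test_that("the resampling null flags a lone large change and degenerates safely", {
  d0 <- setNames(rep(0, 10), paste0("P", 1:10))
  res <- dysregulation_z(d0, n_resamples = 200, seed = 1)
  expect_true(attr(res, "degenerate"))
  expect_false(any(res$dysregulated))

  flagged <- vapply(1:50, function(s) {
    d <- setNames(c(rep(0, 19), 10), paste0("P", 1:20))
    res <- dysregulation_z(d, n_resamples = 1000, fraction = 0.2, seed = s)
    top <- res$parent[which.max(abs(res$z))]
    top == "P20" && res$dysregulated[res$parent == "P20"]
  }, logical(1))
  expect_true(all(flagged))

  d <- setNames(c(-3, 0, 2, 5, 1, 0, -1, 4), paste0("P", 1:8))
  za <- dysregulation_z(d, n_resamples = 500, seed = 7)
  zb <- dysregulation_z(-d, n_resamples = 500, seed = 7)
  expect_equal(zb$z, -za$z, tolerance = 1e-12)
  expect_error(dysregulation_z(c(a = 1, b = 2)), ">= 5 parents")
})

test_that("common dysregulated regulators carry per-disease change signs", {
  mk_res <- function(parents, d, flag) {
    structure(data.frame(parent = parents, d = d, z = d, dysregulated = flag,
                         stringsAsFactors = FALSE),
              class = c("DysregulationResult", "data.frame"))
  }
  a <- mk_res(c("P1", "P2", "P3"), c(-3, 4, -2), c(TRUE, TRUE, FALSE))
  b <- mk_res(c("P1", "P4"), c(-5, 2), c(TRUE, TRUE))
  out <- common_dysregulated(a, b)
  expect_identical(out$parent, "P1")
  expect_identical(out$direction_a, "decreased edges")
  expect_identical(out$direction_b, "decreased edges")
  expect_identical(nrow(common_dysregulated(a, mk_res("P9", 1, TRUE))), 0L)
  self <- common_dysregulated(a, a)
  expect_setequal(self$parent, c("P1", "P2"))
})
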