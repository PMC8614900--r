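#' Simulation configuration for multi-cohort expression data
#'
#' Defines the study conditions the synthetic generator emulates: several
#' case/control cohorts measured on a shared gene universe, a subset of
#' genes differentially expressed in cases, additive per-(dataset, gene)
#' batch offsets, and a planted TF-driven linear regulatory structure.
#' All randomness flows from `seed` through named streams, so each stage of
#' the simulation is independently reproducible.
#'
#' @param n_datasets Number of cohorts.
#' @param samples_per_dataset Samples per condition within each cohort.
#' @param n_genes Size of the shared gene universe.
#' @param n_planted_deg Number of genes shifted in cases.
#' @param effect_size Case-vs-control mean shift of planted genes, in units
#'   of the residual SD.
#' @param batch_shift_sd SD of the additive per-(dataset, gene) offset.
#' @param noise_sd Residual SD of expression around the gene mean.
#' @param n_tf Number of genes labelled as transcription factors (the only
#'   admissible network regulators).
#' @param n_regulatory_edges Number of planted TF -> target dependencies.
#' @param regulatory_coefficient Linear strength of a planted dependency:
#'   target = coefficient x regulator + noise.
#' @param esnp_rate Fraction of genes carrying >= 1 cis-eSNP.
#' @param seed Integer seed fixing every output bit-for-bit.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_datasets = 3, samples_per_dataset = 30, n_genes = 1000,
                       n_planted_deg = 50, effect_size = 1.5,
                       batch_shift_sd = 1, noise_sd = 1,
                       n_tf = 40, n_regulatory_edges = 30,
                       regulatory_coefficient = 0.8, esnp_rate = 0.3,
                       seed = 1) {
  cfg <- list(n_datasets = n_datasets, samples_per_dataset = samples_per_dataset,
              n_genes = n_genes, n_planted_deg = n_planted_deg,
              effect_size = effect_size, batch_shift_sd = batch_shift_sd,
              noise_sd = noise_sd, n_tf = n_tf,
              n_regulatory_edges = n_regulatory_edges,
              regulatory_coefficient = regulatory_coefficient,
              esnp_rate = esnp_rate, seed = seed)
  counts <- c("n_datasets", "samples_per_dataset", "n_genes", "n_planted_deg",
              "n_tf", "n_regulatory_edges")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      abort_xdrg(sprintf("`%s` must be a non-negative integer", f), "xdrg_config_error")
    }
  }
  if (cfg$n_datasets < 1 || cfg$samples_per_dataset < 2 || cfg$n_genes < 1) {
    abort_xdrg("need >=1 dataset, >=2 samples per condition, >=1 gene",
               "xdrg_config_error")
  }
  if (cfg$n_planted_deg > cfg$n_genes) {
    abort_xdrg("n_planted_deg exceeds n_genes", "xdrg_config_error")
  }
  if (cfg$n_tf > cfg$n_genes) abort_xdrg("n_tf exceeds n_genes", "xdrg_config_error")
  for (f in c("effect_size", "batch_shift_sd", "noise_sd",
              "regulatory_coefficient", "esnp_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort_xdrg(sprintf("`%s` must be a number", f), "xdrg_config_error")
    }
  }
  if (cfg$batch_shift_sd < 0 || cfg$noise_sd < 0) {
    abort_xdrg("SDs must be non-negative", "xdrg_config_error")
  }
  if (cfg$esnp_rate < 0 || cfg$esnp_rate > 1) {
    abort_xdrg("esnp_rate must be in [0, 1]", "xdrg_config_error")
  }
  structure(cfg, class = "SimulationConfig")
}

#' Generate multi-cohort expression data with planted ground truth
#'
#' Each cohort receives `samples_per_dataset` case and control samples.
#' Expression of gene g in cohort d is
#' `baseline_g + batch_{d,g} + N(0, noise_sd)`, with planted DEGs shifted by
#' `effect_size * noise_sd` in cases. Planted regulatory targets are then
#' overwritten as `regulatory_coefficient * regulator + N(0, noise_sd)` in the
#' conditions named by `regulatory_conditions`, giving a linear Gaussian
#' dependency a tree-ensemble network learner should recover. Planted DEGs,
#' TFs and regulatory targets are disjoint gene groups so each signal is
#' attributable.
#'
#' @param config A [sim_config()].
#' @param regulatory_mode How the planted regulatory structure depends on the
#'   condition: `"shared"` (default) wires every sample identically;
#'   `"case_only"` activates the dependencies in cases only (controls keep
#'   their baseline expression); `"rewired"` gives each child a
#'   control-group parent in control samples and a different disease-group
#'   parent in cases, emulating a disease that shifts regulatory control
#'   between transcription factors.
#' @return A list with `datasets` (list of [expression_dataset()], one per
#'   cohort, batches `"d1"`, `"d2"`, ...) and `truth` (class `GroundTruth`:
#'   `planted_deg`, `tf_genes`, `planted_edges` data.frame with columns
#'   `parent`/`child` (the wiring active in cases), `control_edges` (the
#'   control wiring; empty unless `regulatory_mode = "rewired"`),
#'   `rewired_parents` (regulators whose children change between conditions),
#'   `esnp_counts`, and an `annotation_overlaps` slot filled by
#'   [generate_annotations()]).
#' @export
generate_cohorts <- function(config,
                             regulatory_mode = c("shared", "case_only", "rewired")) {
  stopifnot(inherits(config, "SimulationConfig"))
  regulatory_mode <- match.arg(regulatory_mode)
  genes <- sprintf("G%04d", seq_len(config$n_genes))

  tf_genes <- with_stream(config$seed, "tf", sample(genes, config$n_tf))
  child_pool <- setdiff(genes, tf_genes)
  n_edges <- min(config$n_regulatory_edges, length(child_pool))
  children <- if (n_edges > 0 && length(tf_genes) > 0) {
    with_stream(config$seed, "children", sample(child_pool, n_edges))
  } else character()
  # a share of the planted DEGs is drawn from the TF labels, mirroring the
  # typical minority of transcription factors inside a disease gene set, so
  # DEG-derived candidate sets carry regulators for the network stage
  planted_deg <- with_stream(config$seed, "deg", {
    n_tf_deg <- min(config$n_tf, ceiling(0.2 * config$n_planted_deg))
    pool <- setdiff(genes, c(children, tf_genes))
    tf_part <- if (n_tf_deg > 0) sample(tf_genes, n_tf_deg) else character()
    rest <- min(config$n_planted_deg - length(tf_part), length(pool))
    c(tf_part, if (rest > 0) sample(pool, rest) else character())
  })
  empty_edges <- data.frame(parent = character(), child = character(),
                            stringsAsFactors = FALSE)
  control_edges <- empty_edges
  planted_edges <- if (length(children)) {
    with_stream(config$seed, "edges", {
      if (regulatory_mode == "rewired") {
        # disease rewires regulatory control from one group of TFs to
        # another: each child follows a control-group parent in controls and
        # a disease-group parent in cases
        grp <- sample(tf_genes)
        half <- max(1L, length(grp) %/% 2L)
        ctrl_pool <- grp[seq_len(half)]
        dis_pool <- grp[-seq_len(half)]
        if (!length(dis_pool)) dis_pool <- ctrl_pool
        control_edges <- data.frame(
          parent = sample(ctrl_pool, n_edges, replace = TRUE),
          child = children, stringsAsFactors = FALSE)
        data.frame(parent = sample(dis_pool, n_edges, replace = TRUE),
                   child = children, stringsAsFactors = FALSE)
      } else {
        parent_pool <- intersect(tf_genes, planted_deg)
        if (!length(parent_pool)) parent_pool <- tf_genes
        data.frame(parent = sample(parent_pool, n_edges, replace = TRUE),
                   child = children, stringsAsFactors = FALSE)
      }
    })
  } else {
    empty_edges
  }
  esnp_counts <- with_stream(config$seed, "esnp", {
    has <- stats::runif(length(genes)) < config$esnp_rate
    stats::setNames(ifelse(has, 1L + stats::rpois(length(genes), 2), 0L), genes)
  })
  # planted regulators carry at least as many cis-eSNPs as any of their
  # targets: the eSNP anchoring rules rest on the premise that causal
  # regulators harbour local genetic variation, so the annotation must be
  # consistent with the planted causal structure
  all_edges <- rbind(planted_edges, control_edges)
  if (nrow(all_edges)) {
    for (pa in unique(all_edges$parent)) {
      kids <- all_edges$child[all_edges$parent == pa]
      esnp_counts[pa] <- max(esnp_counts[pa], 1L, esnp_counts[kids])
    }
  }
  baseline <- with_stream(config$seed, "baseline",
                          stats::setNames(stats::rnorm(length(genes), 7, 1), genes))

  datasets <- lapply(seq_len(config$n_datasets), function(d) {
    ds_id <- paste0("d", d)
    n <- config$samples_per_dataset
    sample_ids <- sprintf("%s_s%03d", ds_id, seq_len(2 * n))
    condition <- stats::setNames(rep(c("case", "control"), each = n), sample_ids)
    with_stream(config$seed, paste0("cohort_", d), {
      batch_off <- stats::rnorm(length(genes), 0, config$batch_shift_sd)
      mat <- baseline + batch_off +
        matrix(stats::rnorm(length(genes) * 2L * n, 0, config$noise_sd),
               nrow = length(genes))
      dimnames(mat) <- list(genes, sample_ids)
      is_case <- condition == "case"
      mat[planted_deg, is_case] <- mat[planted_deg, is_case] +
        config$effect_size * config$noise_sd
      if (nrow(planted_edges)) {
        wire <- function(rows, which_samples) {
          for (i in seq_len(nrow(rows))) {
            ch <- rows$child[i]; pa <- rows$parent[i]
            mat[ch, which_samples] <<- config$regulatory_coefficient *
              mat[pa, which_samples] +
              stats::rnorm(sum(which_samples), 0, config$noise_sd)
          }
        }
        if (regulatory_mode == "shared") {
          wire(planted_edges, rep(TRUE, length(condition)))
        } else if (regulatory_mode == "case_only") {
          wire(planted_edges, is_case)
        } else {
          wire(planted_edges, is_case)
          wire(control_edges, !is_case)
        }
      }
      expression_dataset(mat, condition = condition,
                         batch = stats::setNames(rep(ds_id, length(sample_ids)),
                                                 sample_ids))
    })
  })
  names(datasets) <- paste0("d", seq_len(config$n_datasets))

  rewired_parents <- if (regulatory_mode == "shared") character() else {
    unique(c(planted_edges$parent, control_edges$parent))
  }
  truth <- structure(list(planted_deg = planted_deg, tf_genes = tf_genes,
                          planted_edges = planted_edges,
                          control_edges = control_edges,
                          rewired_parents = rewired_parents,
                          esnp_counts = esnp_counts,
                          genes = genes,
                          annotation_overlaps = list()),
                     class = "GroundTruth")
  list(datasets = datasets, truth = truth)
}

#' Generate annotation resources with controlled overlap to the planted signal
#'
#' Emulates the knowledge resources the set-construction stage consumes:
#' a PPI edge list with a skewed degree distribution (some genes >= 10
#' neighbours), a TF list, curated disease gene lists, integer CFG scores in
#' 0..5, per-gene cis-eSNP counts, a GWAS gene list, a pathway collection and
#' cell-type-specific DEG lists. A fraction `overlap` of each list is drawn
#' from the planted DEGs so enrichment and set recovery are assessable.
#'
#' @param config A [sim_config()].
#' @param truth The `GroundTruth` from [generate_cohorts()].
#' @param overlap Fraction in `[0, 1]` of each annotation list drawn from the
#'   planted DEGs.
#' @return A named list (class `AnnotationBundle`) with elements `ppi`
#'   (data.frame from/to), `tf` (character), `digsee`, `alzgene`, `cvddb`,
#'   `mtcvd`, `gwas` (character), `cfg_scores` and `esnp_counts` (named
#'   integer), `pathways` and `cell_type_degs` (named lists of gene sets);
#'   plus the updated `truth` with `annotation_overlaps` recorded.
#' @export
generate_annotations <- function(config, truth, overlap = 0.6) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(truth, "GroundTruth"))
  if (!is.numeric(overlap) || overlap < 0 || overlap > 1) {
    abort_xdrg("`overlap` must be in [0, 1]", "xdrg_config_error")
  }
  genes <- truth$genes
  # annotation lists overlap the full planted disease signal: the shifted
  # DEGs plus the regulatory targets wired to them
  planted <- union(truth$planted_deg, truth$planted_edges$child)
  other <- setdiff(genes, planted)

  draw_list <- function(size, stream) {
    with_stream(config$seed, stream, {
      n_hit <- round(overlap * min(size, length(planted)))
      hits <- if (n_hit > 0) sample(planted, n_hit) else character()
      n_fill <- max(0, size - n_hit)
      fills <- if (n_fill > 0) sample(other, min(n_fill, length(other))) else character()
      unique(c(hits, fills))
    })
  }
  list_size <- max(10L, round(0.1 * length(genes)))

  ann <- list()
  ann$tf <- truth$tf_genes
  ann$digsee <- draw_list(list_size, "ann_digsee")
  ann$alzgene <- draw_list(list_size, "ann_alzgene")
  ann$cvddb <- draw_list(list_size, "ann_cvddb")
  ann$mtcvd <- draw_list(list_size, "ann_mtcvd")
  ann$gwas <- draw_list(list_size, "ann_gwas")

  # CFG scores: overlapping planted genes score >= 3, a background of other
  # genes scores 1-2, everything else implicitly 0
  ann$cfg_scores <- with_stream(config$seed, "ann_cfg", {
    n_hit <- round(overlap * length(planted))
    hi <- if (n_hit > 0) sample(planted, n_hit) else character()
    lo <- sample(other, min(length(other), list_size))
    stats::setNames(
      c(sample(3:5, length(hi), replace = TRUE),
        sample(0:2, length(lo), replace = TRUE)),
      c(hi, lo))
  })
  ann$esnp_counts <- truth$esnp_counts

  # PPI: designated hub genes get >= 12 distinct partners; plus random
  # background edges, giving a right-skewed degree distribution
  ann$ppi <- with_stream(config$seed, "ann_ppi", {
    n_hub_hit <- round(overlap * length(planted))
    hubs <- unique(c(if (n_hub_hit > 0) sample(planted, n_hub_hit) else character(),
                     sample(other, min(length(other), max(5L, list_size %/% 2)))))
    edges <- do.call(rbind, lapply(hubs, function(h) {
      partners <- sample(setdiff(genes, h), 12)
      data.frame(from = h, to = partners, stringsAsFactors = FALSE)
    }))
    n_bg <- 2 * length(genes)
    a <- sample(genes, n_bg, replace = TRUE)
    b <- sample(genes, n_bg, replace = TRUE)
    keep <- a != b
    edges <- rbind(edges, data.frame(from = a[keep], to = b[keep],
                                     stringsAsFactors = FALSE))
    edges[!duplicated(paste(pmin(edges$from, edges$to),
                            pmax(edges$from, edges$to))), ]
  })

  ann$pathways <- with_stream(config$seed, "ann_pathways", {
    n_pw <- 10L
    pws <- lapply(seq_len(n_pw), function(i) sample(genes, 30))
    names(pws) <- sprintf("PW%02d", seq_len(n_pw))
    n_hit <- round(overlap * length(planted))
    pws[["PW_signal"]] <- unique(c(
      if (n_hit > 0) sample(planted, n_hit) else character(),
      sample(other, 15)))
    pws
  })

  ann$cell_type_degs <- with_stream(config$seed, "ann_celltype", {
    n_lists <- 6L
    lists <- lapply(seq_len(n_lists), function(i) {
      if (i <= n_lists / 2) {
        n_hit <- round(overlap * length(planted))
        unique(c(if (n_hit > 0) sample(planted, n_hit) else character(),
                 sample(other, list_size)))
      } else {
        sample(other, list_size)
      }
    })
    names(lists) <- sprintf("cell%02d", seq_len(n_lists))
    lists
  })

  truth$annotation_overlaps <- lapply(
    c(digsee = "digsee", alzgene = "alzgene", cvddb = "cvddb", mtcvd = "mtcvd",
      gwas = "gwas"),
    function(nm) intersect(ann[[nm]], planted))
  ann$truth <- truth
  structure(ann, class = "AnnotationBundle")
}

#' Write a simulated study to disk in the pipeline's file formats
#'
#' @param cohorts Result of [generate_cohorts()].
#' @param annotations Result of [generate_annotations()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulation <- function(cohorts, annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(cohorts$datasets)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_expression(cohorts$datasets[[nm]], p)
    paths[[nm]] <- p
  }
  paths$ppi <- file.path(dir, "ppi.tsv")
  utils::write.table(annotations$ppi, paths$ppi, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$tf <- file.path(dir, "tf.txt")
  writeLines(annotations$tf, paths$tf)
  for (nm in c("digsee", "alzgene", "cvddb", "mtcvd", "gwas")) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".txt"))
    writeLines(annotations[[nm]], paths[[nm]])
  }
  paths$cfg <- file.path(dir, "cfg.tsv")
  write_gene_table(annotations$cfg_scores, paths$cfg)
  paths$esnp <- file.path(dir, "esnp.tsv")
  write_gene_table(annotations$esnp_counts, paths$esnp)
  paths$pathways <- file.path(dir, "pathways.gmt")
  write_gmt(annotations$pathways, paths$pathways)
  paths$cell_type_degs <- file.path(dir, "cell_type_degs.gmt")
  write_gmt(annotations$cell_type_degs, paths$cell_type_degs)
  invisible(paths)
}
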