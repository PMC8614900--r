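#' Run the full cross-disease discovery pipeline
#'
#' Orchestrates the four-step workflow for each configured disease and then
#' compares the diseases:
#' \enumerate{
#'   \item dataset quality ranking (subset-wise scoring, SMR) and selection
#'     of the top-`top_t` cohorts, batch adjustment, integration;
#'   \item differential expression and construction of the eight candidate
#'     gene sets from the annotation resources;
#'   \item matched-random classification validation on each evaluation panel
#'     (sets must be significant on every panel to stay in play), then
#'     single-cell concordance to pick the winning set;
#'   \item GRN inference on the winning set's genes (disease vs control
#'     samples), eSNP-anchored orientation, child-count differencing and the
#'     resampling null for dysregulated regulators.
#' }
#' Finally the cross-disease set-overlap matrix and the regulators
#' dysregulated in both diseases are reported.
#'
#' @param config A nested list, or path to a YAML file with the same
#'   structure: top-level `seed`, `params` (stage parameters: `k`, `top_t`,
#'   `alpha`, `min_degree`, `min_cfg`, `iterations`, `n_sets`, `resamples`,
#'   `fraction`, `z_cut`, `n_trees`), `annotations` (paths to `ppi`, `tf`,
#'   `digsee`, `alzgene`, `cvddb`, `mtcvd`, `gwas`, `cfg`, `esnp`,
#'   `pathways`, `cell_type_degs` — or the in-memory `AnnotationBundle`), and
#'   `diseases`: one entry per disease with `datasets` (named list of
#'   expression TSV paths or `ExpressionDataset` objects), `conditions`
#'   (2 or 3 labels, disease condition first, control last), `db_tag`
#'   (curated database to use, e.g. `"alzgene"` or `"cvddb"`), optionally its
#'   own `annotations` bundle overriding the shared one, and
#'   `eval_panels` (named list of dataset lists).
#' @return A `PipelineResult`: list with per-disease results
#'   (`selected_datasets`, `de`, `sets`, `validation`, `concordance`,
#'   `winners`, `grn`, `dysregulation`), the cross-disease `overlap` matrix,
#'   `common_dysregulated`, and a `log` of every stage decision and seed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_xdrg(paste0("no such config: ", config),
                                         "xdrg_config_error")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1
  p <- default_params(config$params)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  note("pipeline seed = %d", seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_xdrg(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 "xdrg_stage_error")
    })
  }

  diseases <- names(config$diseases)
  if (length(diseases) < 1) abort_xdrg("no diseases configured", "xdrg_config_error")
  shared_ann <- if (!is.null(config$annotations)) {
    stage("annotations", load_annotations(config$annotations))
  }
  per_disease <- list()

  for (dz in diseases) {
    dcfg <- config$diseases[[dz]]
    # disease-specific annotation resources override the shared bundle
    ann <- if (!is.null(dcfg$annotations)) {
      stage(paste0(dz, ":annotations"), load_annotations(dcfg$annotations))
    } else {
      shared_ann
    }
    datasets <- stage(paste0(dz, ":load"), load_datasets(dcfg$datasets))
    conditions <- dcfg$conditions %||% c("case", "control")
    ctrl <- conditions[length(conditions)]

    # step 1: quality ranking and integration
    selected <- names(datasets)
    if (length(datasets) > p$top_t) {
      report <- stage(paste0(dz, ":qc"), score_subsets(
        datasets, k = min(p$k, length(datasets)),
        index_provider = quality_indices(pathways = ann$pathways,
                                         conditions = conditions[c(1, length(conditions))])))
      ranked <- aggregate_smr(report)
      selected <- select_top(ranked, p$top_t)
      note("%s: selected %s by SMR", dz, paste(selected, collapse = ", "))
    } else {
      note("%s: %d cohorts <= top_t, all integrated", dz, length(datasets))
    }
    merged <- stage(paste0(dz, ":integrate"), adjust_batches(datasets[selected]))

    # step 2: differential expression and candidate sets
    de <- stage(paste0(dz, ":de"), differential_expression(merged, conditions))
    deg <- select_deg(de, alpha = p$alpha, disease = dz)
    note("%s: %d DEGs at FDR < %g", dz, length(deg$genes), p$alpha)
    sets <- stage(paste0(dz, ":sets"), build_candidate_sets(
      deg, ann, db_tag = dcfg$db_tag %||% "alzgene",
      min_degree = p$min_degree, min_cfg = p$min_cfg))

    # step 3: validation on every panel, then single-cell concordance
    panels <- lapply(dcfg$eval_panels, load_datasets)
    validation <- list()
    ok_all_panels <- stats::setNames(rep(TRUE, length(sets)), names(sets))
    for (pn in names(panels)) {
      for (sn in names(sets)) {
        vr <- if (length(sets[[sn]]$genes) >= 2) {
          stage(paste0(dz, ":validate"), run_validation(
            sets[[sn]], panels[[pn]], n_iterations = p$iterations,
            alpha_family = p$alpha, n_sets = p$n_sets,
            seed = stream_seed(seed, paste(dz, pn, sn))))
        } else NULL
        validation[[pn]][[sn]] <- vr
        ok_all_panels[sn] <- ok_all_panels[sn] &&
          !is.null(vr) && isTRUE(vr$significant)
      }
    }
    shortlist <- names(sets)[ok_all_panels]
    note("%s: %d/%d sets significant on every panel (%s)",
         dz, length(shortlist), length(sets), paste(shortlist, collapse = ", "))
    conc_pool <- if (length(shortlist)) sets[shortlist] else sets
    if (!length(shortlist)) note("%s: no set passed all panels; concordance over all sets", dz)
    conc <- stage(paste0(dz, ":concordance"), single_cell_concordance(
      conc_pool, ann$cell_type_degs, universe = rownames(merged$matrix),
      alpha = p$alpha))
    winners <- sort(conc$winners)
    note("%s: concordance winner(s): %s", dz, paste(winners, collapse = ", "))

    # step 4: GRN comparison on the winning set; among tied concordance
    # winners, prefer the set carrying the most TF regulators (the network
    # comparison needs parent nodes), then the larger set, then the name
    n_tf_in <- vapply(winners, function(w) {
      length(intersect(ann$tf, sets[[w]]$genes))
    }, integer(1))
    n_size <- vapply(winners, function(w) length(sets[[w]]$genes), integer(1))
    feasible <- (n_tf_in >= 5) + (n_tf_in >= 1 & n_size >= 5)
    grn_target <- winners[order(-feasible, -n_tf_in, -n_size, winners)][1]
    note("%s: GRN built on %s (%d regulators)", dz, grn_target,
         n_tf_in[[grn_target]])
    win_set <- sets[[grn_target]]
    regulators <- intersect(ann$tf, intersect(win_set$genes, rownames(merged$matrix)))
    grn_res <- dys <- NULL
    if (length(regulators) >= 1 && length(win_set$genes) >= 5) {
      g_dis <- stage(paste0(dz, ":grn"), build_grn(
        merged, win_set$genes, regulators, ann$esnp_counts,
        condition = conditions[1], n_trees = p$n_trees,
        seed = stream_seed(seed, paste(dz, "grn_disease"))))
      g_ctl <- stage(paste0(dz, ":grn"), build_grn(
        merged, win_set$genes, regulators, ann$esnp_counts,
        condition = ctrl, n_trees = p$n_trees,
        seed = stream_seed(seed, paste(dz, "grn_control"))))
      diffs <- child_count_diff(g_dis, g_ctl, regulators)
      dys <- if (length(diffs) >= 5) {
        dysregulation_z(diffs, n_resamples = p$resamples, fraction = p$fraction,
                        z_cut = p$z_cut, seed = stream_seed(seed, paste(dz, "dys")))
      } else {
        note("%s: only %d regulators, too few for the resampling null", dz,
             length(diffs))
        NULL
      }
      grn_res <- list(disease = g_dis, control = g_ctl, diffs = diffs)
      note("%s: GRN %d disease / %d control edges; %d regulators, %d dysregulated",
           dz, nrow(g_dis$edges), nrow(g_ctl$edges), length(regulators),
           if (is.null(dys)) 0L else sum(dys$dysregulated))
    } else {
      note("%s: winning set too small for GRN comparison, skipped", dz)
    }

    per_disease[[dz]] <- list(
      selected_datasets = selected, merged = merged, de = de, sets = sets,
      validation = validation, concordance = conc, winners = winners,
      grn = grn_res, dysregulation = dys)
  }

  overlap <- common <- NULL
  if (length(diseases) >= 2) {
    a <- per_disease[[diseases[1]]]; b <- per_disease[[diseases[2]]]
    shared_universe <- intersect(rownames(a$merged$matrix), rownames(b$merged$matrix))
    restrict <- function(s) candidate_gene_set(s$name,
                                               intersect(s$genes, shared_universe),
                                               s$disease)
    overlap <- stage("overlap", overlap_matrix(
      lapply(a$sets, restrict), lapply(b$sets, restrict), shared_universe))
    if (!is.null(a$dysregulation) && !is.null(b$dysregulation)) {
      common <- common_dysregulated(a$dysregulation, b$dysregulation)
      note("common dysregulated regulators: %s",
           if (nrow(common)) paste(common$parent, collapse = ", ") else "none")
    }
  }

  structure(list(diseases = per_disease, overlap = overlap,
                 common_dysregulated = common, params = p, seed = seed,
                 log = log),
            class = "PipelineResult")
}

default_params <- function(params) {
  defaults <- list(k = 4, top_t = 3, alpha = 0.05, min_degree = 10, min_cfg = 3,
                   iterations = 1000, n_sets = 8, resamples = 1000,
                   fraction = 0.2, z_cut = 1.96, n_trees = 1000)
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  defaults
}

load_datasets <- function(x) {
  if (is.null(names(x))) names(x) <- paste0("d", seq_along(x))
  out <- lapply(x, function(el) {
    if (inherits(el, "ExpressionDataset")) el
    else if (is.character(el)) read_expression(el)
    else abort_xdrg("datasets must be paths or ExpressionDataset objects",
                    "xdrg_config_error")
  })
  out
}

load_annotations <- function(ann) {
  if (inherits(ann, "AnnotationBundle")) return(ann)
  need <- c("ppi", "tf", "digsee", "alzgene", "cvddb", "mtcvd", "gwas",
            "cfg", "esnp", "pathways", "cell_type_degs")
  for (nm in intersect(need, names(ann))) {
    if (is.character(ann[[nm]]) && !file.exists(ann[[nm]])) {
      abort_xdrg(paste0("missing annotation file: ", ann[[nm]]),
                 "xdrg_config_error")
    }
  }
  out <- list()
  out$ppi <- if (is.character(ann$ppi)) read_edge_list(ann$ppi) else ann$ppi
  read_lines_or_pass <- function(x) if (is.character(x) && length(x) == 1 &&
                                        file.exists(x)) readLines(x) else x
  for (nm in c("tf", "digsee", "alzgene", "cvddb", "mtcvd", "gwas")) {
    out[[nm]] <- read_lines_or_pass(ann[[nm]])
  }
  out$cfg_scores <- if (is.character(ann$cfg)) read_gene_table(ann$cfg)
                    else ann$cfg_scores %||% ann$cfg
  out$esnp_counts <- if (is.character(ann$esnp)) read_gene_table(ann$esnp)
                     else ann$esnp_counts %||% ann$esnp
  out$pathways <- if (is.character(ann$pathways)) read_gmt(ann$pathways)
                  else ann$pathways
  out$cell_type_degs <- if (is.character(ann$cell_type_degs))
    read_gmt(ann$cell_type_degs) else ann$cell_type_degs
  out
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  for (dz in names(x$diseases)) {
    d <- x$diseases[[dz]]
    cat(sprintf("  %s: cohorts {%s}; %d DEGs; winner(s): %s\n", dz,
                paste(d$selected_datasets, collapse = ", "),
                length(d$sets[[1]]$genes), paste(d$winners, collapse = ", ")))
    if (!is.null(d$dysregulation)) {
      cat(sprintf("    dysregulated regulators: %d of %d\n",
                  sum(d$dysregulation$dysregulated), nrow(d$dysregulation)))
    }
  }
  if (!is.null(x$common_dysregulated)) {
    cat(sprintf("  common dysregulated: %s\n",
                if (nrow(x$common_dysregulated))
                  paste(x$common_dysregulated$parent, collapse = ", ")
                else "none"))
  }
  invisible(x)
}
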