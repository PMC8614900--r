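#' Candidate disease-related gene set
#'
#' A named gene list with provenance tag and disease label. The tag records
#' which evidence stream produced the set (differential expression alone, or
#' its intersection with PPI hubs, transcription factors, curated disease
#' databases, CFG scores, cis-eQTL or GWAS evidence).
#'
#' @param name Provenance tag, e.g. `"DEG"`, `"DEG+HUB"`, `"DEG+CFG"`.
#' @param genes Character vector of gene IDs (de-duplicated).
#' @param disease Disease label (e.g. `"AD"` or `"CVD"`).
#' @return An object of class `CandidateGeneSet`.
#' @export
candidate_gene_set <- function(name, genes, disease = "disease") {
  stopifnot(is.character(name), length(name) == 1)
  genes <- unique(as.character(genes))
  structure(list(name = name, genes = genes, disease = disease),
            class = "CandidateGeneSet")
}

#' @export
print.CandidateGeneSet <- function(x, ...) {
  cat(sprintf("CandidateGeneSet '%s' (%s): %d genes\n",
              x$name, x$disease, length(x$genes)))
  invisible(x)
}

as_gene_vector <- function(x) {
  if (inherits(x, "CandidateGeneSet")) x$genes else unique(as.character(x))
}

#' Restrict a DEG set to PPI hub genes
#'
#' Keeps the DEGs whose degree (number of distinct neighbours) in the
#' undirected PPI network is at least `min_degree` (inclusive). Genes absent
#' from the network have degree 0.
#'
#' @param deg A `CandidateGeneSet` of DEGs.
#' @param ppi Data.frame edge list with columns `from`, `to` (undirected).
#' @param min_degree Hub threshold (default 10, inclusive).
#' @return A `CandidateGeneSet` tagged `<parent>+HUB`.
#' @export
intersect_hub <- function(deg, ppi, min_degree = 10) {
  stopifnot(inherits(deg, "CandidateGeneSet"), is.data.frame(ppi))
  pairs <- unique(data.frame(
    a = pmin(ppi$from, ppi$to), b = pmax(ppi$from, ppi$to),
    stringsAsFactors = FALSE))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  degree <- table(c(pairs$a, pairs$b))
  d <- as.numeric(degree[deg$genes])
  d[is.na(d)] <- 0
  candidate_gene_set(paste0(deg$name, "+HUB"), deg$genes[d >= min_degree],
                     disease = deg$disease)
}

#' Intersect a DEG set with an annotation gene list
#'
#' @param deg A `CandidateGeneSet` of DEGs.
#' @param resource Character vector of genes from the annotation resource.
#' @param tag Suffix for the provenance tag (result is `<parent>+<tag>`).
#' @return A `CandidateGeneSet` holding the intersection.
#' @export
intersect_list <- function(deg, resource, tag) {
  stopifnot(inherits(deg, "CandidateGeneSet"))
  resource <- as_gene_vector(resource)
  if (!length(resource)) {
    abort_xdrg("annotation resource is empty (file problem?)", "xdrg_invalid_input")
  }
  candidate_gene_set(paste0(deg$name, "+", tag), intersect(deg$genes, resource),
                     disease = deg$disease)
}

#' Filter a DEG set by convergent-functional-genomics score
#'
#' Keeps DEGs whose CFG score (integer count of independent evidence lines,
#' 0-5) reaches `min_score` (inclusive). Genes without a score count as 0.
#'
#' @param deg A `CandidateGeneSet` of DEGs.
#' @param scores Named integer vector, gene -> CFG score in 0..5.
#' @param min_score Threshold (default 3, inclusive).
#' @return A `CandidateGeneSet` tagged `<parent>+CFG`.
#' @export
filter_cfg <- function(deg, scores, min_score = 3) {
  stopifnot(inherits(deg, "CandidateGeneSet"))
  if (any(scores < 0 | scores > 5)) {
    abort_xdrg("CFG scores must lie in [0, 5]", "xdrg_invalid_input")
  }
  s <- scores[deg$genes]
  s[is.na(s)] <- 0
  candidate_gene_set(paste0(deg$name, "+CFG"), deg$genes[s >= min_score],
                     disease = deg$disease)
}

#' Build the eight standard candidate sets for one disease
#'
#' Convenience wrapper applying the full construction battery to a DEG set:
#' the DEG set itself, PPI hubs, TF intersection, a text-mining disease list,
#' a curated disease-database list, CFG-score filtering, cis-eQTL evidence
#' (genes with >= 1 eSNP), and GWAS evidence.
#'
#' @param deg `CandidateGeneSet` of DEGs for the disease.
#' @param annotations List with elements `ppi`, `tf`, `digsee`, a curated
#'   database list (name given by `db_tag`, e.g. `alzgene` or `cvddb`),
#'   `cfg_scores`, `esnp_counts`, `gwas`.
#' @param db_tag Which curated database element/tag to use (e.g. `"alzgene"`).
#' @param min_degree,min_cfg Thresholds for the hub and CFG filters.
#' @return Named list of eight `CandidateGeneSet`s.
#' @export
build_candidate_sets <- function(deg, annotations, db_tag = "alzgene",
                                 min_degree = 10, min_cfg = 3) {
  esnp_genes <- names(annotations$esnp_counts)[annotations$esnp_counts >= 1]
  sets <- list(
    deg,
    intersect_hub(deg, annotations$ppi, min_degree = min_degree),
    intersect_list(deg, annotations$tf, "TF"),
    intersect_list(deg, annotations$digsee, "DIGSEE"),
    intersect_list(deg, annotations[[db_tag]], toupper(db_tag)),
    filter_cfg(deg, annotations$cfg_scores, min_score = min_cfg),
    intersect_list(deg, esnp_genes, "eQTL"),
    intersect_list(deg, annotations$gwas, "GWAS")
  )
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Cross-disease overlap matrix of candidate sets
#'
#' For every (set A, set B) pair, counts the common genes and computes the
#' hypergeometric upper-tail p-value of the overlap against the shared
#' background universe, with Benjamini-Hochberg adjustment across all pairs.
#'
#' @param sets_a,sets_b Lists of `CandidateGeneSet`s (e.g. the 8 AD and 8 CVD
#'   sets).
#' @param universe Character vector: the background gene universe (all sets
#'   must be subsets of it).
#' @return Data.frame of class `OverlapMatrix` with one row per pair:
#'   `set_a`, `set_b`, `size_a`, `size_b`, `m`, `N`, `p`, `p_adj`.
#' @export
overlap_matrix <- function(sets_a, sets_b, universe) {
  universe <- unique(as.character(universe))
  check_sub <- function(s) {
    extra <- setdiff(s$genes, universe)
    if (length(extra)) {
      abort_xdrg(sprintf("set '%s' has gene '%s' outside the universe",
                         s$name, extra[1]), "xdrg_invalid_input")
    }
  }
  lapply(sets_a, check_sub); lapply(sets_b, check_sub)
  grid <- expand.grid(i = seq_along(sets_a), j = seq_along(sets_b))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    a <- sets_a[[grid$i[r]]]; b <- sets_b[[grid$j[r]]]
    m <- length(intersect(a$genes, b$genes))
    p <- hypergeom_p(N = length(universe), M = length(a$genes),
                     n = length(b$genes), m = m)
    data.frame(set_a = a$name, set_b = b$name,
               size_a = length(a$genes), size_b = length(b$genes),
               m = m, N = length(universe), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  class(out) <- c("OverlapMatrix", "data.frame")
  out
}
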