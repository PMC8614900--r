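Package: xdrg
Title: Cross-Disease Blood Disease-Related Gene Discovery Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for identifying blood disease-related
    genes shared between diseases from multi-cohort gene-expression data.
    Stages: combinatorial subset-wise dataset quality scoring aggregated into
    a standardized mean rank, location/scale batch adjustment, differential
    expression with Benjamini-Hochberg FDR control, knowledge-anchored
    candidate gene-set construction (PPI hubs, transcription factors, curated
    disease databases, convergent functional genomics scores, cis-eQTL and
    GWAS evidence), matched-random gene-set classification validation with
    paired AUC comparison, hypergeometric pathway enrichment and Fisher-exact
    single-cell concordance, and gene-regulatory-network comparison using
    tree-ensemble importance weights, eSNP-anchored edge orientation, and a
    resampling null for dysregulated regulators. Includes a synthetic-data
    generator that emulates multi-cohort expression with planted signal so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
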