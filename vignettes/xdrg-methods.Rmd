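---
title: "Methods: cross-disease blood DRG discovery with xdrg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-disease blood DRG discovery with xdrg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdrg)
```

# The problem

Two diseases that co-occur in patients — the motivating case is Alzheimer's
disease and cardiovascular disease — may share blood-measurable molecular
machinery. `xdrg` implements a staged screen for such shared disease-related
genes (DRGs): statistical evidence from multi-cohort blood expression,
knowledge filters from curated resources, a predictive-validity gate against
matched random gene sets, concordance with cell-type-resolved signatures,
and finally a regulatory-network comparison that looks for upstream
regulators whose influence changes with disease. This vignette documents
the model behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data experiments do and do not demonstrate.

# Dataset quality ranking (SMR)

Pooling many public cohorts indiscriminately loses signal: platforms differ
and some cohorts are simply noisy. Rather than scoring all `n` cohorts at
once, `score_subsets()` scores every size-`k` subset separately, re-running
batch adjustment inside each subset before the quality indices are
computed, so each index sees data adjusted exactly as it would be at
integration time. Every cohort is a member of `choose(n-1, k-1)` subsets
and accrues that many values per index; the per-index means are ranked
(rank 1 = best, average ranks on ties) and a cohort's **standardized mean
rank** is the mean of its per-index ranks. `select_top()` keeps the `t`
cohorts with the smallest SMR (`t = 3` by default).

The quality indices are deliberately pluggable: the provider contract is a
function from a batch-adjusted subset to one value per (member, index),
with a declared orientation. Two transparent built-ins are provided by
`quality_indices()`:

* *internal consistency* — Spearman correlation between a member's
  within-batch fold-change vector and the pooled fold changes of the other
  members: a cohort whose case/control contrast disagrees with every other
  cohort's is suspect;
* *external consistency* — `-log10` hypergeometric enrichment of the
  member's top-100 absolute-fold-change genes in the union of supplied
  pathway gene sets: real disease signal should touch annotated biology.

Final SMR ties are broken lexicographically by dataset ID so output order
is deterministic; this and the orientation convention are free choices the
procedure itself does not pin down.

# Batch adjustment

`adjust_batches()` restricts all cohorts to their common gene universe and
aligns each gene within each batch to a pooled reference: batch values are
centred at the pooled mean and rescaled so every batch has the same
per-gene SD (the root-mean of per-batch variances). This is the
location/scale core of empirical-Bayes batch correction without the
shrinkage step, and it is the model the synthetic generator plants
(additive per-(dataset, gene) offsets), so the adjustment is exactly
matched to the simulated nuisance. Two consequences are worth noting:

* a single batch passes through unchanged (the map is the identity);
* the map is affine per (gene, batch), so *standardised* within-batch
  contrasts — effect sizes in SD units — are preserved exactly, and the
  tests assert that invariance at 1e-6. Raw mean differences are rescaled
  by the ratio of target to batch SD, which is the price of equalising
  variances.

Zero-variance (gene, batch) cells are centred but not rescaled.

# Differential expression

Expression is assumed to be on a log-like scale throughout, so fold changes
are differences of means. Two conditions use a Welch *t* per gene; three
conditions (the acute/stable/control design) use the classic one-way ANOVA
*F*, and the *omnibus* p-value is what calls DEGs — a gene is
disease-related if expression differs anywhere across the three states —
while all pairwise fold changes are reported for concordance analyses.
Moderated (shrinkage) tests are intentionally not built in: the pipeline's
logic is independent of the per-gene test, which is why the identical
interface can host a moderated variant. BH adjustment is applied across all
tested genes and DEG calling is strict (`p_adj < alpha`).

Genes with zero variance in every group have no defined statistic; they are
kept with `p = 1`, flagged in a `degenerate` column, and counted in a
message — dropping them would silently change multiplicity.

# Candidate sets and overlap

Eight constructions per disease, all intersections with the DEG set:
PPI hubs use an inclusive `degree >= 10` threshold on distinct neighbours
(absent genes have degree 0); CFG filtering is inclusive at score ≥ 3 with
missing scores treated as 0; eQTL membership means ≥ 1 cis-eSNP in the
per-gene count table. Every constructed set is by construction a subset of
its DEG parent, and the tests assert this for all sixteen constructions.

The cross-disease overlap matrix tests all `8 × 8` pairs with the
hypergeometric upper tail. The background `N` is the *shared measured
universe* — the intersection of the two integrated datasets' gene lists —
because a draw must be observable in both analyses; this choice is
configurable since the original procedure leaves it open.

# Matched-random validation

The predictive gate asks: does this gene set classify disease better than a
random set of the same size? For each evaluation dataset and iteration, a
stratified 0.7/0.3 split is drawn once and shared between the candidate
features and a freshly drawn size-matched random set; a classifier is
trained on each and the two test-set AUCs form a pair. After
`n_iterations` (default 1000) per dataset, a two-sided paired *t* is taken
over all pooled pairs and the set is declared informative when
`p < alpha_family / n_sets` (0.05/8 = 0.00625) *and* its mean AUC exceeds
the random mean.

Numerical and design details:

* splits are stratified per class with the train count rounded half-up
  ("toward train": 10 → 7, 3 → 2) and clamped so both partitions retain
  both classes — unstratified splitting can produce single-class test sets
  at small n;
* features are z-scored with train-set statistics only (leakage guard);
* AUC is the rank-based Mann–Whitney probability with ties counting ½,
  verified against the trapezoidal ROC integral;
* random sets are drawn from the full measured universe without excluding
  candidate genes (switchable); "matched" constrains only the size;
* the classifier is a contract (`fit`/`score`); the default centroid-
  distance scorer is fast and parameter-free, and an RBF-kernel SVM with
  default settings is provided for the conventional configuration. The
  harness treats it as a black box;
* a degenerate paired test (all differences equal) is flagged rather than
  computed: `p = 1` if all differences are zero, `p = 0` otherwise.

**A calibration caveat that users should know.** On *signal-free* data, the
pooled paired *t* over repeated splits of the same dataset is
anticonservative: a fixed candidate set has a finite-sample "advantage" on
a given dataset (some gene sets spuriously separate the fixed labels), and
repeated splits re-measure that fixed quantity rather than resample it, so
iterations are not independent evidence. Empirically the false-positive
rate at 0.00625 sits above 10% regardless of sample size when the data
contain no signal at all. The harness is nevertheless a meaningful *gate*
under study conditions, where datasets do carry disease signal: there the
matched random competitors pick up real signal genes the null candidate
lacks, the mean-direction requirement fails, and a signal-free candidate is
essentially never declared informative (0 of 200 harness seeds in the
acceptance suite). Interpret the paired-t p-values comparatively, not as
calibrated error rates; the per-dataset mode (`mode = "per_dataset"`) is
available when a more conservative unit of evidence is wanted.

# Enrichment and single-cell concordance

Pathway enrichment is the hypergeometric upper tail
`p = Σ_{k=m}^{min(M,n)} C(M,k) C(N−M,n−k) / C(N,n)` with `N` the genes
measured in the integrated dataset, computed through the numerically stable
log-space tail (`m = 0` gives exactly 1), BH-adjusted across pathways.
Pathways with no gene in the universe are skipped with a warning rather
than tested vacuously.

Concordance with cell-type-specific DEG lists uses the one-sided
(enrichment-direction) Fisher exact test — the identity between the
one-sided Fisher p and the hypergeometric tail at matching margins is
asserted in the tests on 1000 random tables. The BH family is all
(set × list) pairs of a run, matching a joint display of all candidate
sets; the set significant in the most lists is the concordance winner, with
ties reported in full.

# Regulatory-network comparison

Within a candidate set's genes, a directed network is inferred per
condition:

1. **Weights.** For each target, a regression forest predicts the target
   from the TF regulators (excluding itself); a regulator's weight is its
   impurity importance — summed variance reduction across all splits —
   normalised per target to sum to one. Defaults: 1000 trees,
   `mtry = floor(sqrt(K))`, fixed seed per target, single-threaded (the
   backend is pluggable via `engine`).
2. **Thresholding.** Edges are kept when their weight strictly exceeds
   mean + 2 × population SD over *all* candidate weights of that network,
   computed per network (each network is its own inference run). The
   threshold is translation-invariant and order-invariant.
3. **Orientation.** Four cis-eSNP anchoring rules: (i) a 0-eSNP gene may
   not parent a ≥ 1-eSNP gene; (ii) with unequal positive counts only the
   larger-count direction survives — a lone wrong-way edge is dropped, not
   flipped, because flipping would invent a weight; (iii)–(iv) equal-status
   bidirectional pairs resolve to the higher weight, exact ties to the
   lexicographically first regulator. The output provably contains no
   bidirectional pair and no (0 → ≥1)-eSNP edge.
4. **Dysregulation.** Per regulator, `d` = children in disease − children
   in control. The null draws `ceil(0.2 × n_parents)` of the observed `d`
   values without replacement 1000 times and records the resample *mean*
   (the mean, rather than the sum, keeps null moments stable in the sample
   size; the sum is available). `z = (d − null_mean)/null_sd`, flag at
   `|z| ≥ 1.96`. An all-identical `d` vector degenerates the null: all z
   are set to 0 and nothing is flagged. Regulators flagged in both diseases
   are reported with the sign of their change in each.

The eSNP anchoring embeds a biological premise: causal regulators harbour
local genetic variation. The synthetic generator encodes the same premise —
planted regulators carry at least as many cis-eSNPs as their targets —
because an annotation drawn independently of the planted wiring would force
the orientation rules to delete true edges by construction, and the
recovery experiments would measure that contradiction instead of the
method.

# The synthetic-data generator

`generate_cohorts()` draws, from a single seed through named streams (so
each stage can be regenerated independently): shared per-gene baselines
`N(7, 1)`; additive per-(dataset, gene) batch offsets `N(0, batch_shift_sd)`;
residual noise `N(0, noise_sd)`; planted DEGs shifted by
`effect_size × noise_sd` in cases; and a linear regulatory structure
`child = coefficient × parent + noise` with TF parents. A fifth of the
planted DEGs are drawn from the TF labels, mirroring the typical minority
of transcription factors inside a disease gene set, so DEG-derived
candidate sets carry regulators for the network stage. Three regulatory
modes: `"shared"` (wiring identical in both conditions), `"case_only"`
(dependencies active in cases only), and `"rewired"` (each child follows a
control-group TF in controls and a disease-group TF in cases — disease
shifts regulatory control between regulators). `generate_annotations()`
builds every knowledge resource with a configurable fraction of each list
drawn from the planted signal, a right-skewed PPI degree distribution with
genuine hubs, CFG scores in 0–5, and pathway/cell-type lists that are
enriched in the signal or not.

Default conditions (chosen once, as the regime the analysis assumes):
3 cohorts, 30 samples per condition each, 1000 genes, 50 planted DEGs,
effect 1.5 SD, batch SD 1, noise SD 1, 40 TFs, 30 regulatory edges with
coefficient 0.8, 30% of genes with ≥ 1 cis-eSNP.

What the simulator does *not* emulate — and therefore what passing tests do
not show about real data: microarray platform heterogeneity and
probe-to-gene mapping, heavy-tailed or count-distributed expression,
correlated co-expression modules beyond the planted edges, linkage
structure among eSNPs, and realistic single-cell sampling. Results on real
cohorts depend on all of these.

# Problem sizes in the test and acceptance suites

The suites run the full machinery at desk scale, chosen to keep each
experiment's Monte-Carlo error well inside its margin: DEG-recovery power
at the planted conditions (effect 1.5 SD, 30/group, 10 seeds); validation
bookkeeping at the full 1000 iterations over 6 and 11 datasets with the
centroid scorer; network recovery on 40 genes / 8 TFs / 10 rewired edges
with 75 samples per condition and 150 trees over 25 seeds — network
inference needs substantially more samples than mean-shift detection
(each planted edge explains only ≈ 39% of its child's variance at
coefficient 0.8), and the study-scale cohorts for network building are
several times larger still; harness specificity over 200 seeds at 25
iterations. The end-to-end pipeline fixture uses two diseases × five
cohorts of 300 genes each.

# Known limitations

* The pooled repeated-split paired *t* is anticonservative on signal-free
  data (discussed above); its p-values are comparative scores.
* Mean + 2 SD thresholding on a network with *no* real structure still
  passes the upper ≈ 2.5% tail of noise weights; child counts from a
  structureless condition are therefore noisy, which is why the recovery
  experiments plant structure in both conditions (rewiring) rather than
  one.
* Batch adjustment equalises scales, so raw (unstandardised) effect sizes
  are not comparable across differently scaled cohorts after merging.
* Gene identity is an opaque case-sensitive string; no ID-space mapping is
  attempted.
* The hypergeometric background `N` materially affects printed p-values;
  both the overlap matrix and enrichment take it explicitly rather than
  guessing.
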