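---
title: "Methods and design of the stemdyn pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the stemdyn pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemdyn)
```

# Overview

`stemdyn` tracks cancer stem-like cell dynamics across tumor-progression
stages in single-cell RNA-seq, together with the bulk RNA-seq and survival
statistics that anchor the cell-level findings to outcomes. The pipeline
covers: compartment-specific quality control, log-normalization and
highly-variable-gene (HVG) selection, PCA and graph clustering, differential
expression (single-cell Wilcoxon; bulk moderated-t on TMM log2-CPM),
signature construction by FDR/fold-change gates, per-cell signature scoring
(mean-difference and rank-based enrichment), median-split cancer/normal
classification, stem-cluster identification and stage-wise proportion
dynamics, Mann-Kendall trend testing, Kaplan-Meier/log-rank stratification,
and cytokine-receptor cross-talk summarization.

Because the motivating datasets are large droplet-based atlases, the package
ships a synthetic-data generator with planted ground truth. Every claim a
test makes is therefore a statement about recoverable planted structure, not
about any particular public dataset.

# Quality control

Epithelial and immune cells sequence at very different depths, so one
threshold set cannot serve both compartments. The presets are:

| preset     | total counts | detected genes | mito fraction |
|------------|--------------|----------------|---------------|
| epithelial | > 5,000      | > 2,000        | < 8%          |
| immune     | > 1,000      | > 500          | < 8%          |
| human      | (none)       | > 400 and < 7,000 | < 20%      |

All bounds are strict inequalities and boundary cells are removed; the
`human` preset deliberately has no total-count bound (implemented literally
from its published form; we note this may be an omission in the original).
Mitochondrial genes are recognized by an id prefix (`mt-` mouse, `MT-`
human), so no annotation file is needed. Compartment assignment precedes
filtration and is taken from metadata (or marker-based annotation when
available).

# Normalization, HVGs, embedding, clustering

Log-normalization is `ln(1 + count * 10000 / cell_total)`; zeros map to
zeros and the transform is invariant to per-cell depth rescaling. HVGs are
the `n = 3000` genes with the largest variance of log-normalized expression,
with ties broken lexicographically — a deliberately simple, deterministic
statistic; the mean-variance-standardized alternative used by some toolkits
can be slotted in without changing downstream contracts. Scaling is per-gene
centering to unit variance with clipping at ±10 (the conventional default;
constant genes become zero rows). No covariate regression is performed: the
upstream description of "uninteresting variation" removal names no
covariates, so we do not invent any.

PCA keeps 50 components by default (a fixed count rather than a resampling
based selection, which we treat as out of scope) and fixes each component's
sign so its largest-magnitude loading is positive, making embeddings
reproducible. Clustering builds a k = 20 shared-nearest-neighbor graph
(Jaccard edge weights, pruned below 1/15) and partitions it with seeded
Louvain modularity optimization at resolution 0.4.

One behavior worth knowing: the resolution parameter controls granularity,
and at 0.4 an SNN-Louvain pipeline — ours and the standard toolkit alike —
will subdivide a tight isotropic blob of ~100 cells. Recovering two coarse
planted blobs exactly requires a coarser resolution (~0.2). Cluster counts
are not guaranteed monotone in the resolution (greedy modularity search is
heuristic), although they increase in practice. A seeded k-means fallback
with an explicit cluster count is provided for settings that need a fixed k.

# Differential expression and signatures

**Single-cell.** Per-gene two-sided Wilcoxon rank-sum with midrank ties.
When the smaller group has ≤ 8 cells, the p-value is computed by exhaustive
enumeration of all assignments of the observed midranks — the normal
approximation is poor there, and enumeration is exact even under heavy ties
(base `wilcox.test` cannot produce exact p-values with ties). Larger groups
use the tie-corrected normal approximation with continuity correction.
Fold changes are computed on `expm1` of group-mean log-normalized values
with a pseudocount of 1, so the sign always agrees with the group-mean
ordering.

**TMM normalization.** Between-sample scaling factors are computed from a
weighted trimmed mean of M-values: reference sample = the one whose
upper-quartile depth-adjusted expression is closest to the mean; trims of
30% (M) and 5% (A) per side; inverse-variance weights; factors rescaled to
multiply to one. The implementation is cross-checked against the standard
Bioconductor implementation in the test suite.

**Bulk.** Counts become log2-CPM with TMM effective library sizes and a 0.5
pseudocount. Significance uses the empirical-Bayes moderated t-statistic
with a mean-variance trend rather than a per-gene Welch t-test: at 2–3
replicates per group a per-gene variance estimate has so few degrees of
freedom that planted four-fold changes are recovered with sensitivity well
below one-half, whereas sharing variance information across genes restores
essentially full sensitivity at the same false-discovery proportion. This is
the package's deliberate design choice for the small-replicate regime the
pipeline targets. Genes whose normalized values are constant across samples
carry no evidence and are assigned p = 1 explicitly, so floating-point
residuals cannot manufacture statistics. The BH background is the set of
genes with nonzero row sums; zero-sum genes get NA.

**Gates.** A signature is built from a DE table with strict gates:
up-genes need FDR < 0.05 and fold change > 1.5; down-genes FDR < 0.05 and
fold change < 0.67. Curated markers (e.g. the estrogen-receptor program
Esr1, Foxa1, Gata3, Pgr) are merged by simple union into the up set — the
merge rule is an assumption, as no precedence between curated and
data-derived genes is documented anywhere; conflicts with the down set
resolve in favor of curated membership, with a warning. ER-lineage calls
label a cluster ER-high when its fraction of cells expressing the receptor
gene exceeds a threshold (default 0.5 — a documented package default, not a
published value; the original assignment was made by eye from an embedding
plot).

# Scoring and classification

The mean-difference score of a cell is the mean log-normalized expression of
a signature's up-genes minus that of its down-genes. It is linear in the
expression matrix, which makes its behavior easy to reason about and test.

The rank-based score is a single-sample weighted Kolmogorov–Smirnov walk:
genes are ordered by decreasing expression within the cell; in-set genes
step up proportionally to `(N - midrank + 1)^tau` normalized over the set,
out-of-set genes step down by `1/(N - n)`; the score is the maximum positive
plus minimum negative walk deviation, in [-1, 1]. This captures the
rank-enrichment idea of single-sample gene-set variation scoring; the full
kernel-density rank-conditioning of the original algorithm is intentionally
out of scope, and no numeric equality with that package is claimed — the
relevant guarantees are the walk identities (verified against a direct walk
oracle) and planted-signal recovery. Scores can be computed per cell and
aggregated per cluster.

Cancer/normal classification splits scored cells at the sample median:
strictly above is cancer, at or below is normal. The boundary rule matters
for ties; assigning the boundary to "normal" is the conservative reading of
a definition that only calls cells *above* the median cancerous. The
stem-like cluster is the cluster with the highest mean stemness score (ties
broken by label, flagged), and BCSCs — breast cancer stem-like cells — are
operationally the intersection of that cluster with median-split cancer
cells. Stage-wise proportions divide by the per-stage denominator population
and report missing values (not zeros) for empty denominators.

# Trend and survival statistics

The Mann-Kendall statistic is `S = sum_{i<j} sign(x_j - x_i)` with the
tie-corrected variance `[n(n-1)(2n+5) - sum_t t(t-1)(2t+5)]/18` and a
continuity-corrected two-sided normal p-value. For n ≤ 10 an exact
permutation p-value is also reported: by full enumeration of distinct
orderings when ties are present (skipped above 200,000 distinct orderings),
or by the inversion-count recursion when values are distinct. Both routes
are verified against brute-force enumeration.

A practical floor follows from the arithmetic: with four stage medians the
two-sided exact p can never be below 2/4! ≈ 0.083, and the
continuity-corrected normal p not below ≈ 0.089. A perfectly concordant
four-stage median sequence is therefore reported with S = 6 and exact
p = 1/12 — maximally significant *for that n* — and any stricter nominal
level is unattainable by construction. Consumers who need conventional
significance levels should feed the test more ordered groups or per-sample
scores.

Kaplan-Meier curves and the two-group log-rank test delegate to the standard
survival package (censorings follow events at tied times, the standard
convention); cohorts with no events return statistic 0 and p = 1 with a
warning rather than erroring. Survival stratification takes the per-subject
mean expression over a signature's up-genes (a single gene list, matching
the mean-expression grouping of public survival portals) and median-splits
it with the same boundary rule as cell classification.

# Cross-talk

For each ligand-receptor pair the package reports per-cluster mean
expression and fraction of expressing cells (the dot-plot quantities). A
(pair, source, target) triple is flagged when the ligand passes in the
source cluster and the receptor passes in the target cluster; "passes"
means fraction ≥ 0.1 and a cluster-mean z-score (across clusters) ≥ 1.
The z-score rule is this package's explicit operationalization of what is
otherwise a visual dot-plot judgement; both thresholds are configuration
knobs and no claim is made that any published analysis used these values.
Flagging is monotone in both thresholds, and the z-floor means at least two
clusters are required. The shipped pair list seeds the two canonical
cytokine-receptor axes (Cxcl1–Cxcr2 to macrophages, Cxcl16–Cxcr6 to T
cells) plus decoys, and is a small editable TSV, not a curated resource.

# The synthetic-data generator

`simulate_single_cell()` draws negative-binomial counts (mean-dispersion
parameterization, variance `mu + mu^2 d`, default d = 0.3) for four stages
(W07/W09/W11/W17) with an epithelial and an immune compartment. Structure
planted, with defaults chosen once to emulate the regime the analysis
assumes:

* **Depth:** log-normal library sizes, epithelial mean 20,000–25,000 vs
  immune 4,000–5,000 — the depth asymmetry that motivates dual QC. With the
  shipped 4,000-gene universe, typical epithelial cells detect >2,000 genes
  and immune cells >500, so the published thresholds separate good cells
  from the tails rather than annihilating a compartment.
* **Mitochondrial content:** per-cell Beta-distributed fractions around 4%
  (epithelial) and 5% (immune), placing a realistic minority of cells above
  the 8% gate.
* **Cell types:** five marker-defined types (luminal, basal, stem-like,
  T cell, macrophage) with 40-gene identity programs at fold 6. Marker genes
  get at least median baseline expression — a marker that is not well
  detected in its own type would not be a marker.
* **Cancer:** a configurable fraction of stem-like (or all epithelial)
  cells per stage carries the planted cancer signature: 60 up-genes
  multiplied and 40 down-genes divided by the signature effect. The
  generator default is 8 (a strong, easily recoverable effect for
  recovery experiments); the shipped pipeline configuration uses 4, strong
  enough for median-split recovery but gentle enough that normal and
  cancer stem-like cells still co-cluster in one mixed stem cluster — the
  topology the analysis expects.
* **Cross-talk:** the ligands Cxcl1/Cxcl16 are planted as stem-cell markers
  and the receptors Cxcr2/Cxcr6 as macrophage/T-cell markers.
* **Seeding:** one global seed drives derived per-stage seeds, so stages can
  be regenerated independently and the whole object is bit-reproducible.

`simulate_bulk()` reuses the same gene universe and planted signature for
tumor-vs-normal replicates (default 3v3, fold 4, dispersion 0.05);
`simulate_cohort()` plants a hazard ratio on subjects whose signature-gene
expression is shifted upward, with independent exponential censoring whose
rate is expressed relative to the baseline hazard.

The generator deliberately does **not** simulate doublets, ambient RNA,
batch effects, or transcriptome-wide correlation structure. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
clean overdispersed-count assumptions — they do not certify performance on
real data with those artifacts.

# Problem sizes and numerical choices

The shipped pipeline configuration uses 4,000 genes × 480 cells, 3v3 bulk
replicates and a 200-subject cohort — small enough to run interactively,
large enough that every stage has signal to find. The test suite's largest
experiment uses 2,000 genes × 2,000 cells for score-recovery and clustering
checks, 200 Monte-Carlo replicates for log-rank size/power, and 50 seeds for
cross-talk ranking. Further numerical conventions: strict inequalities at
every published gate; exact enumeration limits as described above; a 1e-12
zero-range tolerance for degenerate genes in bulk DE; clip at ±10 in
scaling; cluster labels ordered by decreasing size; deterministic
tie-breaks (lexicographic gene ids in HVG selection, cluster label order in
stem-cluster ties, sign-fixed PCA components).

# Known limitations

* The rank-enrichment score is a transparent weighted-KS statistic, not a
  drop-in numeric replacement for kernel-conditioned gene-set variation
  scores.
* Bulk DE targets the two-group small-replicate design only; no dispersion
  shrinkage on the count scale, no multi-factor designs.
* Graph clustering inherits the resolution behavior of modularity methods;
  cluster counts at a fixed resolution depend on data density.
* Survival analysis is limited to KM/log-rank stratification; no Cox
  models or multivariable adjustment.
* Mann-Kendall on a handful of group medians has the significance floor
  described above.
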