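---
title: "Methods: joint transcriptome and paired TCR analysis of alloreactive T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint transcriptome and paired TCR analysis of alloreactive T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allorep)
```

# Scope and model

`allorep` analyzes sorted alloreactive (donor-reactive) T cells profiled
jointly for their transcriptome (scRNA-seq counts) and their T cell
receptor alpha/beta repertoire (per-cell chain records from an
IgBLAST-class aligner). The package covers the desk-scale analysis chain:
cell quality control, log-normalization, highly-variable-gene selection,
PCA, shared-nearest-neighbor graph clustering, per-cluster and
pre/post-transplant differential expression, gene-length-bias-aware GO
over-representation, a five-rule TCR chain filter cascade with paired
clonotype construction, and Shannon Equitability diversity. A synthetic
data generator with complete ground truth stands in for real sorted-cell
data so that every stage can be validated against known injections.

## Cell quality control

Cells are summarized by the number of expressed genes (count > 0), total
counts, and the percentage of counts on mitochondrial genes (symbol prefix
`MT-`, overridable). Removal is by strict inequality — fewer than 500
expressed genes (low quality), more than 5000 (likely doublets), or more
than 5% mitochondrial signal (dying cells) — so boundary cells at exactly
500 genes or exactly 5.0% mito are retained. A cell with zero total counts
has no defined mito fraction; we define it as 0 and flag the cell for
removal regardless. Filtering is idempotent and errors loudly (rather than
returning an empty object) when nothing survives.

## Normalization, feature selection, PCA

Normalized expression is `ln(1 + count / cell_total * 10000)`; the scale
factor 10,000 puts values on a per-10k-counts scale and `log1p` keeps
zeros at zero. Gene selection ranks genes by a variance-stabilizing
statistic: raw-count variance is regressed on the mean (loess of log10
variance on log10 mean, span 0.3, degree 2), counts are standardized by
the trend-expected standard deviation, clipped at `sqrt(n_cells)`, and
genes are ranked by the variance of the clipped values. A plain
log-normalized-variance ranking is available (`method = "dispersion"`).
Ties break deterministically by gene id and constant genes always rank
after genes with signal. By default only protein-coding genes are
eligible, which requires a `biotype` annotation column.

PCA operates on the selected genes after centering and unit scaling, with
scaled values clipped at ±10 so single outlier cells cannot dominate a
component. The first 16 components are retained by default. Component
signs are fixed so each component's largest-magnitude loading is positive,
making coordinates reproducible across runs and platforms. Explained
variance fractions are reported relative to total input variance and sum
to 1 over all computable components. Cross-chip batch integration is out
of scope; an optional per-chip gene-wise centering switch
(`center_by_chip`, off by default) offers a light control when chips carry
additive offsets — synthetic fixtures control batch structure directly, so
the switch is exercised rather than relied on.

## Graph clustering

The neighbor graph is a Euclidean k-nearest-neighbor graph (k = 20 by
default; the choice is config-exposed since no single value is canonical)
whose edges are weighted by the Jaccard overlap of the two cells' neighbor
sets (shared nearest neighbors); zero-weight edges are dropped. Clustering
is Louvain multilevel modularity optimization with a resolution parameter,
fixed at 0.4 by default. Determinism and order-invariance are handled
structurally: vertices are sorted by barcode and then shuffled by a
seed-derived permutation before optimization, so the same seed always
yields the same partition regardless of input cell order. Labels are
re-indexed 0..K−1 by decreasing cluster size, so label 0 is always the
largest cluster.

Clusters are annotated by marker-set expression margin (mean expression of
the set inside the cluster minus outside; largest positive margin wins).
A cluster is flagged for exclusion as a non-T contaminant when a
configured contaminant marker (e.g. CD14, CD19, NCAM1) is significantly
upregulated in one-vs-rest differential expression (adjusted p < 0.01 and
log2FC > 1, both config-exposed) — the same rule by which a
monocyte-admixture cluster would be dropped from a sorted-T-cell dataset.

## Differential expression

The default test is the two-sided Wilcoxon rank-sum test. When both groups
have at most 10 cells the p-value is computed by exact enumeration of all
group assignments of the observed (possibly tied) ranks; otherwise a
tie-corrected normal approximation with continuity correction is used. A
logistic-regression likelihood-ratio test (`method = "logistic_lr"`) is
provided as the alternative; both share the same filtering and
fold-change path. Genes expressed in fewer than 5% of cells in *both*
groups are skipped (the one-group reading of the 5% rule: a gene silent in
one group but present in the other is precisely the interesting case).
The fold change is
`log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))` — group means on
the depth-normalized scale with a pseudocount of 1, so it is finite,
antisymmetric under group swap, and matches the convention of the
single-cell toolkits this field uses. Multiple-testing adjustment is
Bonferroni by default (Benjamini–Hochberg selectable). Ranked marker
tables keep genes with adjusted p strictly below 1e-5 and order by
decreasing absolute fold change, ties by gene id.

The pre/post contrast compares post-transplant against pre-transplant
cells of one cluster and one stimulus (donor or third-party), pooling
cells across patients; genes lost after transplantation therefore carry
negative fold change. The third-party contrast is the built-in control
for donor-unrelated time effects. A per-patient covariate is left to
future work; at the cell counts this assay produces (100–300 cells per
chip), pooled-cell testing is the pragmatic choice.

## GO over-representation with length bias

Longer transcripts yield more reads and hence more power, so DE calls are
biased toward long genes. The probability weighting function (PWF) is
estimated by binning genes into 10 quantile bins of length, taking per-bin
DE proportions, and smoothing with isotonic regression against bin median
length — a monotone nondecreasing estimate of P(DE | length). Genes
without a length get the mean weight; a degenerate DE vector (all or no
genes DE) yields a flat function with a warning.

Each category's over-represented p-value is the upper tail
P(X ≥ numDEInCat) of the Wallenius noncentral hypergeometric
distribution, with odds equal to the mean weight inside the category over
the mean weight outside. The pmf is evaluated through its integral
representation (substituted to an exponentially damped integrand on
(0, ∞), integrated adaptively at rel.tol 1e-12), which is stable for
desk-scale universes; with uniform weights it reduces exactly to the
central hypergeometric tail, which is verified to 1e-10 in the tests, and
with biased weights it is cross-checked against a weighted-urn simulation
(`sample(prob =, replace = FALSE)` draws exactly from the multivariate
Wallenius law). Up- and downregulated DE sets are tested separately. The
DE-set cutoff is adjusted p < 0.01 for cluster-vs-rest enrichment and
< 0.1 for the (lower-powered) pre/post enrichment, both config-exposed.

## TCR chain filter cascade

Chain records pass five rules in order: (1) productivity — in frame
(CDR3 nucleotide length a multiple of 3) with no premature stop codon; the
record's `productive` flag is trusted when present and recomputed from the
junction otherwise; (2) a minimum of 25 reads, inclusive; (3) primary
chain selection (r = 1): per cell and locus, the highest-read surviving
chain, ties broken lexicographically by junction; (4) the top rule: the
selected chain must hold strictly more than 0.8 of the total reads of that
cell and locus; (5) the locus-fraction rule: the locus must hold strictly
more than 0.1 of the cell's total TCR reads. The read totals in rules 4
and 5 are computed over *all* chains of the cell (including chains already
removed as unproductive or low-read) — the conservative reading, since a
cell whose locus signal is mostly unproductive noise should not gain
confidence from that noise being filtered first. Boundary conventions
("minimum of 25" inclusive; "greater than 0.8"/"0.1" strict) are fixed by
the quoted wording of the rules and pinned by tests on both sides of each
threshold. Every decision is recorded in a per-chain trace (`top`,
`flocus`, first failing rule).

Clonotype keys are `locus:V:J:CDR3nt`. The D segment is excluded from the
key — TRA has no D and D calls are unreliable — while the V(D)J usage
table keeps the full triple. A paired key (`TRA|TRB`) exists only for
cells where both chains survive the cascade. TRD chains run through the
cascade but never enter clonotypes or diversity; they are reported in a
sidecar table.

## Shannon diversity

For each sample and clonotype level (TRA, TRB, paired), with `n_i` cells
per unique clonotype and `N` cells total, `p_i = n_i / N`,
`H = −Σ p_i ln p_i`, and the Shannon Equitability Index `EH = H / ln(S)`
for `S` unique clonotypes. At S = 1 the formula is 0/0; we define EH = 0,
matching its verbal meaning (every cell the same clonotype). EH = 1 means
every cell carries a different clonotype. EH is invariant under clonotype
relabeling and under duplicating every cell, and strictly decreases when
counts concentrate — all pinned by tests against a brute-force entropy
oracle.

# The synthetic data generator

The generator emulates the statistical structure this analysis assumes,
at the scale of the sorted-alloreactive-cell assay: ~200 cells per sample
(chips carry on the order of 100–300 sorted cells; the exact per-sample
count is a convention, not a measured value), 3 transcriptional clusters
with 20 planted marker genes each at log2FC 2, negative-binomial counts
(log-normal baseline means, median 2, dispersion 0.4), 13 mitochondrial
genes whose per-cell expression fraction follows Beta(2, 60) (mean ≈ 3.2%,
so the 5% QC filter has work to do), 3% doublets built as exact sums of
two independent cell profiles, and 5% dying cells whose mito fraction is
drawn from the upper 5% tail of the same Beta law. Cluster proportions are
deliberately uneven so size-ordered labels are informative.

Repertoires are polyclonal by default: 90% of cells receive a fresh
singleton clonotype and the rest draw from a power-law pool
(`p_i ∝ i^−α`, α = 0.25), matching the near-1 equitability this cell
population shows. Primary chains carry negative-binomial reads around 100;
with probability 0.1 a locus gains a secondary chain with uniform reads on
1..0.3×primary (placing chains on both sides of the top and flocus rules),
and with probability 0.05 a chain is made unproductive by frameshift or an
injected internal stop codon — so productivity is recomputable from the
junction itself, not just a flag. CDR3s are random in-frame codon strings
(8–16 codons, no stops) under the standard genetic code.

What the generator does *not* emulate: ambient RNA contamination, UMI
saturation, batch effects beyond an optional per-chip mean shift, V(D)J
segment-pairing biases, and transcriptional heterogeneity within a
clonotype. Tests passing on this generator therefore demonstrate
correctness of the algorithms under the stated noise model, not robustness
to every artifact of real chips.

# Numerical and design choices

- **Determinism.** Every stochastic step derives its stream from one
  integer seed through a fixed linear map (kept below 2^31); identical
  configurations give bit-identical outputs, and cluster labels are
  canonicalized by size so cell order never matters.
- **Exactness switches.** Wilcoxon switches from exact enumeration to the
  normal approximation when either group exceeds 10 cells; the Wallenius
  integral is summed term-by-term over the upper tail with the binomial
  coefficients held in log space.
- **Degenerate inputs.** All-zero cells are flagged at QC and rejected by
  normalization; an empty post-QC matrix, an empty graph, a group smaller
  than 3 cells, an empty category list, and a level with no clonotypes
  all raise explicit errors rather than returning empty results; the
  all-genes-filtered DE case returns an empty table with a warning.
- **Problem sizes.** Validation runs use 100–300 cells and 300–2000 genes
  per sample across 10 seeds — the scale of the assay itself, where every
  stage completes in seconds.
- **Interface.** The pipeline is driven from R (`run_pipeline()` plus
  readers/writers for Matrix Market counts, AIRR-style chain TSVs, and
  GMT/TSV gene sets); no shell wrapper is shipped, as the expected user
  drives the analysis from scripts or the console.

# Known limitations

Anchor-based cross-chip integration, UMAP embeddings, and data-driven
resolution selection are deliberately out of scope (the resolution is a
fixed parameter). The logistic-regression test uses no latent covariates.
Pre/post contrasts pool cells across patients without a patient random
effect. The PWF uses binned isotonic smoothing rather than a monotone
spline; with few DE genes the bin proportions are coarse, which is why
the pre/post GO cutoff is the laxer 0.1.
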