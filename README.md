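# allorep

Joint single-cell transcriptome and paired TCR repertoire analysis of
alloreactive (donor-reactive) T cells.

After kidney transplantation, recipient T cells reactive against donor
antigen can gradually lose responsiveness (donor-specific
hyporesponsiveness). Studying this process at single-cell resolution means
combining two modalities for the same sorted cells: an scRNA-seq count
matrix, and per-cell TRA/TRB chain records from an IgBLAST-class aligner.
`allorep` implements the full desk-scale analysis chain for such data —
for immunologists and bioinformaticians working with small sorted T-cell
populations (on the order of 100–300 cells per chip):

- **Cell QC and normalization** — strict-boundary filters (< 500 or
  \> 5000 expressed genes, > 5% mitochondrial signal) and
  `ln(1 + count/total × 10⁴)` log-normalization.
- **Feature selection and PCA** — variance-stabilizing HVG ranking
  (loess mean–variance trend, clipped standardized counts), scaled and
  clipped PCA with deterministic component signs (16 dims by default).
- **Clustering** — shared-nearest-neighbor graph (Jaccard weights) and
  Louvain modularity optimization at resolution 0.4, with size-ordered
  labels, seed-stable and cell-order-invariant; marker-based cluster
  annotation and contaminant-cluster exclusion (e.g. CD14⁺ admixture).
- **Differential expression** — Wilcoxon rank-sum (exact tie-aware
  enumeration for groups ≤ 10 cells, tie-corrected normal approximation
  otherwise) or logistic-regression LRT; fold change
  `log2((mean(expm1(in))+1)/(mean(expm1(out))+1))`; one-vs-rest cluster
  markers and post-vs-pre contrasts per cluster and stimulus, with the
  third-party stimulation as built-in control.
- **GO over-representation with gene-length bias correction** — an
  isotonic probability-weighting function P(DE | length) and the
  Wallenius noncentral hypergeometric upper tail
  P(X ≥ numDEInCat | category size, length odds), reducing exactly to the
  hypergeometric tail under uniform weights.
- **TCR filter cascade and clonotypes** — the five rules in order:
  productive CDR3 (in frame, no premature stop), ≥ 25 reads, primary
  chain per cell × locus (r = 1), top = max(n)/reads > 0.8,
  flocus = reads/sum(reads) > 0.1; paired clonotype keys
  (`locus:V:J:CDR3nt`), V(D)J usage tables, cross-sample clonotype
  overlap.
- **Repertoire diversity** — Shannon index `H = −Σ pᵢ ln pᵢ` and
  Equitability `EH = H / ln S` per sample and clonotype level (TRA, TRB,
  paired), with EH ≡ 0 for monoclonal samples.
- **Synthetic data with ground truth** — a negative-binomial scRNA
  generator (planted cluster markers, mito contamination, doublets, dead
  cells) plus a paired-repertoire generator (power-law clonality,
  secondary and unproductive chains), so every stage can be validated
  against known injections.

## Worked example

```r
library(allorep)

cfg <- synth_config(n_cells_per_sample = 150, rng_seed = 7)
study <- simulate_study(cfg, n_patients = 3, n_thirdparty_patients = 2,
                        condition_effect = list(cluster = 1, n_genes = 5,
                                                log2fc = -0.8))
study$counts
#> count_matrix: 1500 genes x 1500 cells, 10 sample(s)

report <- run_pipeline(study$counts, study$chains,
                       config = pipeline_config(min_genes = 200,
                                                n_hvg = 500, seed = 7))
report
#> run_report: 1168 / 1500 cells retained after QC; 3 clusters
#>   TCR: 2763 / 3293 chains retained; 1493 cells with clonotypes
```

QC removed the planted dying cells and doublets (1168 of 1500 retained),
and clustering recovered the three planted transcriptional clusters. The
top one-vs-rest markers of cluster 0 are planted marker genes at their
injected fold change (log2FC ≈ 2):

```r
head(report$markers[["0"]][, c("gene_id", "symbol", "avg_log2FC", "p_adjusted")], 3)
#>           gene_id   symbol avg_log2FC    p_adjusted
#> 1 ENSG00000000646 GENE0646   1.960859 1.769482e-129
#> 2 ENSG00000000632 GENE0632   1.874655 3.265038e-116
#> 3 ENSG00000001074 GENE1074   1.864835 7.190543e-118
```

The post-vs-pre contrast within cluster 0 of donor-stimulated cells
recovers the planted down-shift — four of the five top-ranked genes are
the injected ones, all with negative fold change (the fifth planted gene
ranks just below):

```r
de <- report$prepost[["cluster0_don"]]
head(de[order(de$p_adjusted), c("gene_id", "avg_log2FC", "p_adjusted")], 4)
#>              gene_id avg_log2FC   p_adjusted
#> 438  ENSG00000000438 -0.8948110 1.645145e-07
#> 972  ENSG00000000972 -0.8107115 4.313455e-04
#> 1158 ENSG00000001158 -0.5878616 7.365207e-02
#> 348  ENSG00000000348 -0.5434448 5.645882e-01
```

The repertoire is highly polyclonal, as configured: paired (TRA AND TRB)
equitability sits at or near 1 in every sample, meaning nearly every cell
carries its own clonotype:

```r
head(subset(report$tcr$diversity, level == "TRA_AND_TRB"), 3)
#>      sample_id       level   S   N        H        EH
#> 3   P0_pre_don TRA_AND_TRB 124 125 4.817223 0.9993656
#> 6  P0_post_don TRA_AND_TRB 128 128 4.852030 1.0000000
#> 9 P0_pre_thirdP TRA_AND_TRB 127 127 4.844187 1.0000000
```

`published_equitability()` returns the published per-sample EH reference
table; the six donor-stimulated paired values average 0.97.

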