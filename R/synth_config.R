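#' Configuration for the synthetic joint scRNA + scTCR generator
#'
#' Returns a validated configuration list for [simulate_counts()] and
#' [simulate_repertoire()]. Defaults emulate the sorted-alloreactive-T-cell
#' study conditions: 200 cells per sample (chips carry on the order of
#' 100-300 sorted cells), 3 transcriptional clusters plus rare contaminants,
#' negative-binomial counts, a small mitochondrial gene set whose per-cell
#' expression fraction follows a Beta law, a low doublet and dead-cell rate,
#' and a highly polyclonal repertoire (nearly every cell its own clonotype).
#'
#' @param n_cells_per_sample cells generated per sample.
#' @param n_genes total genes, including mitochondrial genes.
#' @param n_clusters number of transcriptional clusters.
#' @param marker_genes_per_cluster planted marker genes per cluster
#'   (disjoint across clusters).
#' @param marker_log2fc log2 fold change of a marker gene in its own cluster
#'   relative to the rest.
#' @param nb_dispersion negative-binomial dispersion (1/size); larger means
#'   noisier counts.
#' @param baseline_mean median of the log-normal distribution of baseline
#'   per-gene mean counts.
#' @param mito_gene_count number of genes carrying the mitochondrial symbol
#'   prefix.
#' @param mito_fraction_beta_params length-2 numeric `(a, b)`: Beta
#'   parameters of the per-cell mitochondrial expression fraction of healthy
#'   cells.
#' @param doublet_rate fraction of cells that are doublets (sum of two
#'   cell profiles).
#' @param dead_cell_rate fraction of cells whose mito fraction is drawn from
#'   the upper 5% tail of the Beta law (dying cells).
#' @param clonality_alpha power-law exponent of the clonotype frequency
#'   vector (`p_i` proportional to `i^-alpha`); `Inf` collapses the
#'   repertoire onto a single clonotype.
#' @param unique_clonotype_fraction probability that a cell receives a fresh
#'   singleton clonotype instead of drawing from the shared pool; 1 makes
#'   every cell its own clonotype.
#' @param clonotype_pool_size size of the shared clonotype pool; `NULL`
#'   means one pool entry per cell.
#' @param unproductive_chain_prob probability that a generated chain is
#'   unproductive (out of frame or containing a premature stop).
#' @param secondary_chain_prob probability that a cell carries an extra
#'   low-read chain on a locus.
#' @param reads_per_chain_mean mean read count of a primary chain.
#' @param rng_seed integer seed; the same configuration yields bit-identical
#'   output.
#'
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_cells_per_sample = 200L,
                         n_genes = 1500L,
                         n_clusters = 3L,
                         marker_genes_per_cluster = 20L,
                         marker_log2fc = 2,
                         nb_dispersion = 0.4,
                         baseline_mean = 2,
                         mito_gene_count = 13L,
                         mito_fraction_beta_params = c(2, 60),
                         doublet_rate = 0.03,
                         dead_cell_rate = 0.05,
                         clonality_alpha = 0.25,
                         unique_clonotype_fraction = 0.9,
                         clonotype_pool_size = NULL,
                         unproductive_chain_prob = 0.05,
                         secondary_chain_prob = 0.1,
                         reads_per_chain_mean = 100,
                         rng_seed = 1L) {
  cfg <- list(n_cells_per_sample = as.integer(n_cells_per_sample),
              n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
              marker_log2fc = marker_log2fc,
              nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean,
              mito_gene_count = as.integer(mito_gene_count),
              mito_fraction_beta_params = mito_fraction_beta_params,
              doublet_rate = doublet_rate,
              dead_cell_rate = dead_cell_rate,
              clonality_alpha = clonality_alpha,
              unique_clonotype_fraction = unique_clonotype_fraction,
              clonotype_pool_size =
                if (is.null(clonotype_pool_size)) NULL
                else as.integer(clonotype_pool_size),
              unproductive_chain_prob = unproductive_chain_prob,
              secondary_chain_prob = secondary_chain_prob,
              reads_per_chain_mean = reads_per_chain_mean,
              rng_seed = as.integer(rng_seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  pos_int <- c("n_cells_per_sample", "n_genes", "n_clusters",
               "marker_genes_per_cluster")
  for (f in pos_int)
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1L) cfg_error(f, "must be a positive integer")
  if (!is_count(cfg$mito_gene_count) || cfg$mito_gene_count < 0L)
    cfg_error("mito_gene_count", "must be a nonnegative integer")
  probs <- c("doublet_rate", "dead_cell_rate", "unique_clonotype_fraction",
             "unproductive_chain_prob", "secondary_chain_prob")
  for (f in probs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      cfg_error(f, "must be a probability in [0, 1]")
  }
  for (f in c("nb_dispersion", "baseline_mean", "reads_per_chain_mean"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) cfg_error(f, "must be > 0")
  if (!is.numeric(cfg$clonality_alpha) || cfg$clonality_alpha < 0)
    cfg_error("clonality_alpha", "must be >= 0 (Inf allowed)")
  b <- cfg$mito_fraction_beta_params
  if (!is.numeric(b) || length(b) != 2L || any(b <= 0))
    cfg_error("mito_fraction_beta_params", "must be two positive numbers (a, b)")
  if (!is.null(cfg$clonotype_pool_size) &&
      (!is_count(cfg$clonotype_pool_size) || cfg$clonotype_pool_size < 1L))
    cfg_error("clonotype_pool_size", "must be a positive integer or NULL")
  if (cfg$mito_gene_count + cfg$n_clusters * cfg$marker_genes_per_cluster >
      cfg$n_genes)
    cfg_error("n_genes", "too small for the requested marker and mito genes")
  if (!is_count(cfg$rng_seed)) cfg_error("rng_seed", "must be an integer")
  invisible(cfg)
}
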