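#' Simulate a gene x cell count matrix with known ground truth
#'
#' Draws negative-binomial counts for one or more samples under a shared
#' gene model: log-normal baseline means, disjoint per-cluster marker genes
#' shifted by `marker_log2fc`, a mitochondrial gene block whose per-cell
#' expression fraction follows `Beta(a, b)` (upper-tail draws for dying
#' cells), and doublets formed as the sum of two independent cell profiles.
#' Everything injected is recorded in the returned ground truth.
#'
#' @param cfg a [synth_config()].
#' @param samples optional data.frame describing samples (columns
#'   `sample_id`, `patient`, `timepoint`, `stimulus`, `chip`; optional
#'   `n_cells`). Default: a single pre-transplant donor-stimulated sample.
#' @param condition_effect optional list injecting a timepoint effect:
#'   `list(cluster =, n_genes =, log2fc =, stimulus = "don")`. Cells of that
#'   cluster in `timepoint == "post"` samples with the matching stimulus
#'   have the selected genes' means multiplied by `2^log2fc`.
#'
#' @return list with `counts` (a [count_matrix]) and `truth`, a list holding
#'   `clusters` (named integer vector, 1-based true cluster per barcode),
#'   `markers` (data.frame gene_id/cluster/log2fc), `doublets`,
#'   `dead_cells` (barcode vectors), `doublet_parents` (per doublet a
#'   genes x 2 matrix of the two parent profiles), `mito_fraction` (named
#'   per-cell target fraction) and `condition_effect` (data.frame of
#'   affected genes, or NULL).
#' @export
simulate_counts <- function(cfg, samples = NULL, condition_effect = NULL) {
  validate_synth_config(cfg)
  if (is.null(samples))
    samples <- data.frame(sample_id = "S1", patient = "P1",
                          timepoint = "pre", stimulus = "don", chip = "chip1")
  if (is.null(samples$n_cells)) samples$n_cells <- cfg$n_cells_per_sample

  gm <- gene_model(cfg, condition_effect)

  per_sample <- lapply(seq_len(nrow(samples)), function(i) {
    set.seed(derive_seed(cfg$rng_seed, 100L + i))
    simulate_one_sample(cfg, gm, samples[i, , drop = FALSE])
  })

  counts <- do.call(cbind, lapply(per_sample, `[[`, "counts"))
  meta <- do.call(rbind, lapply(per_sample, `[[`, "meta"))
  m <- count_matrix(counts, gm$genes, meta)

  truth <- list(
    clusters = do.call(c, lapply(per_sample, `[[`, "clusters")),
    markers = gm$markers,
    doublets = do.call(c, lapply(per_sample, `[[`, "doublets")),
    dead_cells = do.call(c, lapply(per_sample, `[[`, "dead")),
    doublet_parents = do.call(c, lapply(per_sample, `[[`, "parents")),
    mito_fraction = do.call(c, lapply(per_sample, `[[`, "mito_fraction")),
    condition_effect = gm$condition_effect)
  list(counts = m, truth = truth)
}

# shared gene-level model: ids, baseline means, marker/mito assignment
gene_model <- function(cfg, condition_effect = NULL) {
  set.seed(derive_seed(cfg$rng_seed, 0L))
  g <- cfg$n_genes
  n_mito <- cfg$mito_gene_count
  gene_id <- sprintf("ENSG%011d", seq_len(g))
  symbol <- sprintf("GENE%04d", seq_len(g))
  is_mito <- rep(FALSE, g)
  if (n_mito > 0L) {
    mito_idx <- (g - n_mito + 1L):g
    is_mito[mito_idx] <- TRUE
    symbol[mito_idx] <- sprintf("MT-G%d", seq_len(n_mito))
  }
  genes <- data.frame(gene_id = gene_id, symbol = symbol,
                      biotype = "protein_coding",
                      length_bp = round(rlnorm(g, log(2000), 0.7)))
  base_mu <- rlnorm(g, log(cfg$baseline_mean), 1)

  nonmito <- which(!is_mito)
  n_mark <- cfg$n_clusters * cfg$marker_genes_per_cluster
  marker_idx <- sample(nonmito, n_mark)
  markers <- data.frame(
    gene_id = gene_id[marker_idx],
    cluster = rep(seq_len(cfg$n_clusters), each = cfg$marker_genes_per_cluster),
    log2fc = cfg$marker_log2fc,
    idx = marker_idx)

  ce <- NULL
  if (!is.null(condition_effect)) {
    pool <- setdiff(nonmito, marker_idx)
    idx <- sample(pool, condition_effect$n_genes)
    ce <- data.frame(gene_id = gene_id[idx], idx = idx,
                     cluster = condition_effect$cluster,
                     log2fc = condition_effect$log2fc,
                     stimulus = condition_effect$stimulus %||% "don")
  }
  list(genes = genes, base_mu = base_mu, is_mito = is_mito,
       markers = markers, condition_effect = ce)
}

simulate_one_sample <- function(cfg, gm, srow) {
  n <- srow$n_cells
  g <- cfg$n_genes
  barcodes <- sprintf("%s_cell%03d", srow$sample_id, seq_len(n))

  # uneven cluster proportions so size-ordered labels are informative
  w <- seq(2, 1, length.out = cfg$n_clusters)
  clusters <- sample(cfg$n_clusters, n, replace = TRUE, prob = w / sum(w))

  n_dead <- round(cfg$dead_cell_rate * n)
  dead <- if (n_dead > 0L) sample(n, n_dead) else integer(0)
  ab <- cfg$mito_fraction_beta_params
  mito_f <- rbeta(n, ab[1], ab[2])
  if (n_dead > 0L)  # dying cells: upper 5% tail of the same Beta law
    mito_f[dead] <- qbeta(runif(n_dead, 0.95, 1), ab[1], ab[2])

  mu <- cell_mean_matrix(cfg, gm, clusters, mito_f, srow)
  counts <- matrix(rnbinom(g * n, mu = as.vector(mu),
                           size = 1 / cfg$nb_dispersion), nrow = g)

  n_doub <- round(cfg$doublet_rate * n)
  doub <- if (n_doub > 0L) sample(setdiff(seq_len(n), dead),
                                  min(n_doub, n - n_dead)) else integer(0)
  parents <- list()
  for (j in doub) {
    cl2 <- sample(cfg$n_clusters, 1)
    f2 <- rbeta(1, ab[1], ab[2])
    mu2 <- cell_mean_matrix(cfg, gm, cl2, f2, srow)
    p2 <- rnbinom(g, mu = as.vector(mu2), size = 1 / cfg$nb_dispersion)
    parents[[barcodes[j]]] <- cbind(parent1 = counts[, j], parent2 = p2)
    counts[, j] <- counts[, j] + p2
  }

  meta <- data.frame(barcode = barcodes, sample_id = srow$sample_id,
                     patient = srow$patient, timepoint = srow$timepoint,
                     stimulus = srow$stimulus, chip = srow$chip)
  list(counts = counts, meta = meta,
       clusters = setNames(clusters, barcodes),
       doublets = barcodes[doub], dead = barcodes[dead], parents = parents,
       mito_fraction = setNames(mito_f, barcodes))
}

# genes x cells matrix of NB means for one sample
cell_mean_matrix <- function(cfg, gm, clusters, mito_f, srow) {
  g <- cfg$n_genes
  n <- length(clusters)
  mu <- matrix(gm$base_mu, nrow = g, ncol = n)
  for (k in seq_len(cfg$n_clusters)) {
    idx <- gm$markers$idx[gm$markers$cluster == k]
    in_k <- clusters == k
    if (any(in_k)) mu[idx, in_k] <- mu[idx, in_k] * 2^cfg$marker_log2fc
  }
  ce <- gm$condition_effect
  if (!is.null(ce) && srow$timepoint == "post" &&
      srow$stimulus == ce$stimulus[1]) {
    in_cl <- clusters == ce$cluster[1]
    if (any(in_cl)) mu[ce$idx, in_cl] <- mu[ce$idx, in_cl] * 2^ce$log2fc[1]
  }
  if (any(gm$is_mito)) {
    t_nm <- colSums(mu[!gm$is_mito, , drop = FALSE])
    base_mito <- sum(gm$base_mu[gm$is_mito])
    s <- mito_f / (1 - mito_f) * t_nm / base_mito
    mu[gm$is_mito, ] <- outer(gm$base_mu[gm$is_mito], s)
  }
  mu
}
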