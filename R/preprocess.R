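#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of expressed genes (count > 0),
#' total counts, and the percentage of total counts coming from
#' mitochondrial genes (symbols starting with `mito_prefix`). Cells with
#' zero total counts get `pct_mito = 0` and are flagged for removal.
#'
#' @param m a [count_matrix].
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return data.frame with columns `barcode`, `n_genes_expressed`,
#'   `total_counts`, `pct_mito`, `flag_zero_total`.
#' @export
compute_qc_metrics <- function(m, mito_prefix = "MT-") {
  counts <- m$counts
  n_expr <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  is_mito <- startsWith(m$genes$symbol, mito_prefix)
  mito <- if (any(is_mito)) Matrix::colSums(counts[is_mito, , drop = FALSE])
          else rep(0, ncol(counts))
  pct <- ifelse(total > 0, 100 * mito / total, 0)
  data.frame(barcode = m$cell_meta$barcode,
             n_genes_expressed = as.integer(n_expr),
             total_counts = as.integer(total),
             pct_mito = pct,
             flag_zero_total = total == 0)
}

#' Filter low-quality cells
#'
#' Removes cells with fewer than `min_genes` expressed genes (low quality),
#' more than `max_genes` expressed genes (likely doublets), or more than
#' `max_pct_mito` percent mitochondrial signal (dying cells). The removal
#' inequalities are strict — "fewer than 500" / "more than 5000" / "more
#' than 5%" — so a cell at exactly 500 genes and exactly 5% mito is
#' retained. Cell order is preserved.
#'
#' @param m a [count_matrix].
#' @param qc QC table from [compute_qc_metrics()], aligned to `m`'s cells.
#' @param min_genes minimum expressed genes (retained if `>=`).
#' @param max_genes maximum expressed genes (retained if `<=`).
#' @param max_pct_mito maximum mitochondrial percentage (retained if `<=`).
#' @return filtered [count_matrix]; errors if no cell survives.
#' @export
filter_cells <- function(m, qc, min_genes = 500, max_genes = 5000,
                         max_pct_mito = 5) {
  stopifnot(identical(qc$barcode, m$cell_meta$barcode))
  keep <- qc$n_genes_expressed >= min_genes &
    qc$n_genes_expressed <= max_genes &
    qc$pct_mito <= max_pct_mito &
    !qc$flag_zero_total
  if (!any(keep))
    stop("all cells removed by QC filtering", call. = FALSE)
  count_matrix(m$counts[, keep, drop = FALSE], m$genes,
               m$cell_meta[keep, , drop = FALSE])
}

#' Log-normalize counts
#'
#' Each cell's counts are divided by the cell's total counts, multiplied by
#' `scale_factor` (default 10,000) and natural-log transformed with
#' `log1p`: `value = ln(1 + count / total * scale_factor)`.
#'
#' @param m a [count_matrix]; every cell must have total counts > 0.
#' @param scale_factor library-size scale factor.
#' @return an object of class `normalized_matrix`: list with `values`
#'   (sparse genes x cells matrix), `scale_factor`, `genes`, `cell_meta`.
#' @export
normalize_counts <- function(m, scale_factor = 10000) {
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0))
    stop("cells with zero total counts present; run QC filtering first",
         call. = FALSE)
  v <- m$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$counts)
  structure(list(values = v, scale_factor = scale_factor,
                 genes = m$genes, cell_meta = m$cell_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " cells (scale factor ", x$scale_factor, ")\n", sep = "")
  invisible(x)
}

#' Select highly variable genes
#'
#' Ranks genes by a variance-stabilizing statistic: per-gene raw-count
#' variance is regressed on the mean (loess of log10 variance on log10
#' mean), counts are standardized by the trend-expected standard deviation,
#' clipped at `sqrt(n_cells)`, and genes are ranked by the variance of the
#' clipped values. `method = "dispersion"` ranks by plain log-normalized
#' variance instead. Ties break by gene id; constant genes rank last.
#'
#' @param nm a `normalized_matrix` (used for gene annotation and, for the
#'   vst statistic, its provenance counts must be supplied via `counts`).
#' @param counts the raw [count_matrix] the normalization came from
#'   (required for `method = "vst"`).
#' @param n_top number of genes to return (clamped to eligible genes).
#' @param protein_coding_only restrict to genes annotated
#'   `biotype == "protein_coding"`; requires a `biotype` column.
#' @param method `"vst"` (default) or `"dispersion"`.
#' @return character vector of gene ids, ranked most variable first.
#' @export
select_hvg <- function(nm, counts = NULL, n_top = 2000,
                       protein_coding_only = TRUE, method = c("vst", "dispersion")) {
  method <- match.arg(method)
  genes <- nm$genes
  eligible <- rep(TRUE, nrow(genes))
  if (protein_coding_only) {
    if (is.null(genes$biotype))
      stop("protein_coding_only = TRUE but gene annotation has no biotype",
           call. = FALSE)
    eligible <- genes$biotype == "protein_coding"
  }
  stat <- if (method == "vst") {
    if (is.null(counts))
      stop("method = 'vst' needs the raw count_matrix via `counts`",
           call. = FALSE)
    vst_statistic(counts$counts)
  } else {
    apply(as.matrix(nm$values), 1, var)
  }
  stat[!eligible] <- -Inf
  ord <- order(-stat, genes$gene_id)
  ord <- ord[stat[ord] > -Inf]
  # never pick constant genes ahead of genes with signal
  ord <- ord[order(stat[ord] == 0)]
  head(genes$gene_id[ord], min(n_top, sum(eligible)))
}

# variance of standardized, clipped counts under a loess mean-variance trend
vst_statistic <- function(counts, span = 0.3) {
  x <- as.matrix(counts)
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  stat <- rep(0, nrow(x))
  use <- v > 0 & mu > 0
  if (sum(use) < 10) return(v)   # too few informative genes for a trend
  fit <- loess(log10(v[use]) ~ log10(mu[use]), span = span, degree = 2)
  exp_sd <- sqrt(10^predict(fit))
  clip <- sqrt(n)
  z <- (x[use, , drop = FALSE] - mu[use]) / exp_sd
  z <- pmin(pmax(z, -clip), clip)
  stat[use] <- apply(z, 1, var)
  stat
}

#' PCA on scaled highly variable genes
#'
#' Centers and unit-scales each HVG across cells (clipping scaled values at
#' `clip`, +/-10 by default), optionally centers gene means within each
#' chip, and computes principal components. Component signs are fixed so
#' each component's largest-magnitude gene loading is positive. Explained
#' variance fractions are relative to the total variance of the scaled
#' input, over all computable components.
#'
#' @param nm a `normalized_matrix`.
#' @param hvg character vector of gene ids to use (length >= `n_dims`).
#' @param n_dims number of components to retain.
#' @param clip clipping bound for scaled values.
#' @param center_by_chip if TRUE, gene means are centered per chip before
#'   scaling (a light alternative to cross-chip integration).
#' @return object of class `pca_embedding`: list with `coordinates`
#'   (cells x n_dims), `explained_variance` (fraction per retained
#'   component), `hvg`, `cell_meta`.
#' @export
run_pca <- function(nm, hvg, n_dims = 16, clip = 10, center_by_chip = FALSE) {
  if (length(hvg) < n_dims)
    stop("need at least n_dims = ", n_dims, " HVGs, got ", length(hvg),
         call. = FALSE)
  x <- as.matrix(nm$values[match(hvg, nm$genes$gene_id), , drop = FALSE])
  n_cells <- ncol(x)
  if (n_dims > min(n_cells, length(hvg)))
    stop("n_dims exceeds min(cells, genes)", call. = FALSE)
  if (center_by_chip) {
    for (ch in unique(nm$cell_meta$chip)) {
      j <- nm$cell_meta$chip == ch
      x[, j] <- x[, j, drop = FALSE] - rowMeans(x[, j, drop = FALSE])
    }
  }
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  z <- pmin(pmax((x - mu) / s, -clip), clip)
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(n_dims, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| of each component positive
  for (j in seq_len(k)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) coords[, j] <- -coords[, j]
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rownames(coords) <- nm$cell_meta$barcode
  structure(list(coordinates = coords,
                 explained_variance = ev[seq_len(k)],
                 explained_variance_all = ev,
                 hvg = hvg, cell_meta = nm$cell_meta),
            class = "pca_embedding")
}
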