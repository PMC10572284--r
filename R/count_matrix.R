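#' Construct a raw count matrix container
#'
#' Bundles a nonnegative integer gene x cell count matrix with gene
#' annotation and per-cell metadata. This is the raw-input container for the
#' pipeline; all entries must be integral counts, gene ids and cell barcodes
#' must be unique.
#'
#' @param counts numeric or sparse [Matrix::Matrix] of nonnegative integer
#'   counts, genes in rows, cells in columns. Dimnames are taken from
#'   `genes$gene_id` and `cell_meta$barcode` if absent.
#' @param genes data.frame with columns `gene_id`, `symbol`, and optionally
#'   `biotype` and `length_bp` (one row per matrix row).
#' @param cell_meta data.frame with columns `barcode`, `sample_id`,
#'   `patient`, `timepoint` (`"pre"`/`"post"`), `stimulus`
#'   (`"don"`/`"thirdP"`), `chip` (one row per matrix column).
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix), `genes`, `cell_meta`.
#' @export
count_matrix <- function(counts, genes, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (nrow(counts) != nrow(genes))
    stop("genes table has ", nrow(genes), " rows but counts has ",
         nrow(counts), " gene rows", call. = FALSE)
  if (ncol(counts) != nrow(cell_meta))
    stop("cell_meta has ", nrow(cell_meta), " rows but counts has ",
         ncol(counts), " cell columns", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genes table", call. = FALSE)
  if (anyDuplicated(cell_meta$barcode))
    stop("duplicate cell barcodes", call. = FALSE)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be nonnegative integers", call. = FALSE)
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cell_meta$barcode
  structure(list(counts = counts, genes = genes, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells, ", length(unique(x$cell_meta$sample_id)), " sample(s)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to a set of cells
#'
#' @param m a [count_matrix].
#' @param barcodes character vector of barcodes to retain (order preserved
#'   as in `m`).
#' @return a [count_matrix] restricted to those cells.
#' @export
subset_cells <- function(m, barcodes) {
  keep <- m$cell_meta$barcode %in% barcodes
  if (!any(keep)) stop("no cells left after subsetting", call. = FALSE)
  count_matrix(m$counts[, keep, drop = FALSE], m$genes,
               m$cell_meta[keep, , drop = FALSE])
}
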