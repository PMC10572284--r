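#' Write a count matrix as Matrix Market + TSV sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv` (gene annotation), `barcodes.tsv` and
#' `metadata.tsv` (per-cell metadata) into `dir`.
#'
#' @param m a [count_matrix].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  write.table(m$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(m$cell_meta$barcode, file.path(dir, "barcodes.tsv"))
  write.table(m$cell_meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `metadata.tsv`.
#' @return a [count_matrix]; integer-exact round trip of [write_counts()].
#' @export
read_counts <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx_path)) stop("missing ", mtx_path, call. = FALSE)
  counts <- tryCatch(Matrix::readMM(mtx_path), error = function(e)
    stop("malformed Matrix Market file ", mtx_path, ": ",
         conditionMessage(e), call. = FALSE))
  genes <- read.delim(file.path(dir, "genes.tsv"))
  meta <- read.delim(file.path(dir, "metadata.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(genes) != nrow(counts))
    stop("genes.tsv rows (", nrow(genes), ") do not match matrix rows (",
         nrow(counts), ")", call. = FALSE)
  if (!identical(barcodes, meta$barcode))
    stop("barcodes.tsv and metadata.tsv disagree", call. = FALSE)
  count_matrix(counts, genes, meta)
}

AIRR_REQUIRED <- c("cell_id", "locus", "v_call", "j_call", "junction",
                   "consensus_count")

#' Read an AIRR-style rearrangement table
#'
#' Reads a TSV of per-cell chain observations as produced by an
#' IgBLAST-class aligner. Required columns: `cell_id`, `locus`, `v_call`,
#' `j_call`, `junction`, `consensus_count`; `d_call`, `junction_aa` and
#' `productive` are used when present and extra columns are tolerated.
#' `productive` values `T/F/TRUE/FALSE` are parsed as logical.
#'
#' @param path TSV file path.
#' @return data.frame of chain records.
#' @export
read_chains <- function(path) {
  if (!file.exists(path)) stop("missing ", path, call. = FALSE)
  ch <- read.delim(path, colClasses = c(junction = "character"))
  miss <- setdiff(AIRR_REQUIRED, names(ch))
  if (length(miss))
    stop("rearrangement table ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("productive" %in% names(ch) && !is.logical(ch$productive))
    ch$productive <- toupper(as.character(ch$productive)) %in% c("T", "TRUE")
  ch
}

#' Write an AIRR-style rearrangement table
#'
#' @param chains chain data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path) {
  ch <- chains
  if ("productive" %in% names(ch))
    ch$productive <- ifelse(ch$productive, "T", "F")
  write.table(ch, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-set annotation (two-column TSV or GMT)
#'
#' Two-column TSV: columns `term` and `gene` (header required), one
#' gene-term pair per line, optional third column `term_name`. GMT: one
#' term per line, `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path; format inferred from the `.gmt` extension.
#' @return named list of gene-id vectors, with attribute `term_names`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("missing ", path, call. = FALSE)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- strsplit(readLines(path), "\t")
    sets <- lapply(lines, function(x) x[-(1:2)])
    names(sets) <- vapply(lines, `[`, character(1), 1)
    tn <- vapply(lines, `[`, character(1), 2)
  } else {
    df <- read.delim(path)
    if (!all(c("term", "gene") %in% names(df)))
      stop("gene-set TSV needs columns 'term' and 'gene'", call. = FALSE)
    sets <- split(df$gene, df$term)
    tn <- if ("term_name" %in% names(df))
      vapply(split(df$term_name, df$term), `[`, character(1), 1)
    else setNames(names(sets), names(sets))
  }
  attr(sets, "term_names") <- setNames(tn, names(sets))
  sets
}

#' Read gene lengths
#'
#' @param path TSV with columns `gene_id` and `length_bp`.
#' @return named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- read.delim(path)
  if (!all(c("gene_id", "length_bp") %in% names(df)))
    stop("gene-length TSV needs columns 'gene_id' and 'length_bp'",
         call. = FALSE)
  setNames(df$length_bp, df$gene_id)
}
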