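#' Canonical clonotype key
#'
#' A clonotype is identified by locus, V gene, J gene and CDR3 nucleotide
#' sequence (`locus:V:J:cdr3_nt`). The D segment is excluded from the key
#' (TRA has none and D calls are unreliable); the V(D)J usage table keeps
#' the full triple separately.
#'
#' @param locus,v_call,j_call,cdr3_nt character vectors.
#' @return character vector of keys.
#' @export
clonotype_key <- function(locus, v_call, j_call, cdr3_nt) {
  paste(locus, v_call, j_call, cdr3_nt, sep = ":")
}

#' Apply the TCR chain filter cascade
#'
#' Runs the five-rule cascade on a chain table, in order:
#' \enumerate{
#'   \item productivity: keep chains that are in frame with no premature
#'     stop codon (the record's `productive` flag when set, otherwise
#'     computed from the junction) — strict removal of unproductive chains;
#'   \item minimum reads: keep chains with `consensus_count >= min_reads`
#'     (inclusive: "a minimum of 25 reads");
#'   \item primary chain (r = 1): per cell and locus keep only the
#'     highest-read surviving chain, ties broken lexicographically by
#'     junction;
#'   \item top rule: the selected chain's reads divided by the total reads
#'     of all chains of that cell and locus (including chains already
#'     removed) must be strictly greater than `top_threshold`;
#'   \item locus fraction: the locus's share of the cell's total TCR reads
#'     (`flocus = locus reads / cell reads`, computed over all chains)
#'     must be strictly greater than `flocus_threshold`.
#' }
#'
#' @param chains data.frame with columns `cell_id`, `locus`, `v_call`,
#'   `d_call`, `j_call`, `junction`, `junction_aa`, `consensus_count`, and
#'   optionally `productive` (logical; NA = compute from junction). Extra
#'   columns are tolerated.
#' @param min_reads minimum reads per chain (inclusive).
#' @param top_threshold strict lower bound on `top`.
#' @param flocus_threshold strict lower bound on `flocus`.
#' @return list with `chains` (surviving chains with added trace columns
#'   `top` and `flocus`) and `trace` (per input chain: pass/fail per rule
#'   and the first `fail_reason`, or `"pass"`).
#' @export
filter_chains <- function(chains, min_reads = 25, top_threshold = 0.8,
                          flocus_threshold = 0.1) {
  required <- c("cell_id", "locus", "v_call", "j_call", "junction",
                "consensus_count")
  miss <- setdiff(required, names(chains))
  if (length(miss))
    stop("chain table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(chains)
  prod_flag <- if ("productive" %in% names(chains))
    as.logical(chains$productive) else rep(NA, n)
  computed <- is_productive_cdr3(chains$junction)
  productive <- ifelse(is.na(prod_flag), computed, prod_flag)
  # unparseable junction with no flag: drop with reason
  productive[is.na(productive)] <- FALSE

  reads_ok <- chains$consensus_count >= min_reads

  # locus totals over ALL chains (pre-productivity, the conservative read)
  cl <- paste(chains$cell_id, chains$locus, sep = "\r")
  locus_total <- ave(chains$consensus_count, cl, FUN = sum)
  cell_total <- ave(chains$consensus_count, chains$cell_id, FUN = sum)
  flocus <- locus_total / cell_total

  alive <- productive & reads_ok
  # r = 1: highest-read surviving chain per (cell, locus)
  is_primary <- rep(FALSE, n)
  for (grp in split(seq_len(n), cl)) {
    cand <- grp[alive[grp]]
    if (!length(cand)) next
    best <- cand[order(-chains$consensus_count[cand],
                       chains$junction[cand])][1]
    is_primary[best] <- TRUE
  }
  top <- chains$consensus_count / locus_total
  top_ok <- top > top_threshold
  flocus_ok <- flocus > flocus_threshold
  keep <- alive & is_primary & top_ok & flocus_ok

  fail_reason <- rep("pass", n)
  fail_reason[!flocus_ok] <- "flocus"
  fail_reason[is_primary & !top_ok] <- "top"
  fail_reason[alive & !is_primary] <- "not_primary"
  fail_reason[productive & !reads_ok] <- "min_reads"
  fail_reason[!productive] <- "unproductive"
  fail_reason[keep] <- "pass"

  trace <- data.frame(cell_id = chains$cell_id, locus = chains$locus,
                      junction = chains$junction,
                      reads = chains$consensus_count,
                      productive = productive, reads_ok = reads_ok,
                      selected = is_primary, top = top, flocus = flocus,
                      retained = keep, fail_reason = fail_reason)
  out <- chains[keep, , drop = FALSE]
  out$top <- top[keep]
  out$flocus <- flocus[keep]
  rownames(out) <- NULL
  list(chains = out, trace = trace)
}

#' Build per-cell clonotypes from filtered chains
#'
#' One record per cell that retains at least one TRA or TRB chain after
#' [filter_chains()]. The paired key (`tra_key|trb_key`) is present only
#' when both chains survive. TRD chains never enter clonotypes and are
#' returned in a sidecar table.
#'
#' @param filtered the `chains` element of a [filter_chains()] result (or
#'   any chain table that has already passed the cascade).
#' @return list with `clonotypes` (data.frame `cell_id`, `tra_clonotype`,
#'   `trb_clonotype`, `paired_key`; NA where a chain is absent) and `trd`
#'   (retained TRD chains).
#' @export
build_clonotypes <- function(filtered) {
  trd <- filtered[filtered$locus == "TRD", , drop = FALSE]
  ab <- filtered[filtered$locus %in% c("TRA", "TRB"), , drop = FALSE]
  key <- clonotype_key(ab$locus, ab$v_call, ab$j_call, ab$junction)
  cells <- unique(ab$cell_id)
  tra <- setNames(rep(NA_character_, length(cells)), cells)
  trb <- tra
  ia <- ab$locus == "TRA"
  tra[ab$cell_id[ia]] <- key[ia]
  trb[ab$cell_id[!ia]] <- key[!ia]
  paired <- ifelse(!is.na(tra) & !is.na(trb), paste(tra, trb, sep = "|"),
                   NA_character_)
  list(clonotypes = data.frame(cell_id = cells,
                               tra_clonotype = unname(tra),
                               trb_clonotype = unname(trb),
                               paired_key = unname(paired)),
       trd = trd)
}

#' Shannon diversity and equitability of a clonotype repertoire
#'
#' For the cells carrying a clonotype at the requested level, computes the
#' number of unique clonotypes `S`, per-clonotype proportions
#' `p_i = n_i / N`, the Shannon Diversity Index `H = -sum p_i ln p_i`, and
#' the Shannon Equitability Index `EH = H / ln(S)` (defined as 0 when
#' `S = 1`). `EH` is 0 when every cell shares one clonotype and 1 when
#' every cell has a different clonotype.
#'
#' @param clonotypes data.frame from [build_clonotypes()].
#' @param level `"TRA"`, `"TRB"` or `"TRA_AND_TRB"` (paired).
#' @param sample_id optional label stored on the result.
#' @return one-row data.frame with `sample_id`, `level`, `S`, `N`, `H`,
#'   `EH`.
#' @export
shannon_diversity <- function(clonotypes, level = c("TRA_AND_TRB", "TRA", "TRB"),
                              sample_id = NA_character_) {
  level <- match.arg(level)
  keys <- switch(level,
                 TRA = clonotypes$tra_clonotype,
                 TRB = clonotypes$trb_clonotype,
                 TRA_AND_TRB = clonotypes$paired_key)
  keys <- keys[!is.na(keys)]
  if (!length(keys))
    stop("no cells carry a clonotype at level ", level, call. = FALSE)
  n_i <- table(keys)
  N <- sum(n_i)
  p <- as.numeric(n_i) / N
  H <- -sum(p * log(p))
  S <- length(n_i)
  EH <- if (S >= 2) H / log(S) else 0
  data.frame(sample_id = sample_id, level = level, S = as.integer(S),
             N = as.integer(N), H = H, EH = EH)
}

#' Per-sample diversity table across clonotype levels
#'
#' @param clonotypes data.frame from [build_clonotypes()] with an added
#'   `sample_id` column (or supply `sample_ids`).
#' @param sample_ids optional per-cell sample labels aligned to rows.
#' @param levels clonotype levels to report.
#' @return data.frame, one row per sample x level with cells at that level.
#' @export
diversity_table <- function(clonotypes,
                            sample_ids = clonotypes$sample_id,
                            levels = c("TRA", "TRB", "TRA_AND_TRB")) {
  if (is.null(sample_ids))
    stop("sample ids required (column sample_id or argument sample_ids)",
         call. = FALSE)
  out <- list()
  for (s in unique(sample_ids)) {
    sub <- clonotypes[sample_ids == s, , drop = FALSE]
    for (lv in levels) {
      row <- tryCatch(shannon_diversity(sub, lv, sample_id = s),
                      error = function(e) NULL)
      if (!is.null(row)) out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' V(D)J segment-usage table
#'
#' Counts cells per unique (V, D, J) combination and locus, with
#' proportions normalized within each sample and locus. Segments are
#' ordered by genomic position using the bundled segment-order table
#' (unknown segments sort last, with a warning).
#'
#' @param filtered retained chain table from [filter_chains()].
#' @param sample_ids optional per-chain sample labels; defaults to a single
#'   sample.
#' @param segment_order optional character vector of segment names in
#'   genomic order; default: the bundled order table.
#' @return data.frame `sample_id`, `locus`, `v_call`, `d_call`, `j_call`,
#'   `n_cells`, `proportion`, sorted by segment order then count.
#' @export
vdj_table <- function(filtered, sample_ids = NULL, segment_order = NULL) {
  if (is.null(sample_ids)) sample_ids <- rep("sample", nrow(filtered))
  if (is.null(segment_order)) segment_order <- tr_segment_order()
  d_call <- if ("d_call" %in% names(filtered)) filtered$d_call else ""
  df <- data.frame(sample_id = sample_ids, locus = filtered$locus,
                   v_call = filtered$v_call, d_call = d_call,
                   j_call = filtered$j_call)
  agg <- stats::aggregate(cbind(n_cells = rep(1L, nrow(df))) ~
                            sample_id + locus + v_call + d_call + j_call,
                          data = df, FUN = sum)
  grp <- paste(agg$sample_id, agg$locus)
  agg$proportion <- agg$n_cells / ave(agg$n_cells, grp, FUN = sum)
  vr <- match(agg$v_call, segment_order)
  if (anyNA(vr))
    warning("segment name(s) not in order table, placed last: ",
            paste(unique(agg$v_call[is.na(vr)]), collapse = ", "),
            call. = FALSE)
  vr[is.na(vr)] <- length(segment_order) + 1L
  jr <- match(agg$j_call, segment_order)
  jr[is.na(jr)] <- length(segment_order) + 1L
  agg <- agg[order(agg$sample_id, agg$locus, vr, jr, -agg$n_cells), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Bundled TRA/TRB segment order
#'
#' Genomic-order listing of the V, D and J segment names used by the
#' synthetic generator's nomenclature (numeric order within each segment
#' class, V before D before J per locus).
#'
#' @return character vector of segment names.
#' @export
tr_segment_order <- function() {
  path <- system.file("extdata", "tr_segment_order.tsv", package = "allorep")
  read.delim(path, header = TRUE)$segment
}

#' Shared clonotypes between samples
#'
#' Symmetric matrix of the number of clonotype keys (at one level) shared
#' between each pair of samples; the diagonal holds each sample's own
#' unique-clonotype count.
#'
#' @param clonotypes data.frame from [build_clonotypes()] with `sample_id`.
#' @param level clonotype level (as in [shannon_diversity()]).
#' @param sample_ids optional per-cell sample labels.
#' @return integer matrix, samples x samples.
#' @export
clonotype_overlap <- function(clonotypes, level = "TRA_AND_TRB",
                              sample_ids = clonotypes$sample_id) {
  keys <- switch(level,
                 TRA = clonotypes$tra_clonotype,
                 TRB = clonotypes$trb_clonotype,
                 TRA_AND_TRB = clonotypes$paired_key)
  ok <- !is.na(keys)
  sets <- split(keys[ok], sample_ids[ok])
  sets <- lapply(sets, unique)
  ns <- names(sets)
  m <- matrix(0L, length(ns), length(ns), dimnames = list(ns, ns))
  for (i in seq_along(ns)) for (j in seq_along(ns))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  m
}
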