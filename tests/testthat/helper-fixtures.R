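# shared fixtures and independent oracles, built in code

# tiny count_matrix from a dense matrix
make_cm <- function(mat, symbols = NULL, meta = NULL) {
  g <- nrow(mat)
  n <- ncol(mat)
  genes <- data.frame(gene_id = sprintf("G%03d", seq_len(g)),
                      symbol = symbols %||% sprintf("S%03d", seq_len(g)),
                      biotype = "protein_coding",
                      length_bp = 1000 + seq_len(g))
  if (is.null(meta))
    meta <- data.frame(barcode = sprintf("c%03d", seq_len(n)),
                       sample_id = "S1", patient = "P1",
                       timepoint = "pre", stimulus = "don", chip = "chip1")
  count_matrix(mat, genes, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one chain record row
chain <- function(cell, locus, reads, junction = "TGTGCAAGC",
                  v = "TRAV1", j = "TRAJ1", d = "", productive = NA) {
  data.frame(cell_id = cell, locus = locus, v_call = v, d_call = d,
             j_call = j, junction = junction,
             junction_aa = translate_cdr3(junction),
             consensus_count = as.integer(reads), productive = productive)
}

# independent brute-force two-sided rank-sum p by label enumeration
oracle_rank_sum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  n1 <- length(x)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)])
  combos <- combn(n, n1)
  ws <- apply(combos, 2, function(i) sum(r[i]))
  lo <- sum(ws <= w_obs + 1e-9) / ncol(combos)
  hi <- sum(ws >= w_obs - 1e-9) / ncol(combos)
  min(1, 2 * min(lo, hi))
}

# brute-force Shannon H over a clonotype multiset
oracle_shannon_h <- function(keys) {
  h <- 0
  for (k in unique(keys)) {
    p <- sum(keys == k) / length(keys)
    h <- h - p * log(p)
  }
  h
}

# clonotype table with given per-cell paired keys
make_clonotypes <- function(keys, sample_id = "S1") {
  data.frame(cell_id = sprintf("c%03d", seq_along(keys)),
             tra_clonotype = paste0("TRA:", keys),
             trb_clonotype = paste0("TRB:", keys),
             paired_key = paste0("TRA:", keys, "|TRB:", keys),
             sample_id = rep(sample_id, length(keys)))
}
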