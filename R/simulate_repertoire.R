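#' Simulate paired TRA/TRB chain records for a set of cells
#'
#' Each cell receives one true TRA and one true TRB chain. Clonotype
#' identities come from a power-law frequency pool (`p_i` proportional to
#' `i^-clonality_alpha`) except that with probability
#' `unique_clonotype_fraction` a cell gets a fresh singleton clonotype —
#' the polyclonal regime the sorted alloreactive repertoires show. Primary
#' chain reads are negative binomial around `reads_per_chain_mean`
#' (truncated at 1); with probability `secondary_chain_prob` a locus gains
#' an extra low-read chain (uniform on 1..0.3 x primary reads); with
#' probability `unproductive_chain_prob` a chain is made unproductive by
#' frameshift or an internal stop codon, so productivity can be recomputed
#' from the junction itself.
#'
#' @param cfg a [synth_config()].
#' @param cells nonempty character vector of cell ids (one sample).
#' @param rng_seed seed for this sample's repertoire; defaults to a value
#'   derived from `cfg$rng_seed`.
#'
#' @return list with `chains` (AIRR-style data.frame: cell_id, locus,
#'   v_call, d_call, j_call, junction, junction_aa, consensus_count,
#'   productive) and `truth` (`pool_props`, `pairs` data.frame of each
#'   cell's true TRA/TRB/paired clonotype keys, `clonotype_props` realized
#'   true paired-clonotype proportions).
#' @export
simulate_repertoire <- function(cfg, cells, rng_seed = NULL) {
  validate_synth_config(cfg)
  if (length(cells) < 1L) stop("cells must be nonempty", call. = FALSE)
  set.seed(rng_seed %||% derive_seed(cfg$rng_seed, 7919L))
  n <- length(cells)

  m <- cfg$clonotype_pool_size %||% n
  p <- if (is.infinite(cfg$clonality_alpha)) c(1, rep(0, m - 1L))
       else { w <- seq_len(m)^(-cfg$clonality_alpha); w / sum(w) }
  pool <- replicate(m, random_pair_identity(), simplify = FALSE)

  fresh <- runif(n) < cfg$unique_clonotype_fraction
  idx <- ifelse(fresh, NA_integer_, sample.int(m, n, replace = TRUE, prob = p))
  ids <- lapply(seq_len(n), function(i)
    if (is.na(idx[i])) random_pair_identity() else pool[[idx[i]]])

  chains <- list()
  pairs <- data.frame(cell_id = cells,
                      tra_key = NA_character_, trb_key = NA_character_)
  for (i in seq_len(n)) {
    id <- ids[[i]]
    for (locus in c("TRA", "TRB")) {
      ch <- id[[locus]]
      reads <- max(1L, rnbinom(1, mu = cfg$reads_per_chain_mean, size = 5))
      rec <- chain_row(cells[i], locus, ch, reads, cfg)
      chains[[length(chains) + 1L]] <- rec
      if (locus == "TRA") pairs$tra_key[i] <- clonotype_key("TRA", ch$v, ch$j, ch$nt)
      else pairs$trb_key[i] <- clonotype_key("TRB", ch$v, ch$j, ch$nt)
      if (runif(1) < cfg$secondary_chain_prob) {
        ch2 <- random_chain_identity(locus)
        r2 <- sample.int(max(1L, as.integer(0.3 * reads)), 1)
        chains[[length(chains) + 1L]] <- chain_row(cells[i], locus, ch2, r2, cfg)
      }
    }
  }
  chains <- do.call(rbind, chains)
  rownames(chains) <- NULL
  pairs$paired_key <- paste(pairs$tra_key, pairs$trb_key, sep = "|")
  props <- table(pairs$paired_key) / n
  list(chains = chains,
       truth = list(pool_props = p, pairs = pairs,
                    clonotype_props = as.numeric(props)))
}

chain_row <- function(cell, locus, ch, reads, cfg) {
  nt <- ch$nt
  productive <- TRUE
  if (runif(1) < cfg$unproductive_chain_prob) {
    productive <- FALSE
    nt <- corrupt_cdr3(nt)
  }
  data.frame(cell_id = cell, locus = locus, v_call = ch$v, d_call = ch$d,
             j_call = ch$j, junction = nt, junction_aa = translate_cdr3(nt),
             consensus_count = as.integer(reads), productive = productive)
}

# in-frame CDR3 of 8-16 codons with no stop codon
random_cdr3 <- function() {
  n_codons <- sample(8:16, 1)
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

# frameshift (length not a multiple of 3) or internal stop codon
corrupt_cdr3 <- function(nt) {
  if (runif(1) < 0.5) return(substr(nt, 1L, nchar(nt) - 1L))
  k <- sample.int(nchar(nt) %/% 3L - 1L, 1)
  paste0(substr(nt, 1L, 3L * (k - 1L)), "TAA", substr(nt, 3L * k + 1L, nchar(nt)))
}

random_chain_identity <- function(locus) {
  if (locus == "TRA")
    list(v = sprintf("TRAV%d", sample.int(45, 1)), d = "",
         j = sprintf("TRAJ%d", sample.int(56, 1)), nt = random_cdr3())
  else
    list(v = sprintf("TRBV%d", sample.int(30, 1)),
         d = sprintf("TRBD%d", sample.int(2, 1)),
         j = sprintf("TRBJ%d", sample.int(13, 1)), nt = random_cdr3())
}

random_pair_identity <- function() {
  list(TRA = random_chain_identity("TRA"), TRB = random_chain_identity("TRB"))
}
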