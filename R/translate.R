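# standard genetic code; stops rendered as "*"
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

NONSTOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Translate a CDR3 nucleotide junction
#'
#' Translates complete codons of a nucleotide string under the standard
#' genetic code; a trailing incomplete codon is ignored, stop codons are
#' rendered as `"*"` and unknown codons as `"X"`. Returns `NA` for empty or
#' non-ACGT input of length < 3.
#'
#' @param nt character vector of nucleotide strings.
#' @return character vector of amino-acid strings.
#' @export
translate_cdr3 <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    s <- toupper(s)
    nc <- nchar(s) %/% 3L
    if (nc == 0L) return(NA_character_)
    codons <- substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
    aa <- GENETIC_CODE_TABLE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Decide whether a CDR3 junction is productive
#'
#' Productive means in frame (nucleotide length a multiple of 3) with no
#' premature stop codon in the translation.
#'
#' @param cdr3_nt character vector of nucleotide junctions.
#' @return logical vector (`NA` when the junction is missing/unparseable).
#' @export
is_productive_cdr3 <- function(cdr3_nt) {
  in_frame <- !is.na(cdr3_nt) & nzchar(cdr3_nt) & nchar(cdr3_nt) %% 3L == 0L
  aa <- translate_cdr3(cdr3_nt)
  out <- in_frame & !is.na(aa) & !grepl("*", aa, fixed = TRUE)
  out[is.na(cdr3_nt) | !nzchar(cdr3_nt)] <- NA
  out
}
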