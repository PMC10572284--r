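#' Published per-sample Shannon Equitability values
#'
#' The published per-sample Shannon Equitability Index table for the
#' sorted alloreactive T cell samples (TRA, TRB and matched TRA AND TRB
#' clonotype levels, donor- and third-party-stimulated, pre- and
#' post-transplant), bundled for comparison against pipeline output. The
#' matched TRA AND TRB values of the six donor-stimulated samples average
#' 0.97, the headline polyclonality figure.
#'
#' @return data.frame with columns `sample_id`, `stimulus`, `timepoint`,
#'   `TRA`, `TRB`, `TRA_AND_TRB`.
#' @export
published_equitability <- function() {
  read.delim(system.file("extdata", "published_equitability.tsv",
                         package = "allorep"))
}
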