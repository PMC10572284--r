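#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp rnbinom rbeta rlnorm runif qbeta var
#'   p.adjust phyper pchisq pnorm glm integrate isoreg approx sd
#'   quantile loess predict setNames dist binomial median ave aggregate
#' @importFrom utils read.delim write.table combn head
#' @importFrom methods as
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# configuration error naming the offending field
cfg_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

# deterministic child seeds derived from one user seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 48271L + as.integer(offset)) %% 2147483587L
}
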