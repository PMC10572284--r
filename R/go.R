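#' Fit a gene-length probability weighting function
#'
#' Estimates the monotone nondecreasing probability that a gene is called
#' differentially expressed as a function of its transcript length: genes
#' are grouped into `n_bins` quantile bins of length, the per-bin DE
#' proportion is smoothed by isotonic regression against the bin median
#' length, and each gene's weight is interpolated from the smoothed curve.
#' Genes without a length get the mean weight. Longer transcripts yield
#' more reads, so unequal weights are expected in read-count data; the
#' weights feed the biased-urn enrichment test ([go_test()]).
#'
#' @param de_flags named logical vector: gene id -> is DE.
#' @param gene_lengths named numeric vector: gene id -> transcript length
#'   (bp); must cover >= 90% of the flagged genes.
#' @param n_bins number of quantile bins.
#' @return named numeric vector of weights (one per gene in `de_flags`),
#'   with attribute `"pwf"` holding the fitted bin curve.
#' @export
fit_pwf <- function(de_flags, gene_lengths, n_bins = 10) {
  genes <- names(de_flags)
  len <- gene_lengths[genes]
  if (mean(!is.na(len)) < 0.9)
    stop("gene lengths available for fewer than 90% of tested genes",
         call. = FALSE)
  if (all(de_flags) || !any(de_flags)) {
    warning("degenerate DE vector (all or none DE); flat weights",
            call. = FALSE)
    return(setNames(rep(mean(de_flags) + 1e-6, length(genes)), genes))
  }
  has_len <- !is.na(len)
  l <- len[has_len]
  d <- de_flags[has_len]
  brk <- unique(quantile(l, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(l, breaks = brk, include.lowest = TRUE)
  prop <- tapply(d, bin, mean)
  mid <- tapply(l, bin, median)
  ok <- !is.na(prop)
  iso <- isoreg(mid[ok], prop[ok])
  curve <- data.frame(length = iso$x[order(iso$x)],
                      weight = iso$yf[order(iso$x)])
  w <- rep(NA_real_, length(genes))
  if (nrow(curve) == 1L) {
    w[has_len] <- curve$weight
  } else {
    w[has_len] <- approx(curve$length, curve$weight, xout = l, rule = 2)$y
  }
  w[!has_len] <- mean(w[has_len])
  w <- pmax(w, 1e-6)  # keep odds finite
  out <- setNames(w, genes)
  attr(out, "pwf") <- curve
  out
}

#' Upper tail of the Wallenius noncentral hypergeometric distribution
#'
#' Probability of drawing at least `k` white balls when `n` balls are taken
#' without replacement from an urn of `m1` white and `m2` black balls, the
#' white balls having odds `odds` relative to black. With `odds = 1` this
#' is the central hypergeometric tail. The probability mass function is
#' evaluated through its integral representation
#' `P(X = x) = C(m1,x) C(m2,n-x) D int_0^inf exp(-D v) (1-exp(-w v))^x
#' (1-exp(-v))^(n-x) dv` with `D = w (m1-x) + (m2-n+x)`.
#'
#' @param k threshold count of white draws.
#' @param m1,m2 white/black ball counts.
#' @param n number of draws.
#' @param odds weight of a white ball relative to a black ball.
#' @return `P(X >= k)`.
#' @export
wallenius_upper_tail <- function(k, m1, m2, n, odds = 1) {
  if (k <= 0) return(1)
  hi <- min(n, m1)
  if (k > hi) return(0)
  p <- sum(vapply(k:hi, wallenius_pmf, numeric(1),
                  m1 = m1, m2 = m2, n = n, odds = odds))
  min(1, max(0, p))
}

wallenius_pmf <- function(x, m1, m2, n, odds) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(0)
  w <- odds
  d <- w * (m1 - x) + (m2 - (n - x))
  if (d == 0) return(1)  # all balls drawn
  lb <- lchoose(m1, x) + lchoose(m2, n - x)
  f <- function(v)
    exp(lb + log(d) - d * v +
          x * log1p(-exp(-w * v)) + (n - x) * log1p(-exp(-v)))
  int <- integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 500L, stop.on.error = FALSE)
  int$value
}

#' Gene Ontology over-representation with length-bias correction
#'
#' For each category, tests whether it contains more DE genes than expected
#' given the category size and the gene-length distribution: the
#' over-represented p-value is the upper tail `P(X >= numDEInCat)` under
#' the Wallenius noncentral hypergeometric distribution with odds equal to
#' the mean probability weight inside the category divided by the mean
#' weight outside. With uniform weights this is exactly the hypergeometric
#' tail. Up- and downregulated gene sets are intended to be tested in
#' separate calls (pass `direction` for bookkeeping).
#'
#' @param de_flags named logical vector over the gene universe.
#' @param categories named list: term id -> character vector of gene ids
#'   (genes outside the universe are ignored; empty categories skipped).
#' @param weights gene weights from [fit_pwf()] (named as `de_flags`);
#'   NULL means uniform weights.
#' @param direction label stored in the result (`"up"` or `"down"`).
#' @param term_names optional named character vector of term descriptions.
#' @return data.frame with `term_id`, `term_name`, `direction`,
#'   `over_represented_p`, `numDEInCat`, `numInCat`, sorted by p.
#' @export
go_test <- function(de_flags, categories, weights = NULL,
                    direction = "up", term_names = NULL) {
  if (!length(categories)) stop("categories must be nonempty", call. = FALSE)
  genes <- names(de_flags)
  if (is.null(weights)) weights <- setNames(rep(1, length(genes)), genes)
  n_de <- sum(de_flags)
  rows <- lapply(names(categories), function(tid) {
    cat_genes <- intersect(categories[[tid]], genes)
    m1 <- length(cat_genes)
    if (m1 == 0L) return(NULL)
    k <- sum(de_flags[cat_genes])
    inside <- genes %in% cat_genes
    odds <- if (all(inside) || !any(inside)) 1 else
      mean(weights[inside]) / mean(weights[!inside])
    p <- wallenius_upper_tail(k, m1, length(genes) - m1, n_de, odds)
    data.frame(term_id = tid,
               term_name = if (!is.null(term_names)) term_names[[tid]] %||% tid else tid,
               direction = direction,
               over_represented_p = p,
               numDEInCat = as.integer(k), numInCat = as.integer(m1))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(NULL))
  out <- out[order(out$over_represented_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-bias-aware GO enrichment for a DE contrast
#'
#' Convenience wrapper reproducing the full enrichment path for one DE
#' table: genes with `p_adjusted < de_alpha` are the DE set, split by sign
#' of `avg_log2FC` into up- and downregulated sets, each tested against the
#' tested-gene universe with a freshly fitted length weight function.
#'
#' @param de a `de_result`.
#' @param categories named list of term gene sets.
#' @param gene_lengths named numeric vector of gene lengths.
#' @param de_alpha adjusted-p cutoff defining the DE set.
#' @param term_names optional named term descriptions.
#' @return combined data.frame as from [go_test()] for both directions.
#' @export
go_enrichment <- function(de, categories, gene_lengths, de_alpha = 0.01,
                          term_names = NULL) {
  universe <- de$gene_id
  sig <- de$p_adjusted < de_alpha
  out <- lapply(c(up = 1, down = -1), function(sgn) {
    flags <- setNames(sig & sign(de$avg_log2FC) == sgn, universe)
    if (!any(flags)) return(NULL)
    w <- tryCatch(suppressWarnings(fit_pwf(flags, gene_lengths)),
                  error = function(cond) NULL)
    go_test(flags, categories, weights = w,
            direction = if (sgn > 0) "up" else "down",
            term_names = term_names)
  })
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}
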