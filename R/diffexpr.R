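#' Two-sided Wilcoxon rank-sum p-value
#'
#' Rank-sum test of `x` versus `y`. When both groups have at most
#' `exact_max` observations the two-sided p-value is computed by exact
#' enumeration of all group assignments of the observed (possibly tied)
#' ranks: `p = min(1, 2 * min(P(W <= w), P(W >= w)))`. Otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max largest group size for which exact enumeration is used.
#' @return two-sided p-value.
#' @export
wilcoxon_test <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- combn(n, n1, function(i) sum(r[i]))
    eps <- 1e-9
    p_lo <- mean(sums <= w + eps)
    p_hi <- mean(sums >= w - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Differential expression between two cell groups
#'
#' Tests each gene for differential expression between `cells_in` and
#' `cells_out` on log-normalized data. Genes expressed (value > 0) in fewer
#' than `min_pct` of cells in both groups are skipped. `method =
#' "wilcoxon"` uses the rank-sum test ([wilcoxon_test()]); `method =
#' "logistic_lr"` uses a likelihood-ratio test of a logistic regression of
#' group membership on expression. The fold change is
#' `avg_log2FC = log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`,
#' i.e. computed on depth-normalized (de-logged) expression with a
#' pseudocount of 1. P-values are adjusted over the tested genes.
#'
#' @param nm a `normalized_matrix`.
#' @param cells_in,cells_out disjoint cell index or barcode vectors, each
#'   with at least 3 cells.
#' @param min_pct minimum expressed fraction in at least one group.
#' @param method `"wilcoxon"` or `"logistic_lr"`.
#' @param p_adjust_method `"bonferroni"` (default) or any
#'   [stats::p.adjust()] method.
#' @param contrast optional contrast descriptor stored on the result.
#' @return data.frame (class `de_result`) with columns `gene_id`, `symbol`,
#'   `avg_log2FC`, `p_value`, `p_adjusted`, `pct_in`, `pct_out`.
#' @export
de_test <- function(nm, cells_in, cells_out, min_pct = 0.05,
                    method = c("wilcoxon", "logistic_lr"),
                    p_adjust_method = "bonferroni", contrast = NULL) {
  method <- match.arg(method)
  bc <- nm$cell_meta$barcode
  if (is.character(cells_in)) cells_in <- match(cells_in, bc)
  if (is.character(cells_out)) cells_out <- match(cells_out, bc)
  if (length(intersect(cells_in, cells_out)))
    stop("cells_in and cells_out must be disjoint", call. = FALSE)
  if (length(cells_in) < 3 || length(cells_out) < 3)
    stop("each group needs at least 3 cells", call. = FALSE)
  xin <- as.matrix(nm$values[, cells_in, drop = FALSE])
  xout <- as.matrix(nm$values[, cells_out, drop = FALSE])
  pct_in <- rowMeans(xin > 0)
  pct_out <- rowMeans(xout > 0)
  test_idx <- which(pct_in >= min_pct | pct_out >= min_pct)
  if (!length(test_idx)) {
    warning("all genes filtered by min_pct", call. = FALSE)
    return(empty_de_result(contrast))
  }
  lfc <- log2((rowMeans(expm1(xin[test_idx, , drop = FALSE])) + 1) /
              (rowMeans(expm1(xout[test_idx, , drop = FALSE])) + 1))
  grp <- c(rep(1L, length(cells_in)), rep(0L, length(cells_out)))
  p <- vapply(test_idx, function(i) {
    if (method == "wilcoxon") wilcoxon_test(xin[i, ], xout[i, ])
    else logistic_lr_test(c(xin[i, ], xout[i, ]), grp)
  }, numeric(1))
  res <- data.frame(gene_id = nm$genes$gene_id[test_idx],
                    symbol = nm$genes$symbol[test_idx],
                    avg_log2FC = lfc,
                    p_value = p,
                    p_adjusted = p.adjust(p, method = p_adjust_method),
                    pct_in = pct_in[test_idx],
                    pct_out = pct_out[test_idx])
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

empty_de_result <- function(contrast = NULL) {
  res <- data.frame(gene_id = character(0), symbol = character(0),
                    avg_log2FC = numeric(0), p_value = numeric(0),
                    p_adjusted = numeric(0), pct_in = numeric(0),
                    pct_out = numeric(0))
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

# likelihood-ratio test: group ~ expression vs group ~ 1 (binomial)
logistic_lr_test <- function(expr, grp) {
  fit1 <- suppressWarnings(glm(grp ~ expr, family = binomial()))
  fit0 <- suppressWarnings(glm(grp ~ 1, family = binomial()))
  dev <- fit0$deviance - fit1$deviance
  pchisq(max(dev, 0), df = 1, lower.tail = FALSE)
}

#' Rank significant DE genes by absolute fold change
#'
#' Keeps genes with `p_adjusted < alpha` (strict) and orders them by
#' decreasing `|avg_log2FC|`, ties broken by gene id.
#'
#' @param results a `de_result`.
#' @param alpha adjusted-p significance cutoff.
#' @return the filtered, ranked `de_result`.
#' @export
rank_de <- function(results, alpha = 1e-5) {
  keep <- results$p_adjusted < alpha
  out <- results[keep, , drop = FALSE]
  out <- out[order(-abs(out$avg_log2FC), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-vs-rest DE for every cluster
#'
#' @param nm a `normalized_matrix`.
#' @param assign a `cluster_assignment` covering `nm`'s cells.
#' @param exclude_clusters cluster labels to drop entirely (e.g. flagged
#'   contaminant clusters).
#' @param ... passed to [de_test()].
#' @return named list of `de_result`, one per cluster.
#' @export
cluster_markers <- function(nm, assign, exclude_clusters = integer(0), ...) {
  labels <- assign$labels[nm$cell_meta$barcode]
  use <- !(labels %in% exclude_clusters)
  ks <- sort(unique(labels[use]))
  out <- lapply(ks, function(k) {
    de_test(nm, which(use & labels == k), which(use & labels != k),
            contrast = list(cluster = k, group_in = "cluster",
                            group_out = "rest"), ...)
  })
  setNames(out, as.character(ks))
}

#' Post- versus pre-transplant DE within a cluster
#'
#' Compares cells of one cluster between timepoints for a given stimulus:
#' `cells_in` = post-transplant cells, `cells_out` = pre-transplant cells
#' (so a gene lower after transplantation has negative `avg_log2FC`). The
#' third-party control contrast is the same call with
#' `stimulus = "thirdP"`.
#'
#' @param nm a `normalized_matrix`.
#' @param assign a `cluster_assignment`.
#' @param cluster_id cluster label to restrict to.
#' @param stimulus `"don"` or `"thirdP"`.
#' @param ... passed to [de_test()].
#' @return a `de_result`, or NULL (with a warning) when a timepoint is
#'   missing or a group has fewer than 3 cells.
#' @export
prepost_contrast <- function(nm, assign, cluster_id, stimulus = "don", ...) {
  meta <- nm$cell_meta
  labels <- assign$labels[meta$barcode]
  in_cl <- labels == cluster_id & meta$stimulus == stimulus
  post <- which(in_cl & meta$timepoint == "post")
  pre <- which(in_cl & meta$timepoint == "pre")
  if (length(post) < 3 || length(pre) < 3) {
    warning("cluster ", cluster_id, " (", stimulus,
            "): a timepoint is missing or too small; contrast skipped",
            call. = FALSE)
    return(NULL)
  }
  de_test(nm, post, pre,
          contrast = list(cluster = cluster_id, group_in = "post",
                          group_out = "pre", stimulus = stimulus), ...)
}
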