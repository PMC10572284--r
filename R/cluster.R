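#' Build a shared-nearest-neighbor graph on a PCA embedding
#'
#' Finds each cell's `k` Euclidean nearest neighbors (self excluded, ties
#' broken by barcode order), connects every pair in which at least one cell
#' neighbors the other, and weights the edge by the Jaccard overlap of the
#' two neighbor sets. Zero-weight edges are dropped; the graph has no
#' self-loops.
#'
#' @param emb a `pca_embedding` (or a plain cells x dims matrix with
#'   rownames).
#' @param k number of neighbors; must be < number of cells.
#' @return object of class `neighbor_graph`: list with `graph` (weighted
#'   undirected [igraph::igraph] whose vertices are barcodes, sorted), `k`,
#'   `neighbors` (list of neighbor index sets).
#' @export
build_knn_graph <- function(emb, k = 20) {
  coords <- if (inherits(emb, "pca_embedding")) emb$coordinates else emb
  n <- nrow(coords)
  if (k >= n) stop("k = ", k, " must be smaller than the number of cells (",
                   n, ")", call. = FALSE)
  # vertex order independent of input order: sort by barcode
  ord <- order(rownames(coords))
  coords <- coords[ord, , drop = FALSE]
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
  # candidate edges: union of directed kNN relations
  ii <- rep(seq_len(n), each = k)
  jj <- unlist(nb)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  key <- unique(a * (n + 1) + b)
  a <- key %/% (n + 1); b <- key %% (n + 1)
  w <- vapply(seq_along(a), function(e) {
    s1 <- nb[[a[e]]]; s2 <- nb[[b[e]]]
    length(intersect(s1, s2)) / length(union(s1, s2))
  }, numeric(1))
  keep <- w > 0
  edges <- cbind(a[keep], b[keep])
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(coords)[edges[, 1]],
               to = rownames(coords)[edges[, 2]],
               weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = rownames(coords)))
  structure(list(graph = g, k = k,
                 neighbors = setNames(nb, rownames(coords))),
            class = "neighbor_graph")
}

#' Cluster cells by modularity optimization
#'
#' Runs Louvain multilevel modularity optimization with a resolution
#' parameter on the SNN graph. Vertices are visited in a seed-shuffled
#' barcode-sorted order, so results are reproducible for a given seed and
#' independent of the input cell order. Cluster labels are re-indexed
#' 0..K-1 by decreasing cluster size (label 0 = largest cluster).
#'
#' @param g a `neighbor_graph`.
#' @param resolution resolution parameter gamma of the modularity quality
#'   function.
#' @param seed integer seed controlling the (shuffled) vertex visit order.
#' @return object of class `cluster_assignment`: list with `labels` (named
#'   integer vector, 0-based, names = barcodes), `k` (number of clusters),
#'   `modularity`, `resolution`.
#' @export
cluster_cells <- function(g, resolution = 0.4, seed = 1L) {
  gr <- g$graph
  if (igraph::vcount(gr) == 0) stop("empty graph", call. = FALSE)
  set.seed(derive_seed(seed, 13L))
  perm <- sample(igraph::vcount(gr))
  gp <- igraph::permute(gr, perm)
  cl <- igraph::cluster_louvain(gp, resolution = resolution)
  memb <- igraph::membership(cl)
  labels <- setNames(as.integer(memb[match(igraph::V(gr)$name,
                                           names(memb))]),
                     igraph::V(gr)$name)
  labels <- relabel_by_size(labels)
  structure(list(labels = labels, k = length(unique(labels)),
                 modularity = max(cl$modularity),
                 resolution = resolution),
            class = "cluster_assignment")
}

# relabel clusters 0..K-1 by decreasing size; ties by old label
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- setNames(seq_along(tab) - 1L, names(tab))
  setNames(as.integer(map[as.character(labels)]), names(labels))
}

#' Annotate clusters by marker expression and flag contaminants
#'
#' Each annotation in `marker_map` is a character vector of gene symbols;
#' a cluster receives the annotation whose markers have the largest
#' mean-expression margin (mean in cluster minus mean outside), provided
#' the margin is positive. Entries listed in `contaminant` name non-T-cell
#' markers (e.g. CD14, CD19, NCAM1): a cluster is flagged for exclusion
#' when one of these genes is significantly upregulated in one-vs-rest
#' differential expression (adjusted p < `contaminant_alpha` and
#' log2FC > `contaminant_lfc`).
#'
#' @param assign a `cluster_assignment`.
#' @param nm a `normalized_matrix` (same cells).
#' @param marker_map named list of marker gene-symbol vectors.
#' @param contaminant character vector of contaminant gene symbols.
#' @param contaminant_alpha,contaminant_lfc exclusion thresholds.
#' @return data.frame with columns `cluster`, `annotation`, `excluded`.
#' @export
label_clusters <- function(assign, nm, marker_map = list(),
                           contaminant = character(0),
                           contaminant_alpha = 0.01, contaminant_lfc = 1) {
  labels <- assign$labels[nm$cell_meta$barcode]
  ks <- sort(unique(labels))
  ann <- rep(NA_character_, length(ks))
  excl <- rep(FALSE, length(ks))
  sym <- nm$genes$symbol
  vals <- nm$values
  if (length(marker_map)) {
    missing <- names(marker_map)[vapply(marker_map, function(gs)
      !any(sym %in% gs), logical(1))]
    if (length(missing))
      warning("marker genes absent from matrix for: ",
              paste(missing, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(ks)) {
    in_k <- labels == ks[i]
    if (length(marker_map)) {
      margins <- vapply(marker_map, function(gs) {
        idx <- which(sym %in% gs)
        if (!length(idx)) return(NA_real_)
        sum(vals[idx, in_k, drop = FALSE]) / (length(idx) * sum(in_k)) -
          sum(vals[idx, !in_k, drop = FALSE]) / (length(idx) * sum(!in_k))
      }, numeric(1))
      if (any(!is.na(margins)) && max(margins, na.rm = TRUE) > 0)
        ann[i] <- names(which.max(margins))
    }
    if (length(contaminant) && sum(in_k) >= 3 && sum(!in_k) >= 3) {
      de <- de_test(nm, which(in_k), which(!in_k))
      hit <- de[de$gene_id %in% nm$genes$gene_id[sym %in% contaminant], ]
      if (nrow(hit) && any(hit$p_adjusted < contaminant_alpha &
                           hit$avg_log2FC > contaminant_lfc))
        excl[i] <- TRUE
    }
  }
  data.frame(cluster = ks, annotation = ann, excluded = excl)
}
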