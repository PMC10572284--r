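#' Pipeline configuration with study defaults
#'
#' All stage parameters in one list, defaulting to the study's published
#' values: QC at <500 / >5000 expressed genes and >5% mitochondrial signal,
#' scale factor 10,000, 2000 highly variable genes, 16 principal
#' components, clustering resolution 0.4, DE ranking at adjusted p < 1e-5,
#' GO DE-set cutoffs 0.01 (cluster markers) and 0.1 (pre/post), and the
#' TCR cascade thresholds (25 reads, top > 0.8, flocus > 0.1).
#'
#' @param ... overrides for any default field.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_genes = 500, max_genes = 5000, max_pct_mito = 5,
    mito_prefix = "MT-",
    scale_factor = 10000,
    n_hvg = 2000, hvg_method = "vst", protein_coding_only = TRUE,
    n_dims = 16, center_by_chip = FALSE,
    knn_k = 20, resolution = 0.4,
    de_method = "wilcoxon", p_adjust_method = "bonferroni",
    min_pct = 0.05, de_alpha = 1e-5,
    go_alpha_cluster = 0.01, go_alpha_prepost = 0.1,
    min_reads = 25, top_threshold = 0.8, flocus_threshold = 0.1,
    marker_map = list(), contaminant_markers = character(0),
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Save / load a pipeline configuration
#'
#' JSON by default; YAML when the path ends in `.yaml`/`.yml` (requires the
#' yaml package). `load_config(save_config(cfg, path))` restores an
#' identical configuration.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `save_config`: the path, invisibly; `load_config`: the config.
#' @export
save_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::write_yaml(unclass(cfg), path)
  } else {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw$marker_map <- lapply(as.list(raw$marker_map), as.character)
  raw$contaminant_markers <- as.character(unlist(raw$contaminant_markers))
  do.call(pipeline_config, raw)
}

#' Simulate a full multi-sample study (counts + repertoire)
#'
#' Generates a pre/post x donor/third-party study layout over `n_patients`
#' patients: donor-stimulated samples at both timepoints for every patient
#' and third-party-stimulated samples for the first
#' `n_thirdparty_patients`, each on its own chip, with matched TRA/TRB
#' chain records for every cell.
#'
#' @param cfg a [synth_config()].
#' @param n_patients patients with paired donor-stimulated samples.
#' @param n_thirdparty_patients patients (from the start of the list) that
#'   also have paired third-party samples.
#' @param condition_effect optional timepoint effect, see
#'   [simulate_counts()].
#' @return list with `counts` ([count_matrix]), `chains` (chain
#'   data.frame with `sample_id`), `truth` (count truth plus `repertoire`,
#'   a per-sample list of repertoire truths).
#' @export
simulate_study <- function(cfg, n_patients = 3, n_thirdparty_patients = 2,
                           condition_effect = NULL) {
  pats <- sprintf("P%d", seq_len(n_patients) - 1L)
  rows <- list()
  for (p in seq_along(pats)) {
    stims <- if (p <= n_thirdparty_patients) c("don", "thirdP") else "don"
    for (st in stims) for (tp in c("pre", "post"))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_%s", pats[p], tp, st),
        patient = pats[p], timepoint = tp, stimulus = st,
        chip = sprintf("chip_%s_%s_%s", pats[p], tp, st))
  }
  samples <- do.call(rbind, rows)
  sim <- simulate_counts(cfg, samples, condition_effect = condition_effect)
  chains <- list()
  rep_truth <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]
    cells <- sim$counts$cell_meta$barcode[sim$counts$cell_meta$sample_id == s]
    r <- simulate_repertoire(cfg, cells,
                             rng_seed = derive_seed(cfg$rng_seed, 500L + i))
    r$chains$sample_id <- s
    chains[[i]] <- r$chains
    rep_truth[[s]] <- r$truth
  }
  sim$truth$repertoire <- rep_truth
  list(counts = sim$counts, chains = do.call(rbind, chains),
       truth = sim$truth)
}

#' Run the full analysis pipeline
#'
#' Orchestrates QC, normalization, HVG selection, PCA, SNN-graph
#' clustering, contaminant-cluster exclusion, one-vs-rest cluster markers,
#' pre/post contrasts (donor and third-party), optional length-bias-aware
#' GO enrichment, the TCR filter cascade, paired clonotypes, and Shannon
#' diversity. Stage errors propagate with the stage name attached.
#'
#' @param counts a [count_matrix] (or a directory path for
#'   [read_counts()]).
#' @param chains chain data.frame with a `sample_id` column (or a TSV path
#'   for [read_chains()]), or NULL to skip the repertoire stages.
#' @param config a [pipeline_config()].
#' @param gene_sets optional named list of term gene sets (or GMT/TSV path)
#'   enabling the GO stage.
#' @param out_dir optional directory; when given, all tables and a JSON
#'   report are written there.
#' @return list of class `run_report`: `config`, `qc`, `counts_stage`
#'   (cells/genes before and after each filter), `clusters` (labels,
#'   annotation), `markers` (per-cluster ranked DE), `prepost` (per
#'   cluster x stimulus DE), `go` (per contrast), `tcr` (trace summary,
#'   clonotypes, diversity, vdj, overlap).
#' @export
run_pipeline <- function(counts, chains = NULL, config = pipeline_config(),
                         gene_sets = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(counts)) counts <- stage("read_counts", read_counts(counts))
  if (is.character(chains)) chains <- stage("read_chains", read_chains(chains))

  qc <- stage("qc", compute_qc_metrics(counts, config$mito_prefix))
  filtered <- stage("qc", filter_cells(counts, qc, config$min_genes,
                                       config$max_genes, config$max_pct_mito))
  nm <- stage("normalize", normalize_counts(filtered, config$scale_factor))
  hvg <- stage("hvg", select_hvg(nm, counts = filtered, n_top = config$n_hvg,
                                 protein_coding_only = config$protein_coding_only,
                                 method = config$hvg_method))
  n_dims <- min(config$n_dims, length(hvg), ncol(nm$values) - 1L)
  emb <- stage("pca", run_pca(nm, hvg, n_dims = n_dims,
                              center_by_chip = config$center_by_chip))
  k <- min(config$knn_k, ncol(nm$values) - 1L)
  graph <- stage("knn", build_knn_graph(emb, k = k))
  assign <- stage("cluster", cluster_cells(graph, config$resolution,
                                           seed = config$seed))
  labels <- stage("annotate",
                  label_clusters(assign, nm, config$marker_map,
                                 config$contaminant_markers))
  excluded <- labels$cluster[labels$excluded]

  markers <- stage("markers",
                   cluster_markers(nm, assign, exclude_clusters = excluded,
                                   min_pct = config$min_pct,
                                   method = config$de_method,
                                   p_adjust_method = config$p_adjust_method))
  ranked <- lapply(markers, rank_de, alpha = config$de_alpha)

  prepost <- list()
  for (k_id in setdiff(sort(unique(assign$labels)), excluded))
    for (st in intersect(c("don", "thirdP"), unique(nm$cell_meta$stimulus))) {
      de <- withCallingHandlers(
        prepost_contrast(nm, assign, k_id, st, min_pct = config$min_pct,
                         method = config$de_method,
                         p_adjust_method = config$p_adjust_method),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(de)) prepost[[sprintf("cluster%s_%s", k_id, st)]] <- de
    }

  go <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
    lengths <- setNames(counts$genes$length_bp, counts$genes$gene_id)
    tn <- attr(gene_sets, "term_names")
    go <- list()
    for (nm_k in names(markers))
      go[[paste0("cluster", nm_k)]] <- stage("go",
        go_enrichment(markers[[nm_k]], gene_sets, lengths,
                      de_alpha = config$go_alpha_cluster, term_names = tn))
    for (nm_c in names(prepost))
      go[[nm_c]] <- stage("go",
        go_enrichment(prepost[[nm_c]], gene_sets, lengths,
                      de_alpha = config$go_alpha_prepost, term_names = tn))
  }

  tcr <- NULL
  if (!is.null(chains)) {
    fc <- stage("tcr_filter",
                filter_chains(chains, config$min_reads,
                              config$top_threshold, config$flocus_threshold))
    ct <- stage("clonotypes", build_clonotypes(fc$chains))
    clono <- ct$clonotypes
    cell_sample <- setNames(as.character(chains$sample_id), chains$cell_id)
    clono$sample_id <- unname(cell_sample[clono$cell_id])
    div <- stage("diversity", diversity_table(clono))
    vdj <- stage("vdj", suppressWarnings(
      vdj_table(fc$chains, sample_ids = cell_sample[fc$chains$cell_id])))
    ov <- if (length(unique(clono$sample_id)) >= 2)
      clonotype_overlap(clono) else NULL
    tcr <- list(trace = fc$trace, clonotypes = clono, trd = ct$trd,
                diversity = div, vdj = vdj, overlap = ov,
                n_chains_in = nrow(chains),
                n_chains_retained = nrow(fc$chains))
  }

  report <- structure(list(
    config = config,
    qc = qc,
    counts_stage = list(cells_in = ncol(counts$counts),
                        cells_retained = ncol(filtered$counts),
                        cells_removed = ncol(counts$counts) -
                          ncol(filtered$counts),
                        genes = nrow(counts$counts),
                        n_hvg = length(hvg), n_dims = n_dims),
    clusters = list(labels = assign$labels, k = assign$k,
                    modularity = assign$modularity,
                    annotation = labels, excluded = excluded),
    markers = ranked, markers_full = markers,
    prepost = prepost, go = go, tcr = tcr),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write all pipeline tables and a JSON summary
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(report$qc, "qc_metrics.tsv")
  cl <- data.frame(barcode = names(report$clusters$labels),
                   cluster = unname(report$clusters$labels))
  wt(cl, "clusters.tsv")
  for (k in names(report$markers))
    wt(report$markers[[k]], sprintf("markers_cluster%s.tsv", k))
  for (nm in names(report$prepost))
    wt(report$prepost[[nm]], sprintf("prepost_%s.tsv", nm))
  for (nm in names(report$go %||% list()))
    if (!is.null(report$go[[nm]])) wt(report$go[[nm]],
                                      sprintf("go_%s.tsv", nm))
  if (!is.null(report$tcr)) {
    wt(report$tcr$trace, "tcr_filter_trace.tsv")
    wt(report$tcr$clonotypes, "clonotypes.tsv")
    wt(report$tcr$diversity, "diversity.tsv")
    wt(report$tcr$vdj, "vdj_usage.tsv")
  }
  summary <- list(
    counts_stage = report$counts_stage,
    n_clusters = report$clusters$k,
    modularity = report$clusters$modularity,
    excluded_clusters = report$clusters$excluded,
    n_significant_markers = vapply(report$markers, nrow, integer(1)),
    tcr = if (!is.null(report$tcr))
      list(n_chains_in = report$tcr$n_chains_in,
           n_chains_retained = report$tcr$n_chains_retained,
           diversity = report$tcr$diversity)
    else NULL,
    config = unclass(report$config))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cs <- x$counts_stage
  cat("run_report:", cs$cells_retained, "/", cs$cells_in,
      "cells retained after QC;", x$clusters$k, "clusters\n")
  if (!is.null(x$tcr))
    cat("  TCR:", x$tcr$n_chains_retained, "/", x$tcr$n_chains_in,
        "chains retained;", nrow(x$tcr$clonotypes), "cells with clonotypes\n")
  invisible(x)
}
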