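test_that("rank-sum p matches brute-force enumeration for small groups", {
  set.seed(11)
  cases <- list()
  for (n1 in c(3, 5, 8)) for (n2 in c(3, 6, 8)) {
    cases[[length(cases) + 1]] <- list(x = rnorm(n1), y = rnorm(n2))
    # tied data exercise the midrank path
    cases[[length(cases) + 1]] <- list(x = rpois(n1, 2), y = rpois(n2, 2))
  }
  for (cs in cases) {
    expect_equal(wilcoxon_test(cs$x, cs$y),
                 oracle_rank_sum_p(cs$x, cs$y), tolerance = 1e-12)
  }
  # tie-free cases also agree with the distribution-based exact test
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(wilcoxon_test(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("worked example: complete separation of two groups of 5", {
  nm <- normalize_counts(make_cm(
    rbind(c(rep(100, 5), rep(0, 5)), rep(5, 10),
          c(rep(0, 5), rep(100, 5)))))   # keeps cell totals equal
  de <- de_test(nm, 1:5, 6:10)
  g1 <- de[de$gene_id == "G001", ]
  # in-group normalized value ln(101), out-group 0 (single-gene depth aside)
  expect_equal(g1$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(g1$pct_in, 1)
  expect_equal(g1$pct_out, 0)
  # identical distributions: p ~ 1 under exact enumeration
  g2 <- de[de$gene_id == "G002", ]
  expect_gte(g2$p_value, 0.9)
})

test_that("fold change follows the expm1 pseudocount formula and is antisymmetric", {
  mat <- rbind(c(rep(4, 5), rep(1, 6)), matrix(rpois(33, 6) + 1, 3))
  cm <- make_cm(mat)
  nm <- normalize_counts(cm)
  # direct formula evaluation on gene 1
  xin <- expm1(as.matrix(nm$values)[1, 1:5])
  xout <- expm1(as.matrix(nm$values)[1, 6:11])
  de <- de_test(nm, 1:5, 6:11)
  expect_equal(de$avg_log2FC[de$gene_id == "G001"],
               log2((mean(xin) + 1) / (mean(xout) + 1)))
  rev <- de_test(nm, 6:11, 1:5)
  m <- merge(de, rev, by = "gene_id")
  expect_equal(m$avg_log2FC.x, -m$avg_log2FC.y, tolerance = 1e-12)
})

test_that("pure separation yields log2(101) fold change", {
  # one gene expressed at ln(101) in-group and 0 out-group
  vals <- Matrix::Matrix(rbind(c(rep(log(101), 5), rep(0, 5)),
                               rep(1, 10)), sparse = TRUE)
  nm <- structure(list(values = vals, scale_factor = 10000,
                       genes = data.frame(gene_id = c("G001", "G002"),
                                          symbol = c("A", "B")),
                       cell_meta = data.frame(barcode = sprintf("c%02d", 1:10))),
                  class = "normalized_matrix")
  de <- de_test(nm, 1:5, 6:10)
  expect_equal(de$avg_log2FC[de$gene_id == "G001"], log2(101),
               tolerance = 1e-12)
  expect_equal(log2(101), 6.658, tolerance = 1e-3)
})

test_that("min_pct filtering, group-size guards and empty results", {
  mat <- rbind(rep(0:1, 30), c(1, rep(0, 59)), rpois(60, 5) + 1)
  nm <- normalize_counts(make_cm(mat))
  de <- de_test(nm, 1:30, 31:60, min_pct = 0.05)
  expect_false("G002" %in% de$gene_id)   # expressed in 1/30 of one group only
  expect_true(all(c("G001", "G003") %in% de$gene_id))
  expect_error(de_test(nm, 1:2, 3:30), "at least 3")
  expect_error(de_test(nm, 1:5, 4:10), "disjoint")
  expect_warning(de_empty <- de_test(nm, 1:30, 31:60, min_pct = 1.1),
                 "min_pct")
  expect_equal(nrow(de_empty), 0)
})

test_that("adjusted p is never below raw p and methods are selectable", {
  cfg <- synth_config(n_cells_per_sample = 60, n_genes = 150, rng_seed = 2)
  sim <- simulate_counts(cfg)
  nm <- normalize_counts(sim$counts)
  de_b <- de_test(nm, 1:30, 31:60)
  expect_true(all(de_b$p_adjusted >= de_b$p_value - 1e-15))
  de_bh <- de_test(nm, 1:30, 31:60, p_adjust_method = "BH")
  expect_true(all(de_bh$p_adjusted <= de_b$p_adjusted + 1e-15))
  de_lr <- de_test(nm, 1:30, 31:60, method = "logistic_lr")
  expect_true(all(de_lr$p_value >= 0 & de_lr$p_value <= 1))
})

test_that("rank_de filters strictly at alpha and orders by |log2FC|", {
  de <- empty <- data.frame(gene_id = character(0), avg_log2FC = numeric(0),
                            p_adjusted = numeric(0))
  expect_equal(nrow(rank_de(empty)), 0)
  de <- data.frame(gene_id = c("a", "b", "c"),
                   avg_log2FC = c(1.5, -2.0, 0.3),
                   p_adjusted = c(1e-6, 1e-6, 1e-5))
  r <- rank_de(de, alpha = 1e-5)
  expect_equal(r$gene_id, c("b", "a"))   # -2.0 outranks +1.5; c at alpha drops
})

test_that("planted cluster markers are recovered", {
  recovered <- total <- 0
  for (seed in 1:3) {
    cfg <- synth_config(n_cells_per_sample = 150, n_genes = 400,
                        n_clusters = 2, marker_genes_per_cluster = 10,
                        marker_log2fc = 2, doublet_rate = 0,
                        dead_cell_rate = 0, rng_seed = seed)
    sim <- simulate_counts(cfg)
    nm <- normalize_counts(sim$counts)
    cl <- sim$truth$clusters[nm$cell_meta$barcode]
    de <- de_test(nm, which(cl == 1), which(cl == 2))
    mk <- sim$truth$markers$gene_id[sim$truth$markers$cluster == 1]
    hit <- de$gene_id[de$p_adjusted < 0.01 & de$avg_log2FC > 0]
    recovered <- recovered + sum(mk %in% hit)
    total <- total + length(mk)
  }
  expect_gte(recovered / total, 0.9)
})

test_that("pre/post contrast recovers a planted down-shift, donor-only", {
  cfg <- synth_config(n_cells_per_sample = 120, n_genes = 300,
                      n_clusters = 2, doublet_rate = 0, dead_cell_rate = 0,
                      rng_seed = 31)
  study <- simulate_study(cfg, n_patients = 2, n_thirdparty_patients = 2,
                          condition_effect = list(cluster = 1, n_genes = 5,
                                                  log2fc = -1))
  nm <- normalize_counts(study$counts)
  truth_cl <- study$truth$clusters[nm$cell_meta$barcode]
  assign <- structure(list(labels = setNames(as.integer(truth_cl - 1),
                                             nm$cell_meta$barcode)),
                      class = "cluster_assignment")
  de_don <- prepost_contrast(nm, assign, cluster_id = 0, stimulus = "don",
                             p_adjust_method = "BH")
  planted <- study$truth$condition_effect$gene_id
  hits <- de_don[de_don$gene_id %in% planted, ]
  expect_true(all(hits$avg_log2FC < 0))
  top <- de_don$gene_id[order(de_don$p_adjusted)][1:5]
  expect_gte(sum(planted %in% top), 4)
  # third-party control shows no overlapping hits
  de_tp <- prepost_contrast(nm, assign, cluster_id = 0, stimulus = "thirdP",
                            p_adjust_method = "BH")
  tp_hits <- de_tp$gene_id[de_tp$p_adjusted < 0.05]
  expect_length(intersect(tp_hits, planted), 0)
  # missing timepoint warns and returns NULL
  sub <- nm$cell_meta$timepoint == "pre"
  nm_pre <- structure(list(values = nm$values[, sub],
                           genes = nm$genes,
                           cell_meta = nm$cell_meta[sub, ]),
                      class = "normalized_matrix")
  expect_warning(res <- prepost_contrast(nm_pre, assign, 0, "don"),
                 "skipped")
  expect_null(res)
})

test_that("type-I error is calibrated under the null", {
  frac <- vapply(1:10, function(seed) {
    set.seed(seed)
    mat <- matrix(rnbinom(2000 * 60, mu = 2, size = 2.5), nrow = 2000)
    cm <- make_cm(mat)
    nm <- normalize_counts(cm)
    de <- de_test(nm, 1:30, 31:60, min_pct = 0.05)
    mean(de$p_value < 0.05)
  }, numeric(1))
  expect_gte(mean(frac), 0.03)
  expect_lte(mean(frac), 0.07)
})
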