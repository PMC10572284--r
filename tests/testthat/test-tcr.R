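test_that("productivity and read-count rules sit on the stated boundaries", {
  good <- "TGTGCAAGCAGC"          # in frame, no stop
  stopped <- "TGTTAAAGCAGC"       # internal TAA
  frameshift <- "TGTGCAAGCAG"     # length 11
  chains <- rbind(
    chain("c1", "TRA", 24, good),              # reads below minimum
    chain("c2", "TRA", 25, good),              # at the minimum: retained
    chain("c3", "TRA", 100, stopped),          # premature stop
    chain("c4", "TRA", 100, frameshift),       # out of frame
    chain("c5", "TRA", 100, stopped, productive = TRUE),  # flag wins
    chain("c6", "TRA", 100, good, productive = FALSE))
  chains$productive <- c(NA, NA, NA, NA, TRUE, FALSE)
  fc <- filter_chains(chains)
  expect_setequal(fc$chains$cell_id, c("c2", "c5"))
  tr <- fc$trace
  expect_equal(tr$fail_reason[tr$cell_id == "c1"], "min_reads")
  expect_equal(tr$fail_reason[tr$cell_id == "c3"], "unproductive")
  expect_equal(tr$fail_reason[tr$cell_id == "c4"], "unproductive")
  expect_equal(tr$fail_reason[tr$cell_id == "c6"], "unproductive")
})

test_that("primary-chain selection applies the top > 0.8 rule", {
  good <- "TGTGCAAGCAGC"
  alt <- "TGTGCAAGCTGC"
  single <- chain("c1", "TRB", 60, good)
  fc1 <- filter_chains(single)
  expect_equal(fc1$chains$top, 1.0)
  # reads {30, 5}: top = 30/35 > 0.8, retained
  two_ok <- rbind(chain("c2", "TRB", 30, good), chain("c2", "TRB", 5, alt))
  fc2 <- filter_chains(two_ok, min_reads = 1)
  expect_equal(nrow(fc2$chains), 1)
  expect_equal(fc2$chains$junction, good)
  expect_equal(fc2$chains$top, 30 / 35)
  # reads {30, 10}: top = 0.75, the (cell, locus) is removed
  two_bad <- rbind(chain("c3", "TRB", 30, good), chain("c3", "TRB", 10, alt))
  fc3 <- filter_chains(two_bad, min_reads = 1)
  expect_equal(nrow(fc3$chains), 0)
  expect_equal(fc3$trace$fail_reason[1], "top")
  # read ties break lexicographically by junction
  tie <- rbind(chain("c4", "TRB", 50, alt), chain("c4", "TRB", 50, good))
  fc4 <- filter_chains(tie, min_reads = 1, top_threshold = 0.4)
  expect_equal(fc4$chains$junction, good)  # "TGTGCAAGCAGC" < "TGTGCAAGCTGC"
})

test_that("locus fraction rule uses strict > 0.1 on cell totals", {
  good <- "TGTGCAAGCAGC"
  # TRA 12 vs TRB 100: flocus(TRA) = 12/112 > 0.1, both kept
  keep <- rbind(chain("c1", "TRA", 12, good), chain("c1", "TRB", 100, good))
  fc <- filter_chains(keep, min_reads = 1)
  expect_setequal(fc$chains$locus, c("TRA", "TRB"))
  expect_equal(sort(fc$chains$flocus), sort(c(12, 100) / 112))
  # TRA 10 vs TRB 100: flocus(TRA) = 10/110 < 0.1, TRA dropped
  drop <- rbind(chain("c2", "TRA", 10, good), chain("c2", "TRB", 100, good))
  fc2 <- filter_chains(drop, min_reads = 1)
  expect_equal(fc2$chains$locus, "TRB")
  expect_equal(fc2$trace$fail_reason[fc2$trace$locus == "TRA"], "flocus")
  # flocus sums to 1 over a cell's loci
  expect_equal(sum(unique(fc2$trace$flocus)), 1)
})

test_that("the cascade is idempotent on its own output", {
  cfg <- synth_config(n_cells_per_sample = 100, secondary_chain_prob = 0.3,
                      unproductive_chain_prob = 0.2, rng_seed = 5)
  r <- simulate_repertoire(cfg, sprintf("c%03d", 1:100))
  fc1 <- filter_chains(r$chains)
  keep_cols <- setdiff(names(fc1$chains), c("top", "flocus"))
  fc2 <- filter_chains(fc1$chains[, keep_cols])
  expect_equal(fc2$chains[, keep_cols], fc1$chains[, keep_cols])
})

test_that("clonotype records pair only cells with both surviving chains", {
  good <- "TGTGCAAGCAGC"
  chains <- rbind(
    chain("c1", "TRB", 60, good, v = "TRBV2", j = "TRBJ3", d = "TRBD1"),
    chain("c2", "TRA", 60, good, v = "TRAV2", j = "TRAJ3"),
    chain("c2", "TRB", 60, good, v = "TRBV2", j = "TRBJ3", d = "TRBD1"),
    chain("c3", "TRA", 60, good, v = "TRAV2", j = "TRAJ3"),
    chain("c3", "TRB", 60, good, v = "TRBV2", j = "TRBJ3", d = "TRBD1"),
    chain("c4", "TRD", 60, good, v = "TRDV1", j = "TRDJ1"))
  ct <- build_clonotypes(filter_chains(chains)$chains)
  expect_true(is.na(ct$clonotypes$tra_clonotype[
    ct$clonotypes$cell_id == "c1"]))
  expect_true(is.na(ct$clonotypes$paired_key[ct$clonotypes$cell_id == "c1"]))
  # identical chains on both loci give identical paired keys
  keys <- ct$clonotypes$paired_key[ct$clonotypes$cell_id %in% c("c2", "c3")]
  expect_equal(keys[1], keys[2])
  expect_false(any(grepl("TRD", ct$clonotypes$cell_id)))
  expect_equal(ct$trd$cell_id, "c4")
  # the D segment stays out of the clonotype key
  expect_false(grepl("TRBD", keys[1]))
})

test_that("diversity: worked examples and the S = 1 convention", {
  ct <- make_clonotypes(c("A", "A", "B", "B"))
  d <- shannon_diversity(ct, "TRA_AND_TRB")
  expect_equal(d$H, log(2))
  expect_equal(d$EH, 1)
  expect_equal(d$S, 2L)
  expect_equal(shannon_diversity(make_clonotypes(rep("A", 20)),
                                 "TRA_AND_TRB")$EH, 0)
  expect_equal(shannon_diversity(make_clonotypes(letters[1:20]),
                                 "TRA_AND_TRB")$EH, 1)
  none <- data.frame(cell_id = character(0), tra_clonotype = character(0),
                     trb_clonotype = character(0), paired_key = character(0))
  expect_error(shannon_diversity(none), "no cells")
})

test_that("H matches a brute-force oracle and EH is relabel-invariant", {
  set.seed(6)
  for (i in 1:10) {
    keys <- sample(letters[1:8], 40, replace = TRUE)
    d <- shannon_diversity(make_clonotypes(keys), "TRA_AND_TRB")
    expect_equal(d$H, oracle_shannon_h(keys), tolerance = 1e-12)
    # relabeling clonotypes leaves EH unchanged
    relab <- setNames(sample(LETTERS[1:8]), letters[1:8])
    d2 <- shannon_diversity(make_clonotypes(unname(relab[keys])),
                            "TRA_AND_TRB")
    expect_equal(d2$EH, d$EH, tolerance = 1e-12)
    # duplicating every cell leaves proportions, hence EH, unchanged
    d3 <- shannon_diversity(make_clonotypes(c(keys, keys)), "TRA_AND_TRB")
    expect_equal(d3$EH, d$EH, tolerance = 1e-12)
  }
})

test_that("EH strictly decreases when counts concentrate", {
  # move one cell from a minority clonotype to the majority one
  base <- c(rep("A", 10), rep("B", 5), rep("C", 5))
  conc <- c(rep("A", 11), rep("B", 4), rep("C", 5))
  eh0 <- shannon_diversity(make_clonotypes(base), "TRA_AND_TRB")$EH
  eh1 <- shannon_diversity(make_clonotypes(conc), "TRA_AND_TRB")$EH
  expect_lt(eh1, eh0)
  # generator sweep: higher clonality never raises expected EH
  mean_eh <- vapply(c(0, 0.8, 1.6, 2.8), function(a) {
    ehs <- vapply(1:5, function(s) {
      cfg <- synth_config(n_cells_per_sample = 100, clonality_alpha = a,
                          clonotype_pool_size = 100,
                          unique_clonotype_fraction = 0,
                          secondary_chain_prob = 0,
                          unproductive_chain_prob = 0, rng_seed = s)
      r <- simulate_repertoire(cfg, sprintf("c%03d", 1:100))
      ct <- build_clonotypes(filter_chains(r$chains)$chains)
      shannon_diversity(ct$clonotypes, "TRA_AND_TRB")$EH
    }, numeric(1))
    mean(ehs)
  }, numeric(1))
  expect_true(all(diff(mean_eh) <= 1e-9))
})

test_that("diversity table covers sample x level combinations", {
  ct <- rbind(make_clonotypes(c("A", "A", "B"), sample_id = "s1"),
              make_clonotypes(letters[1:5], sample_id = "s2"))
  ct$cell_id <- sprintf("c%03d", seq_len(nrow(ct)))
  tab <- diversity_table(ct)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$level), c("TRA", "TRB", "TRA_AND_TRB"))
  expect_equal(tab$EH[tab$sample_id == "s2" & tab$level == "TRA"], 1)
})

test_that("vdj usage table counts cells and normalizes proportions", {
  good <- "TGTGCAAGCAGC"
  rows <- list()
  vs <- c("TRBV5", "TRBV5", rep("TRBV2", 8))
  for (i in 1:10)
    rows[[i]] <- chain(sprintf("c%d", i), "TRB", 60, good,
                       v = vs[i], j = "TRBJ1", d = "TRBD1")
  tab <- vdj_table(do.call(rbind, rows))
  shared <- tab[tab$v_call == "TRBV5", ]
  expect_equal(shared$n_cells, 2L)
  expect_equal(shared$proportion, 0.2)
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-12)
  expect_lt(which(tab$v_call == "TRBV2")[1], which(tab$v_call == "TRBV5")[1])
  # single cell: one row, proportion 1
  tab1 <- vdj_table(chain("c1", "TRA", 60, good))
  expect_equal(tab1$proportion, 1.0)
  # unknown segment warns and sorts last
  odd <- rbind(chain("c1", "TRA", 60, good, v = "TRAV9"),
               chain("c2", "TRA", 60, good, v = "WEIRD1"))
  expect_warning(tab2 <- vdj_table(odd), "WEIRD1")
  expect_equal(tab2$v_call[nrow(tab2)], "WEIRD1")
})

test_that("clonotype overlap counts shared keys between samples", {
  a <- make_clonotypes(c("x", "y", "z"), sample_id = "s1")
  b <- make_clonotypes(c("p", "q"), sample_id = "s2")
  cc <- make_clonotypes(c("x", "y", "w"), sample_id = "s3")
  ct <- rbind(a, b, cc)
  ct$cell_id <- sprintf("c%03d", seq_len(nrow(ct)))
  ov <- clonotype_overlap(ct)
  expect_equal(ov["s1", "s2"], 0L)
  expect_equal(ov["s1", "s3"], 2L)
  expect_equal(ov["s1", "s1"], 3L)
  expect_equal(ov, t(ov))
})
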