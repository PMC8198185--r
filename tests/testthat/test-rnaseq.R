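test_that("count_reads_per_gene applies strandedness and ambiguity rules", {
  genes <- toy_genes("chr1", c(100, 5000), c(2000, 9000), c("+", "-"))
  # reverse rule: read strand opposite gene strand counts
  expect_equal(unname(count_reads_per_gene(
    bed_ranges("chr1", 150, 176, "-"), genes, "reverse")), c(1L, 0L))
  expect_equal(unname(count_reads_per_gene(
    bed_ranges("chr1", 150, 176, "+"), genes, "reverse")), c(0L, 0L))
  expect_equal(unname(count_reads_per_gene(
    bed_ranges("chr1", 150, 176, "+"), genes, "forward")), c(1L, 0L))
  # ambiguous read spanning two eligible genes is discarded
  genes2 <- toy_genes("chr1", c(100, 300), c(400, 600), c("+", "+"))
  expect_equal(unname(count_reads_per_gene(
    bed_ranges("chr1", 350, 380, "-"), genes2, "reverse")), c(0L, 0L))
  # but if only one gene passes the strand rule, the read is unambiguous
  genes3 <- toy_genes("chr1", c(100, 300), c(400, 600), c("+", "-"))
  expect_equal(unname(count_reads_per_gene(
    bed_ranges("chr1", 350, 380, "-"), genes3, "reverse")), c(1L, 0L))
  expect_error(count_reads_per_gene(bed_ranges("chr1", 0, 20, "."), genes,
                                    "reverse"), "contract error")
})

test_that("count_reads_per_gene equals a per-read adjudication oracle", {
  set.seed(47)
  genes <- toy_genes("chr1", c(500, 2000, 2500, 6000), c(2100, 3500, 4000, 8000),
                     c("+", "-", "+", "-"))
  for (i in 1:5) {
    reads <- rand_intervals(500, chroms = "chr1", L = 9000, max_w = 80)
    got <- count_reads_per_gene(reads, genes, "reverse")
    rd <- gr_df(reads); gd <- gr_df(genes)
    expected <- integer(nrow(gd))
    for (j in seq_len(nrow(rd))) {
      hits <- which(rd$start[j] <= gd$end & rd$end[j] >= gd$start &
                      rd$strand[j] != gd$strand)
      if (length(hits) == 1) expected[hits] <- expected[hits] + 1L
    }
    expect_equal(unname(got), expected)
  }
})

test_that("rpkm follows the formula and is depth-invariant", {
  counts <- matrix(c(10L, 999990L), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  lens <- c(a = 1000, b = 99000)
  # library size 1e6: count 10, len 1000 -> 10.0
  expect_equal(rpkm(counts, lens)["a", "s1"],
               10 * 1e9 / (1000 * 1e6))
  m <- matrix(rpois(200, 100), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  storage.mode(m) <- "integer"
  lens2 <- stats::setNames(sample(500:5000, 50), rownames(m))
  r1 <- rpkm(m, lens2)
  r2 <- rpkm(m * 2L, lens2)
  expect_equal(r1, r2)
  expect_equal(r1["g01", "s1"],
               m[1, 1] * 1e9 / (lens2[["g01"]] * sum(m[, 1])))
})

test_that("size factors recover known library scalings", {
  m <- matrix(rpois(400, 200), 100, 4)
  rownames(m) <- sprintf("g%03d", 1:100)
  expect_equal(size_factors(cbind(m[, 1], m[, 1], m[, 1])), rep(1, 3))
  doubled <- cbind(s1 = m[, 1], s2 = m[, 1] * 2L)
  sf <- size_factors(doubled)
  expect_equal(sf[["s2"]] / sf[["s1"]], 2, tolerance = 1e-9)
  expect_equal(exp(mean(log(sf))), 1)
  # NB simulation with known factors, 2000 genes: recovered within 5%
  cfg <- sim_config(seed = 51, n_genes = 2000, n_primed = 0, n_up = 0,
                    n_down = 0, lib_sdlog = 0.2)
  r <- simulate_rnaseq_counts(cfg)
  sf_hat <- size_factors(r$counts)
  sf_true <- r$truth$size_factors / exp(mean(log(r$truth$size_factors)))
  expect_lt(max(abs(sf_hat / sf_true - 1)), 0.05)
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)),
               "estimation error")
})

test_that("dispersion estimates are calibrated at alpha=0 and alpha=0.1", {
  constant <- matrix(50L, 100, 6)
  rownames(constant) <- sprintf("g%03d", 1:100)
  a0 <- estimate_dispersion(constant, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_true(all(a0 == 0))
  cfg <- sim_config(seed = 53, n_genes = 2000, dispersion = 0, n_primed = 0,
                    n_up = 0, n_down = 0, n_replicates = 3)
  r <- simulate_rnaseq_counts(cfg)
  cols <- r$meta$condition %in% c("sensitive_control", "sensitive_cisplatin")
  sub <- r$counts[, cols]
  alpha <- estimate_dispersion(sub, size_factors(sub),
                               r$meta$condition[cols])
  expect_lte(stats::median(alpha), 0.01)
  cfg1 <- sim_config(seed = 54, n_genes = 2000, dispersion = 0.1, n_primed = 0,
                     n_up = 0, n_down = 0, n_replicates = 3)
  r1 <- simulate_rnaseq_counts(cfg1)
  sub1 <- r1$counts[, cols]
  alpha1 <- estimate_dispersion(sub1, size_factors(sub1),
                                r1$meta$condition[cols])
  expect_gt(stats::median(alpha1), 0.07)
  expect_lt(stats::median(alpha1), 0.13)
})

test_that("NB Wald test recovers planted effects and flags low counts", {
  cfg <- sim_config(seed = 55, n_genes = 1000, dispersion = 0.05,
                    expr_meanlog = log(100), expr_sdlog = 0, n_up = 100,
                    n_primed = 0, n_down = 0, de_log2fc = 2, n_replicates = 3)
  r <- simulate_rnaseq_counts(cfg)
  a_cols <- which(r$meta$condition == "sensitive_control")
  b_cols <- which(r$meta$condition == "sensitive_cisplatin")
  de <- de_analysis(r$counts, a_cols, b_cols)
  up <- de[de$gene_id %in% r$truth$up_ids, ]
  expect_lt(stats::median(abs(up$log2fc - 2)), 0.3)
  expect_gte(mean(up$status == "up"), 0.9)
  # all-zero gene: low_count, no p-value
  counts0 <- r$counts
  counts0["gene_0001", ] <- 0L
  de0 <- de_analysis(counts0, a_cols, b_cols)
  row0 <- de0[de0$gene_id == "gene_0001", ]
  expect_equal(row0$status, "low_count")
  expect_true(is.na(row0$pvalue))
})

test_that("down/up classification is antisymmetric under contrast swap", {
  cfg <- sim_config(seed = 57, n_genes = 800, n_up = 40, n_down = 40,
                    n_primed = 0)
  r <- simulate_rnaseq_counts(cfg)
  a_cols <- which(r$meta$condition == "sensitive_control")
  b_cols <- which(r$meta$condition == "sensitive_cisplatin")
  ab <- de_analysis(r$counts, a_cols, b_cols)
  ba <- de_analysis(r$counts, b_cols, a_cols)
  expect_equal(ba$log2fc, -ab$log2fc, tolerance = 1e-6)
  expect_equal(ab$gene_id[ab$status == "up"], ba$gene_id[ba$status == "down"])
  expect_equal(ab$gene_id[ab$status == "down"], ba$gene_id[ba$status == "up"])
})

test_that("size factors and fold changes agree with DESeq2 on a fixture", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(seed = 59, n_genes = 400, n_up = 40, n_down = 0,
                    n_primed = 0, dispersion = 0.05)
  r <- simulate_rnaseq_counts(cfg)
  cols <- r$meta$condition %in% c("sensitive_control", "sensitive_cisplatin")
  m <- r$counts[, cols]
  sf_ours <- size_factors(m)
  sf_deseq <- DESeq2::estimateSizeFactorsForMatrix(m)
  sf_deseq <- sf_deseq / exp(mean(log(sf_deseq)))
  expect_equal(unname(sf_ours), unname(sf_deseq), tolerance = 1e-4)
  # independent cross-check of the whole chain's effect estimates
  cond <- factor(r$meta$condition[cols],
                 levels = c("sensitive_control", "sensitive_cisplatin"))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, S4Vectors::DataFrame(cond = cond),
                                        ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ours <- de_analysis(m, which(cond == "sensitive_control"),
                      which(cond == "sensitive_cisplatin"))
  keep <- !is.na(res$log2FoldChange) & ours$status != "low_count"
  expect_gt(stats::cor(res$log2FoldChange[keep], ours$log2fc[keep]), 0.98)
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # NA (untested) p-values are excluded from m and stay NA
  p <- c(0.01, NA, 0.02, 0.03, 0.04)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[-2], rep(0.04, 4))
})

test_that("classification respects the log2FC and padj thresholds", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    base_mean = 100, log2fc = c(1.5, 0.99, -1.0, 2),
                    se = 1, wald_stat = 1,
                    pvalue = c(0.001, 1e-6, 0.01, 0.2),
                    padj = c(0.01, 1e-6, 0.049, 0.3),
                    status = "tested")
  out <- classify_de(res)
  expect_equal(out$status, c("up", "unchanged", "down", "unchanged"))
})

test_that("length test flags planted long classes and calibrates on null", {
  set.seed(61)
  lens <- round(stats::rlnorm(2000, log(3000), 0.8))
  # class = longest 10%: overwhelming significance at n = 200
  status <- rep("unchanged", 2000)
  status[order(lens, decreasing = TRUE)[1:200]] <- "down"
  res <- length_distribution_test(status, lens, classes = "down")
  expect_lt(res$pvalue, 1e-6)
  expect_gt(res$median_length, res$background_median)
  # class sampled at random from background: p roughly uniform
  ps <- vapply(1:200, function(i) {
    st <- rep("unchanged", 2000)
    st[sample(2000, 100)] <- "down"
    length_distribution_test(st, lens, classes = "down")$pvalue
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_warning(length_distribution_test(c("down", rep("unchanged", 9)),
                                          rlnorm(10), classes = "down"),
                 "fewer than 3")
})
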