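# All generators: determinism under seed, and the declared distributional
# structure within Monte-Carlo tolerance (fixed seeds throughout).

small_cfg <- function(...) {
  defaults <- list(seed = 42, n_chroms = 2, chrom_length = 2e5, n_genes = 30,
                   n_repair_reads = 5000, n_primed = 4, n_up = 4, n_down = 6,
                   n_peaks = 25, n_fragments = 4000, n_false_peaks = 3)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("generators are reproducible under a fixed seed", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  expect_identical(gr_df(g1$genes), gr_df(g2$genes))
  r1 <- simulate_rnaseq_counts(cfg, g1$genes)
  r2 <- simulate_rnaseq_counts(cfg, g2$genes)
  expect_identical(r1$counts, r2$counts)
  a1 <- simulate_atac_replicates(g1$genome, cfg)
  a2 <- simulate_atac_replicates(g1$genome, cfg)
  expect_identical(lapply(a1$replicates, gr_df), lapply(a2$replicates, gr_df))
  x1 <- simulate_xrseq_reads(g1$genome, g1$genes, r1$truth$expression,
                             a1$true_peaks, cfg)
  x2 <- simulate_xrseq_reads(g1$genome, g1$genes, r1$truth$expression,
                             a1$true_peaks, cfg)
  expect_identical(gr_df(x1), gr_df(x2))
})

test_that("G-G dinucleotide density matches the configured rate", {
  cfg0 <- small_cfg(gg_rate = 0, n_chroms = 1, chrom_length = 5e4, n_genes = 3,
                    n_primed = 0, n_up = 0, n_down = 0, n_peaks = 3)
  seq0 <- as.character(simulate_genome(cfg0)$sequence[[1]])
  expect_false(grepl("GG", seq0, fixed = TRUE))
  expect_false(grepl("G", seq0, fixed = TRUE))  # iid model: P(G) = sqrt(0) = 0
  cfg <- small_cfg(gg_rate = 0.05, n_chroms = 1, chrom_length = 1e5, n_genes = 5,
                   n_primed = 0, n_up = 0, n_down = 0, n_peaks = 5)
  s <- as.character(simulate_genome(cfg)$sequence[[1]])
  n_pos <- nchar(s) - 1
  n_gg <- sum(charToRaw(substr(s, 1, n_pos)) == charToRaw("G") &
                charToRaw(substr(s, 2, n_pos + 1)) == charToRaw("G"))
  sd3 <- 3 * sqrt(n_pos * 0.05 * 0.95)
  expect_lt(abs(n_gg - n_pos * 0.05), sd3)
})

test_that("repair-read mixture honours theta at its extremes", {
  cfg <- small_cfg()
  gen <- simulate_genome(cfg)
  expr <- stats::setNames(rep(1, length(gen$genes)),
                          S4Vectors::mcols(gen$genes)$gene_id)
  # theta = 1: every read is TCR, strand opposite its source gene
  r1 <- simulate_xrseq_reads(gen$genome, gen$genes, expr, NULL, cfg, theta = 1)
  expect_true(all(S4Vectors::mcols(r1)$component == "TCR"))
  sc <- gene_strand_counts(r1, gen$genes)
  expect_true(all(sc$nts_count == 0))
  expect_equal(sum(sc$ts_count), length(r1))
  # theta = 0: strand-symmetric; TS:NTS ratio near 1 over gene-overlapping reads
  r0 <- simulate_xrseq_reads(gen$genome, gen$genes, expr, NULL, cfg, theta = 0)
  expect_true(all(S4Vectors::mcols(r0)$component == "GGR"))
  sc0 <- gene_strand_counts(r0, gen$genes)
  tot <- sum(sc0$ts_count) + sum(sc0$nts_count)
  expect_lt(abs(sum(sc0$ts_count) / tot - 0.5), 3 * sqrt(0.25 / tot))
  # theta > 0 with no expressed genes is a config error
  expect_error(simulate_xrseq_reads(gen$genome, gen$genes, expr * 0, NULL,
                                    cfg, theta = 0.5), "config error")
})

test_that("TS fraction at intermediate theta matches the mixture expectation", {
  cfg <- sim_config(seed = 9, n_chroms = 1, chrom_length = 1e6, n_genes = 60,
                    n_repair_reads = 50000, n_primed = 0, n_up = 0, n_down = 0,
                    n_peaks = 0, atac_enrichment = 1)
  gen <- simulate_genome(cfg)
  expr <- rep(1, length(gen$genes))
  theta <- 0.8
  reads <- simulate_xrseq_reads(gen$genome, gen$genes, expr, NULL, cfg,
                                theta = theta)
  sc <- gene_strand_counts(reads, gen$genes)
  ts <- sum(sc$ts_count); nts <- sum(sc$nts_count)
  # gene-overlapping reads: all TCR reads are TS; GGR reads that land on
  # genes split 50/50. Expected TS fraction = (theta + 0.5 * (1-theta) * f)
  # / (theta + (1-theta) * f), f = genic fraction of the genome.
  f <- sum(GenomicRanges::width(gen$genes)) / sum(as.numeric(gen$genome))
  expected <- (theta + 0.5 * (1 - theta) * f) / (theta + (1 - theta) * f)
  n <- ts + nts
  expect_lt(abs(ts / n - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("RNA-seq counts reproduce planted effects and the NB limits", {
  # alpha = 0, no planted effects: Poisson counts, variance ~ mean
  cfg0 <- sim_config(seed = 5, n_genes = 2000, dispersion = 0,
                     n_primed = 0, n_up = 0, n_down = 0, n_replicates = 6,
                     lib_sdlog = 0)
  r0 <- simulate_rnaseq_counts(cfg0)
  ctrl <- r0$counts[, r0$meta$condition == "sensitive_control"]
  m <- rowMeans(ctrl); v <- apply(ctrl, 1, stats::var)
  # regression of variance on mean should have slope ~ 1 (Poisson)
  expect_equal(unname(stats::coef(stats::lm(v ~ m))[2]), 1, tolerance = 0.05)
  # planted treatment log2FC = 2: treated/control mean ratio ~ 4
  cfg <- sim_config(seed = 6, n_genes = 500, n_up = 50, n_primed = 0,
                    n_down = 0, treatment_log2fc = 2, de_log2fc = 2,
                    lib_sdlog = 0)
  r <- simulate_rnaseq_counts(cfg)
  up <- r$truth$up_ids
  tr <- rowMeans(r$counts[up, r$meta$condition == "sensitive_cisplatin"])
  un <- rowMeans(r$counts[up, r$meta$condition == "sensitive_control"])
  expect_equal(median(tr / un), 4, tolerance = 0.15)
  # primed genes elevated at resistant baseline
  cfgp <- sim_config(seed = 7, n_genes = 500, n_primed = 50, primed_log2fc = 2,
                     n_up = 0, n_down = 0, lib_sdlog = 0)
  rp <- simulate_rnaseq_counts(cfgp)
  pr <- rp$truth$primed_ids
  res <- rowMeans(rp$counts[pr, rp$meta$condition == "resistant_control"])
  sen <- rowMeans(rp$counts[pr, rp$meta$condition == "sensitive_control"])
  expect_equal(median(res / sen), 4, tolerance = 0.15)
})

test_that("method-of-moments dispersion of null NB data centres on alpha", {
  cfg <- sim_config(seed = 8, n_genes = 2000, dispersion = 0.1,
                    n_primed = 0, n_up = 0, n_down = 0, n_replicates = 3)
  r <- simulate_rnaseq_counts(cfg)
  norm <- sweep(r$counts, 2, r$truth$size_factors, "/")
  grp <- r$meta$condition
  raw <- vapply(seq_len(nrow(norm)), function(i) {
    y <- norm[i, ]
    ss <- 0
    for (g in unique(grp)) {
      yy <- y[grp == g]; ss <- ss + sum((yy - mean(yy))^2)
    }
    s2 <- ss / (length(y) - length(unique(grp)))
    m <- mean(y)
    if (m > 0) max(0, (s2 - m) / m^2) else NA_real_
  }, 0)
  expect_gt(mean(raw, na.rm = TRUE), 0.07)
  expect_lt(mean(raw, na.rm = TRUE), 0.13)
})

test_that("ATAC replicate model degenerates correctly at its extremes", {
  cfg <- small_cfg(p_detect = 1, jitter_sd = 0, n_false_peaks = 0)
  gen <- simulate_genome(cfg)
  a <- simulate_atac_replicates(gen$genome, cfg)
  for (rep_set in a$replicates)
    expect_identical(gr_df(rep_set), gr_df(a$true_peaks))
  expect_identical(gr_df(a$pooled), gr_df(a$true_peaks))
  cfg0 <- small_cfg(p_detect = 0, n_false_peaks = 5)
  a0 <- simulate_atac_replicates(gen$genome, cfg0)
  for (rep_set in a0$replicates)
    expect_equal(sum(GenomicRanges::countOverlaps(rep_set, a0$true_peaks)), 0,
                 tolerance = 2)  # false peaks may rarely graze a true peak
  expect_error(simulate_atac_replicates(gen$genome,
                                        small_cfg(n_atac_replicates = 1)),
               "config error")
})

test_that("ATAC fragments are enriched inside true peaks", {
  cfg <- small_cfg(n_fragments = 30000, atac_enrichment = 10)
  gen <- simulate_genome(cfg)
  a <- simulate_atac_replicates(gen$genome, cfg)
  in_peak <- sum(GenomicRanges::countOverlaps(a$fragments, a$true_peaks) > 0)
  peak_bp <- sum(GenomicRanges::width(a$true_peaks))
  total_bp <- sum(as.numeric(gen$genome))
  # expected in-peak start fraction from the 10x weighting
  p <- 10 * peak_bp / (10 * peak_bp + (total_bp - peak_bp))
  expect_lt(abs(in_peak / length(a$fragments) - p), 0.05)
})

test_that("sim_config rejects invalid parameters", {
  expect_error(sim_config(tcr_fraction = 1.2), "tcr_fraction")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_genes = 10, n_primed = 5, n_up = 5, n_down = 5),
               "planted")
})
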