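# End-to-end driver: simulate (or load) inputs, then repair profiles and
# strand bias, differential expression, reproducible peaks, primed genes,
# and cross-assay correlations. Every output file carries a provenance
# header (tool version, config hash, seed), and the run is a pure function
# of (config, seed): rerunning with the same config yields byte-identical
# outputs (only run.log, which records wall-clock timings, differs).

#' Pipeline configuration
#'
#' Analysis thresholds and bin sizes layered on top of a [sim_config()].
#' Defaults encode the study design: log2FC threshold +-1 with adjusted
#' p < 0.05 for DE, RPKM >= 10 to include a gene in strand-bias analysis,
#' RPKM > 70 for primed-gene candidates, strict > 50% replicate coverage
#' for reproducible peaks, 40-bp TSS profile bins, 30-bp peak profile
#' bins, 700-bp replicate-correlation windows, and a 25-bp repair signal
#' track.
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param lfc_threshold,padj_threshold DE classification thresholds.
#' @param rpkm_gene_filter Gene-inclusion RPKM floor for strand bias.
#' @param rpkm_candidate Strict basal-RPKM floor for candidates.
#' @param peak_overlap Strict replicate-coverage fraction for peaks.
#' @param tss_upstream,tss_downstream,tss_bin TSS metaprofile geometry.
#' @param peak_flank,peak_bin Peak profile geometry.
#' @param corr_window Replicate-correlation window (bp).
#' @param track_window Signal-track window (bp).
#' @param theta_sensitive,theta_resistant TCR mixture fractions for the
#'   two simulated cell lines (the resistant line is shifted toward TCR).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            lfc_threshold = 1, padj_threshold = 0.05,
                            rpkm_gene_filter = 10, rpkm_candidate = 70,
                            peak_overlap = 0.5,
                            tss_upstream = 3000, tss_downstream = 5000,
                            tss_bin = 40, peak_flank = 3000, peak_bin = 30,
                            corr_window = 700, track_window = 25,
                            theta_sensitive = 0.5, theta_resistant = 0.8) {
  cfg <- as.list(environment())
  for (k in setdiff(names(cfg), "sim"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("pipeline_config: ", k, " must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a flat key-value file
#'
#' Keys matching [sim_config()] arguments configure the simulation; keys
#' matching [pipeline_config()] arguments configure the analysis. Unknown
#' keys are an error.
#'
#' @param path Path to a key-value config file (see [read_config()]).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  kv <- read_config(path)
  sim_keys <- names(formals(sim_config))
  pipe_keys <- setdiff(names(formals(pipeline_config)), "sim")
  unknown <- setdiff(names(kv), c(sim_keys, pipe_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim <- do.call(sim_config, kv[intersect(names(kv), sim_keys)])
  do.call(pipeline_config, c(list(sim = sim),
                             kv[intersect(names(kv), pipe_keys)]))
}

flatten_config <- function(config) {
  flat <- c(config$sim, config[setdiff(names(config), "sim")])
  flat[order(names(flat))]
}

#' Run the full integrative pipeline on synthetic inputs
#'
#' Executes: genome + gene simulation, ATAC replicate simulation and
#' reproducible-peak merging for two conditions, XR-seq read simulation
#' for the sensitive and resistant lines with strand-bias testing and TSS
#' metaprofiles, RNA-seq simulation and both DE contrasts, primed-gene
#' calling and candidate filtering, and cross-assay correlations. All
#' tables, BED/bedGraph tracks, a resolved config copy, a machine-readable
#' summary, and a timing log are written under `out_dir`.
#'
#' @param config A [pipeline_config()] or path to a key-value config file.
#' @param out_dir Output directory (created; must not require recursion
#'   beyond one level).
#' @return Invisibly, the run summary as a named list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- flatten_config(config)
  cfg_hash <- rp_hash(vapply(names(flat), function(k)
    paste(k, format(flat[[k]], digits = 12)), ""))
  seed <- flat$seed
  hdr <- rp_header(seed, cfg_hash)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    t1 <- Sys.time()
    val <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    cat(sprintf("%s\t%.2fs\n", name,
                as.numeric(difftime(Sys.time(), t1, units = "secs"))),
        file = logf, append = TRUE)
    val
  }
  write_config(flat, file.path(out_dir, "config.tsv"), hdr)
  summary <- list(seed = seed)

  sim <- config$sim
  gen <- stage("simulate_genome", simulate_genome(sim))
  write_genes_bed(gen$genes, file.path(out_dir, "genes.bed"), hdr)
  summary$n_genes <- length(gen$genes)

  atac_a <- stage("simulate_atac_control",
                  simulate_atac_replicates(gen$genome, sim, seed_offset = 3L))
  # treated condition: 80% of control's true peaks survive, 10% new ones
  set.seed(sim$seed + 4L)
  keep <- stats::runif(length(atac_a$true_peaks)) < 0.8
  n_new <- max(1L, as.integer(0.1 * length(atac_a$true_peaks)))
  new_pos <- sample_weighted_positions(gen$genome, NULL, n_new)
  w <- as.integer(sim$peak_width)
  new_pk <- GenomicRanges::GRanges(
    new_pos$chrom,
    IRanges::IRanges(pmax(3100L, pmin(new_pos$pos,
      as.integer(chrom_length(gen$genome, new_pos$chrom)) - w - 3100L)),
      width = w))
  mcols(new_pk)$accessibility <- sim$atac_enrichment *
    stats::rlnorm(length(new_pk), -sim$access_sdlog^2 / 2, sim$access_sdlog)
  true_b <- GenomicRanges::sort(suppressWarnings(
    c(atac_a$true_peaks[keep], new_pk)), ignore.strand = TRUE)
  atac_b <- stage("simulate_atac_treated",
                  simulate_atac_replicates(gen$genome, sim, true_peaks = true_b,
                                           seed_offset = 5L))
  peaks_a <- stage("reproducible_peaks_control",
                   reproducible_peaks(atac_a$replicates, atac_a$pooled,
                                      config$peak_overlap))
  peaks_b <- stage("reproducible_peaks_treated",
                   reproducible_peaks(atac_b$replicates, atac_b$pooled,
                                      config$peak_overlap))
  write_bed(peaks_a, file.path(out_dir, "peaks_control.bed"), hdr)
  write_bed(peaks_b, file.path(out_dir, "peaks_treated.bed"), hdr)
  cmp <- condition_peak_comparison(peaks_a, peaks_b)
  write_tsv(cmp$summary, file.path(out_dir, "peak_comparison.tsv"), hdr)
  summary$n_peaks_control <- length(peaks_a)
  summary$n_peaks_treated <- length(peaks_b)
  summary$peaks_shared_control_side <- cmp$summary$shared_a
  summary$peaks_lost <- cmp$summary$unique_a
  summary$peaks_gained <- cmp$summary$unique_b
  prof_shared <- stage("shared_peak_profile",
                       shared_peak_profile(atac_a$fragments, cmp$shared_a,
                                           flank = config$peak_flank,
                                           bin = config$peak_bin))
  write_tsv(prof_shared, file.path(out_dir, "shared_peak_profile.tsv"), hdr)

  rna <- stage("simulate_rnaseq", simulate_rnaseq_counts(sim, gen$genes))
  write_counts(rna$counts, file.path(out_dir, "counts.tsv"), hdr)
  write_tsv(rna$meta, file.path(out_dir, "sample_meta.tsv"), hdr)
  rpkm_mat <- rpkm(rna$counts, rna$gene_lengths)

  de_treat <- stage("de_treatment", de_analysis(
    rna$counts,
    rna$meta$sample[rna$meta$condition == "sensitive_control"],
    rna$meta$sample[rna$meta$condition == "sensitive_cisplatin"],
    config$lfc_threshold, config$padj_threshold))
  de_base <- stage("de_baseline", de_analysis(
    rna$counts,
    rna$meta$sample[rna$meta$condition == "sensitive_control"],
    rna$meta$sample[rna$meta$condition == "resistant_control"],
    config$lfc_threshold, config$padj_threshold))
  write_tsv(de_treat, file.path(out_dir, "de_treatment.tsv"), hdr)
  write_tsv(de_base, file.path(out_dir, "de_baseline.tsv"), hdr)
  summary$n_up_treatment <- sum(de_treat$status == "up")
  summary$n_down_treatment <- sum(de_treat$status == "down")
  lt <- length_distribution_test(de_treat$status,
                                 unname(rna$gene_lengths[de_treat$gene_id]))
  write_tsv(lt, file.path(out_dir, "gene_length_test.tsv"), hdr)

  # expressed-gene subset for strand-bias analysis: RPKM >= threshold in
  # either cell line's untreated samples
  untreated <- split(rna$meta$sample, rna$meta$cell_line)
  expr_ok <- rep(FALSE, nrow(rpkm_mat))
  for (cl in names(untreated)) {
    cols <- intersect(untreated[[cl]],
                      rna$meta$sample[rna$meta$treatment == "control"])
    expr_ok <- expr_ok |
      rowMeans(rpkm_mat[, cols, drop = FALSE]) >= config$rpkm_gene_filter
  }
  genes_expr <- gen$genes[mcols(gen$genes)$gene_id %in%
                            rownames(rpkm_mat)[expr_ok]]
  summary$n_genes_expressed <- length(genes_expr)

  thetas <- c(sensitive = config$theta_sensitive,
              resistant = config$theta_resistant)
  tss_win <- nonoverlapping_tss_regions(genes_expr, gen$genome,
                                        config$tss_upstream,
                                        config$tss_downstream)
  summary$n_tss_windows <- length(tss_win)
  xr_reads <- list()
  for (line in names(thetas)) {
    line_seed <- sim$seed + 10L + match(line, names(thetas))
    reads <- stage(paste0("simulate_xr_", line), simulate_xrseq_reads(
      gen$genome, gen$genes, rna$truth$expression, atac_a$true_peaks, sim,
      theta = thetas[[line]], seed = line_seed))
    reads <- filter_reads(reads)
    xr_reads[[line]] <- reads
    sc <- gene_strand_counts(reads, genes_expr)
    write_tsv(sc, file.path(out_dir, sprintf("strand_counts_%s.tsv", line)),
              hdr)
    bias <- tcr_bias_test(sc, n_comparisons = length(thetas))
    summary[[paste0("tcr_index_", line)]] <- bias$tcr_index
    summary[[paste0("tcr_p_bonferroni_", line)]] <- bias$p_bonferroni
    prof <- stage(paste0("tss_profile_", line), tss_metaprofile(
      reads, tss_win, config$tss_upstream, config$tss_downstream,
      config$tss_bin))
    write_tsv(prof, file.path(out_dir, sprintf("tss_profile_%s.tsv", line)),
              hdr)
    track <- normalize_track(reads, gen$genome, config$track_window)
    write_bedgraph(track, file.path(out_dir, sprintf("track_%s.bedgraph",
                                                     line)), hdr)
  }

  prime <- stage("call_primed_genes", call_primed_genes(de_treat, de_base))
  basal_cols <- rna$meta$sample[rna$meta$condition == "resistant_control"]
  prime <- filter_candidates(prime,
                             rpkm_mat[, basal_cols, drop = FALSE],
                             config$rpkm_candidate)
  write_tsv(prime, file.path(out_dir, "primed_genes.tsv"), hdr)
  write_tsv(prime[prime$is_candidate, ],
            file.path(out_dir, "primed_candidates.tsv"), hdr)
  summary$n_primed <- sum(prime$is_primed)
  summary$n_candidates <- sum(prime$is_candidate)

  sens <- xr_reads$sensitive
  repair_gene <- coverage_count(sens, genes_expr, "ignore")
  expr_rpkm <- rowMeans(rpkm_mat[mcols(genes_expr)$gene_id, , drop = FALSE])
  ce <- repair_expression_correlation(repair_gene, unname(expr_rpkm))
  acc_counts <- coverage_count(atac_a$fragments, peaks_a, "ignore")
  rep_peak <- coverage_count(sens, peaks_a, "ignore")
  ca <- repair_accessibility_correlation(rep_peak, acc_counts)
  corr <- data.frame(
    comparison = c("repair_vs_expression", "repair_vs_accessibility"),
    rho = c(ce$rho, ca$rho), p_value = c(ce$p_value, ca$p_value),
    n = c(ce$n, ca$n))
  write_tsv(corr, file.path(out_dir, "correlations.tsv"), hdr)
  summary$rho_repair_expression <- ce$rho
  summary$rho_repair_accessibility <- ca$rho

  sum_df <- data.frame(key = names(summary),
                       value = vapply(summary, function(v)
                         format(v, trim = TRUE, digits = 10), ""))
  write_tsv(sum_df, file.path(out_dir, "summary.tsv"), hdr)
  cat(sprintf("total\t%.2fs\n",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = logf, append = TRUE)
  invisible(summary)
}
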