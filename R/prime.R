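# Primed-gene calling and cross-assay correlation. A "primed" gene is
# upregulated by cisplatin in the sensitive line AND constitutively
# elevated in the resistant line before treatment; the candidate subset
# additionally clears a basal-expression floor in the resistant line.

#' Call primed genes from two classified DE tables
#'
#' Primed iff status is `up` in both the treatment contrast (cisplatin vs
#' control in the sensitive line) and the baseline contrast (resistant vs
#' sensitive, both untreated), at the same thresholds. The two tables must
#' describe the same gene universe.
#'
#' @param de_treatment Classified DE table for the treatment contrast.
#' @param de_baseline Classified DE table for the baseline contrast.
#' @return data.frame of `PrimedGeneRecord`s: `gene_id`, both effect
#'   sizes/adjusted p-values, `is_primed`.
#' @export
call_primed_genes <- function(de_treatment, de_baseline) {
  a <- de_treatment$gene_id; b <- de_baseline$gene_id
  if (!setequal(a, b)) {
    off <- union(setdiff(a, b), setdiff(b, a))
    stop("reconciliation error: gene ids differ between DE tables: ",
         paste(utils::head(off, 10), collapse = ", "),
         if (length(off) > 10) " ..." else "")
  }
  de_baseline <- de_baseline[match(a, b), ]
  data.frame(
    gene_id = a,
    log2fc_treatment = de_treatment$log2fc,
    padj_treatment = de_treatment$padj,
    log2fc_baseline = de_baseline$log2fc,
    padj_baseline = de_baseline$padj,
    is_primed = de_treatment$status == "up" & de_baseline$status == "up",
    stringsAsFactors = FALSE)
}

#' Filter primed genes to high-basal-expression candidates
#'
#' A candidate is a primed gene whose mean basal RPKM across untreated
#' resistant replicates strictly exceeds `threshold`.
#'
#' @param records data.frame from [call_primed_genes()].
#' @param basal_rpkm Named numeric vector (or matrix of untreated resistant
#'   samples, averaged row-wise) of basal RPKM per gene.
#' @param threshold Strict RPKM floor (default 70).
#' @return `records` with `basal_rpkm_resistant` and `is_candidate` columns.
#' @export
filter_candidates <- function(records, basal_rpkm, threshold = 70) {
  if (is.matrix(basal_rpkm)) basal_rpkm <- rowMeans(basal_rpkm)
  basal <- basal_rpkm[records$gene_id]
  records$basal_rpkm_resistant <- unname(basal)
  records$is_candidate <- records$is_primed & !is.na(basal) & basal > threshold
  records
}

spearman_test <- function(x, y, what) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop(what, ": need >= 10 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(what, ": undefined correlation (constant vector)")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Spearman correlation of repair signal with expression over genes
#'
#' @param repair_counts Per-gene repair read counts (TS + NTS or total).
#' @param expression Per-gene expression (e.g. RPKM), same order.
#' @return List `rho`, `p_value`, `n`.
#' @export
repair_expression_correlation <- function(repair_counts, expression) {
  spearman_test(repair_counts, expression, "repair-expression correlation")
}

#' Spearman correlation of repair signal with accessibility over peaks
#'
#' @param repair_counts Per-peak repair read counts.
#' @param accessibility Per-peak accessibility counts, same order.
#' @return List `rho`, `p_value`, `n`.
#' @export
repair_accessibility_correlation <- function(repair_counts, accessibility) {
  spearman_test(repair_counts, accessibility, "repair-accessibility correlation")
}

#' Pairwise replicate correlation over genomic windows
#'
#' Counts each replicate's reads in fixed windows and returns the Pearson
#' correlation matrix over windows (unit diagonal). Zero-variance
#' replicates yield `NA` entries with a warning.
#'
#' @param reads_by_replicate Named list of `GRanges`.
#' @param genome A [genome_spec()].
#' @param window Window size in bp (default 700).
#' @return Symmetric correlation matrix.
#' @export
replicate_correlation <- function(reads_by_replicate, genome, window = 700) {
  if (length(reads_by_replicate) < 2)
    stop("replicate_correlation: need >= 2 replicates")
  win <- make_windows(genome, window)
  m <- vapply(reads_by_replicate, function(r)
    as.numeric(coverage_count(r, win, "ignore")), numeric(length(win)))
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) warning("zero-variance replicate(s): ",
                           paste(colnames(m)[v == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}
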