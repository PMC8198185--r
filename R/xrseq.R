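# Strand-resolved excision-repair analysis. XR-seq reads mark repaired
# damage sites: each read's strand is the damaged strand, so reads on the
# strand OPPOSITE a gene's annotated strand lie on the transcribed
# (template) strand and report transcription-coupled repair (TCR), while
# same-strand reads report the non-transcribed strand (global genome
# repair at genes has no strand preference).

#' Post-alignment read filtering
#'
#' Removes reads on excluded chromosomes (chrY and chrM by default),
#' removes exact PCR-duplicate reads (identical chrom/start/end/strand,
#' keeping one), and drops reads at least `max_length` bp long. The length
#' cutoff removes untrimmed library artifacts: genuine excision products
#' are ~26 nt, while adapter read-through produces full-length (50 nt)
#' reads. Set `max_length = Inf` to keep them.
#'
#' @param reads Stranded `GRanges`.
#' @param excluded_chroms Character vector of chromosomes to drop.
#' @param max_length Reads with width `>= max_length` are removed.
#' @return Filtered `GRanges`.
#' @export
filter_reads <- function(reads, excluded_chroms = c("chrY", "chrM"),
                         max_length = 50) {
  validate_intervals(reads, "reads")
  keep <- !(as.character(GenomicRanges::seqnames(reads)) %in% excluded_chroms)
  reads <- reads[keep]
  reads <- reads[GenomicRanges::width(reads) < max_length]
  key <- paste(as.character(GenomicRanges::seqnames(reads)),
               GenomicRanges::start(reads), GenomicRanges::end(reads),
               strand_chr(reads))
  reads[!duplicated(key)]
}

#' Classify reads as transcribed-strand / non-transcribed-strand for a gene
#'
#' A read overlapping the gene is `TS` iff its strand is opposite the gene
#' strand (the template strand carries the damage excised during TCR),
#' `NTS` iff the same; non-overlapping reads are `none`.
#'
#' @param reads Stranded `GRanges` (strand `+`/`-`).
#' @param gene A single gene (`GRanges` of length 1, strand `+`/`-`).
#' @return Character vector in `{TS, NTS, none}`, one per read.
#' @export
assign_ts_nts <- function(reads, gene) {
  validate_intervals(reads, "reads")
  stopifnot(length(gene) == 1)
  validate_genes(gene)
  rs <- strand_chr(reads)
  if (any(rs == "*")) stop("contract error: strandless read")
  ov <- GenomicRanges::countOverlaps(reads, gene, ignore.strand = TRUE) > 0
  gs <- strand_chr(gene)
  ifelse(!ov, "none", ifelse(rs == gs, "NTS", "TS"))
}

#' Per-gene transcribed / non-transcribed strand read counts
#'
#' Counts reads over each gene body, split by strand class. The gene set
#' should already be restricted to expressed genes (the study design:
#' RPKM >= 10 in either cell line, see [rpkm()]).
#'
#' @param reads Stranded `GRanges`.
#' @param genes Gene `GRanges` (strand `+`/`-`, `gene_id`).
#' @return data.frame with `gene_id`, `ts_count`, `nts_count`.
#' @export
gene_strand_counts <- function(reads, genes) {
  validate_genes(genes)
  if (length(genes) == 0) {
    warning("empty gene subset; returning no strand counts")
    return(data.frame(gene_id = character(), ts_count = integer(),
                      nts_count = integer()))
  }
  data.frame(gene_id = mcols(genes)$gene_id,
             ts_count = coverage_count(reads, genes, "opposite"),
             nts_count = coverage_count(reads, genes, "same"))
}

#' Paired test for transcribed-strand repair bias
#'
#' Wilcoxon signed-rank test of per-gene (TS, NTS) read-count pairs across
#' genes, with Bonferroni correction for the number of contrasts displayed
#' together. Zero-difference pairs are dropped (if all pairs are tied the
#' test is degenerate and p = 1 is returned with a warning). Also returns
#' the TCR index: the median per-gene `log2((ts + 0.5) / (nts + 0.5))`
#' (Haldane-Anscombe pseudocount), which summarizes the TCR/GGR balance.
#'
#' @param strand_counts data.frame from [gene_strand_counts()].
#' @param n_comparisons Bonferroni multiplier (number of contrasts plotted
#'   together; supplied by the caller).
#' @return List: `statistic` (V), `p_value`, `p_bonferroni`, `tcr_index`,
#'   `n_genes` (pairs with ts + nts > 0), `n_nonzero` (untied pairs).
#' @export
tcr_bias_test <- function(strand_counts, n_comparisons = 1) {
  ts <- strand_counts$ts_count
  nts <- strand_counts$nts_count
  stopifnot(all(ts >= 0), all(nts >= 0))
  informative <- ts + nts > 0
  if (sum(informative) < 10)
    warning("fewer than 10 genes with nonzero strand counts")
  tcr_index <- stats::median(log2((ts + 0.5) / (nts + 0.5)))
  d <- ts - nts
  nz <- sum(d != 0)
  if (nz == 0) {
    warning("degenerate test: all TS/NTS pairs tied; p = 1 by convention")
    return(list(statistic = 0, p_value = 1, p_bonferroni = 1,
                tcr_index = tcr_index, n_genes = sum(informative),
                n_nonzero = 0L))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    ts, nts, paired = TRUE, exact = nz <= 25, correct = TRUE))
  p <- wt$p.value
  list(statistic = unname(wt$statistic), p_value = p,
       p_bonferroni = min(1, p * n_comparisons),
       tcr_index = tcr_index, n_genes = sum(informative), n_nonzero = nz)
}

# 5'-anchored read midpoint: the base floor((width-1)/2) inward from the
# read's 5' end. Equivariant under genome mirroring + strand flip, unlike a
# naive floor of (start+end)/2 for even-width reads. "*" reads use the +
# convention.
read_midpoints <- function(reads) {
  off <- (GenomicRanges::width(reads) - 1L) %/% 2L
  minus <- strand_chr(reads) == "-"
  ifelse(minus, GenomicRanges::end(reads) - off,
         GenomicRanges::start(reads) + off)
}

profile_ci <- function(mat) {
  n <- nrow(mat)
  if (n < 2) return(rep(0, ncol(mat)))
  1.96 * apply(mat, 2, stats::sd) / sqrt(n)
}

#' Strand-specific repair metaprofile around transcription start sites
#'
#' Bins read midpoints in TSS-relative, strand-oriented coordinates
#' (`-` strand genes are mirrored), separately for the transcribed and
#' non-transcribed strand classes. The reported signal is the cross-gene
#' mean per bin of per-billion-mapped-reads counts, with a normal 95%
#' confidence half-width.
#'
#' @param reads Stranded `GRanges`.
#' @param tss_regions Windows from [nonoverlapping_tss_regions()].
#' @param upstream,downstream Window extent used to build `tss_regions`.
#' @param bin Bin size in bp.
#' @param total_reads Mapped-read count used for normalization
#'   (default `length(reads)`).
#' @return data.frame: `bin_start` (bp relative to TSS), `ts_mean`,
#'   `ts_ci`, `nts_mean`, `nts_ci`; attribute `n_genes`.
#' @export
tss_metaprofile <- function(reads, tss_regions, upstream = 3000,
                            downstream = 5000, bin = 40,
                            total_reads = length(reads)) {
  validate_intervals(reads, "reads")
  if (any(strand_chr(reads) == "*"))
    stop("contract error: strandless reads in TSS metaprofile")
  if (total_reads <= 0) stop("normalization error: zero mapped reads")
  expect_w <- upstream + downstream
  full <- GenomicRanges::width(tss_regions) == expect_w
  if (any(!full))
    message(sum(!full), " region(s) skipped: window width != upstream+downstream")
  tss_regions <- tss_regions[full]
  n_bins <- as.integer(ceiling(expect_w / bin))
  n_genes <- length(tss_regions)
  scale <- 1e9 / total_reads
  mts <- matrix(0, n_genes, n_bins)
  mnts <- matrix(0, n_genes, n_bins)
  if (n_genes > 0 && length(reads) > 0) {
    mid <- read_midpoints(reads)
    mid_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                     IRanges::IRanges(mid, mid))
    ov <- GenomicRanges::findOverlaps(mid_gr, tss_regions,
                                      ignore.strand = TRUE)
    if (length(ov) > 0) {
      q <- queryHits(ov); s <- subjectHits(ov)
      gminus <- strand_chr(tss_regions)[s] == "-"
      rel <- ifelse(gminus,
                    GenomicRanges::end(tss_regions)[s] - mid[q],
                    mid[q] - GenomicRanges::start(tss_regions)[s])
      b <- pmin(rel %/% bin + 1L, n_bins)
      is_ts <- strand_chr(reads)[q] != strand_chr(tss_regions)[s]
      idx <- (s - 1L) * n_bins + b
      tab_ts <- tabulate(idx[is_ts], n_genes * n_bins)
      tab_nts <- tabulate(idx[!is_ts], n_genes * n_bins)
      mts <- matrix(tab_ts, n_genes, n_bins, byrow = TRUE)
      mnts <- matrix(tab_nts, n_genes, n_bins, byrow = TRUE)
    }
  }
  mts <- mts * scale
  mnts <- mnts * scale
  out <- data.frame(
    bin_start = (seq_len(n_bins) - 1L) * bin - upstream,
    ts_mean = colMeans(mts), ts_ci = profile_ci(mts),
    nts_mean = colMeans(mnts), nts_ci = profile_ci(mnts))
  attr(out, "n_genes") <- n_genes
  out
}

#' Signal profile over peaks with length-scaled bodies and fixed flanks
#'
#' Peak-centered profile: `flank` bp on each side in fixed `bin`-bp bins,
#' with each peak body rescaled into `body_bins` bins (default the median
#' peak width over `bin`). Both read strands are pooled. Body-bin signal is
#' rescaled to per-nominal-bin units so bodies of different widths are
#' comparable to the flanks. Signal is per billion mapped reads; mean and
#' normal 95% CI across peaks.
#'
#' @param reads `GRanges` (any strand).
#' @param peaks Strandless `GRanges`.
#' @param flank Flank extent in bp.
#' @param bin Flank bin size in bp.
#' @param body_bins Number of bins for the scaled peak body.
#' @param total_reads Mapped-read count for normalization.
#' @return data.frame: `bin`, `zone` (`upstream`/`body`/`downstream`),
#'   `mean`, `ci`; attributes `flank_bins`, `body_bins`, `n_peaks`.
#' @export
peak_profile <- function(reads, peaks, flank = 3000, bin = 30,
                         body_bins = NULL, total_reads = length(reads)) {
  validate_intervals(peaks, "peaks")
  flank_bins <- as.integer(flank %/% bin)
  if (is.null(body_bins))
    body_bins <- max(1L, as.integer(round(stats::median(
      GenomicRanges::width(peaks)) / bin)))
  n_bins <- 2L * flank_bins + body_bins
  n_peaks <- length(peaks)
  m <- matrix(0, n_peaks, n_bins)
  if (n_peaks > 0 && length(reads) > 0) {
    if (total_reads <= 0) stop("normalization error: zero mapped reads")
    mid <- read_midpoints(reads)
    mid_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                     IRanges::IRanges(mid, mid))
    ext <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(peaks),
      IRanges::IRanges(pmax(1, GenomicRanges::start(peaks) - flank),
                       GenomicRanges::end(peaks) + flank))
    ov <- GenomicRanges::findOverlaps(mid_gr, ext, ignore.strand = TRUE)
    q <- queryHits(ov); s <- subjectHits(ov)
    ps <- GenomicRanges::start(peaks)[s]
    pe <- GenomicRanges::end(peaks)[s]
    pw <- GenomicRanges::width(peaks)[s]
    mq <- mid[q]
    b <- integer(length(q))
    left <- mq < ps
    right <- mq > pe
    body <- !left & !right
    b[left] <- pmax(1L, (mq[left] - (ps[left] - flank)) %/% bin + 1L)
    b[body] <- flank_bins +
      pmin(body_bins, as.integer((mq[body] - ps[body]) / pw[body] * body_bins) + 1L)
    b[right] <- flank_bins + body_bins +
      pmin(flank_bins, as.integer((mq[right] - pe[right] - 1L) %/% bin) + 1L)
    idx <- (s - 1L) * n_bins + b
    counts <- matrix(tabulate(idx, n_peaks * n_bins), n_peaks, n_bins,
                     byrow = TRUE)
    # rescale body bins to nominal per-bin units (body bin width = pw/body_bins)
    pw_all <- GenomicRanges::width(peaks)
    body_cols <- seq(flank_bins + 1L, flank_bins + body_bins)
    counts[, body_cols] <- counts[, body_cols] * (bin / (pw_all / body_bins))
    m <- counts * (1e9 / total_reads)
  }
  zone <- rep(c("upstream", "body", "downstream"),
              c(flank_bins, body_bins, flank_bins))
  out <- data.frame(bin = seq_len(n_bins), zone = zone,
                    mean = colMeans(m), ci = profile_ci(m))
  attr(out, "flank_bins") <- flank_bins
  attr(out, "body_bins") <- body_bins
  attr(out, "n_peaks") <- n_peaks
  out
}

#' Windowed, depth-normalized signal track
#'
#' Tiles the genome, counts reads per window (any strand), and scales to
#' reads per billion mapped reads. Writable as bedGraph via
#' [write_bedgraph()].
#'
#' @param reads `GRanges`.
#' @param genome A [genome_spec()].
#' @param window Window size in bp.
#' @return `GRanges` of windows with a `score` column.
#' @export
normalize_track <- function(reads, genome, window) {
  if (length(reads) == 0) stop("normalization error: zero mapped reads")
  win <- make_windows(genome, window)
  cnt <- coverage_count(reads, win, "ignore")
  mcols(win)$score <- cnt * 1e9 / length(reads)
  win
}
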