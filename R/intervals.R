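#' Build a GRanges from BED-convention (0-based half-open) coordinates
#'
#' All user-facing coordinates in this package follow the BED convention:
#' 0-based starts, exclusive ends. Internally intervals are `GRanges`
#' (1-based closed); this constructor and the BED I/O functions perform the
#' conversion so that callers never mix conventions.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric, 0-based half-open coordinates (`start < end`).
#' @param strand Character, one of `"+"`, `"-"`, `"."` (recycled).
#' @param name,score Optional metadata columns (recycled).
#' @return A `GRanges` with `name` and `score` metadata columns.
#' @examples
#' bed_ranges("chr1", 10, 20, "+")
#' @export
bed_ranges <- function(chrom, start, end, strand = ".", name = ".", score = 0) {
  if (any(start < 0)) stop("coordinate error: start < 0")
  if (any(end <= start)) stop("coordinate error: end <= start")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-", ".", "*")))
    stop("coordinate error: strand must be one of +, -, .")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges   = IRanges::IRanges(start = start + 1, end = end),
    strand   = strand)
  mcols(gr)$name <- rep_len(as.character(name), length(gr))
  mcols(gr)$score <- rep_len(as.numeric(score), length(gr))
  gr
}

validate_intervals <- function(gr, what = "intervals") {
  if (!is(gr, "GRanges")) stop(what, ": expected a GRanges")
  if (length(gr) == 0) return(invisible(gr))
  if (any(GenomicRanges::start(gr) < 1))
    stop("coordinate error: ", what, " with start < 0 (BED)")
  if (any(GenomicRanges::width(gr) < 1))
    stop("coordinate error: ", what, " with end <= start")
  invisible(gr)
}

strand_chr <- function(gr) as.character(GenomicRanges::strand(gr))

#' Merge intervals into maximal non-overlapping runs
#'
#' Union of the covered base set, bedtools-merge style: overlapping or
#' book-ended intervals collapse into one. With `strand_aware = TRUE`,
#' merging happens only within strand.
#'
#' @param intervals `GRanges`.
#' @param strand_aware Merge within strand only?
#' @return Sorted `GRanges` of disjoint intervals covering the same bases.
#' @export
merge_intervals <- function(intervals, strand_aware = FALSE) {
  validate_intervals(intervals)
  if (length(intervals) == 0) return(GenomicRanges::GRanges())
  out <- GenomicRanges::reduce(intervals, ignore.strand = !strand_aware)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Extend an interval strand-relatively, clipped to the genome
#'
#' `upstream`/`downstream` are interpreted relative to the interval's strand
#' (for `-` intervals, upstream extends the right/end side). Unstranded
#' intervals are treated as `+`. Results are clipped to `[0, chrom length)`.
#'
#' @param interval `GRanges` (vectorized).
#' @param genome A [genome_spec()].
#' @param upstream,downstream Extension in bp (non-negative).
#' @return `GRanges` with extended, clipped ranges.
#' @export
slop <- function(interval, genome, upstream = 0, downstream = 0) {
  validate_intervals(interval)
  if (upstream < 0 || downstream < 0)
    stop("parameter error: upstream/downstream must be >= 0")
  if (length(interval) == 0) return(interval)
  len <- chrom_length(genome, GenomicRanges::seqnames(interval))
  minus <- strand_chr(interval) == "-"
  s <- GenomicRanges::start(interval) - ifelse(minus, downstream, upstream)
  e <- GenomicRanges::end(interval) + ifelse(minus, upstream, downstream)
  out <- interval
  GenomicRanges::ranges(out) <- IRanges::IRanges(
    start = pmax(1, s), end = pmin(len, e))
  out
}

#' Tile a genome into fixed-size windows
#'
#' Tiles each chromosome left to right; the last window of a chromosome may
#' be shorter. Windows are disjoint and jointly cover the genome.
#'
#' @param genome A [genome_spec()].
#' @param size Window size in bp (> 0).
#' @return Unstranded `GRanges` of windows, ordered by (chrom, start).
#' @export
make_windows <- function(genome, size) {
  if (!is.numeric(size) || length(size) != 1 || size <= 0)
    stop("parameter error: window size must be a single positive number")
  size <- as.integer(size)
  chroms <- names(genome)
  starts <- lapply(chroms, function(ch)
    seq.int(1L, chrom_length(genome, ch), by = size))
  n_per <- lengths(starts)
  starts <- unlist(starts)
  ends <- pmin(starts + size - 1L,
               rep(as.numeric(genome), n_per))
  GenomicRanges::GRanges(rep(chroms, n_per),
                         IRanges::IRanges(start = starts, end = ends))
}

#' Count reads overlapping each region
#'
#' A read counts for a region if it overlaps by at least 1 bp.
#' `strand_mode = "same"` counts only reads whose strand equals the region
#' strand; `"opposite"` counts the complementary strand; `"ignore"` counts
#' all reads. Unstranded reads are never counted under `"same"`/`"opposite"`.
#'
#' @param reads,regions `GRanges`.
#' @param strand_mode One of `"ignore"`, `"same"`, `"opposite"`.
#' @return Integer vector of counts, one per region.
#' @export
coverage_count <- function(reads, regions,
                           strand_mode = c("ignore", "same", "opposite")) {
  strand_mode <- match.arg(strand_mode)
  validate_intervals(reads, "reads")
  validate_intervals(regions, "regions")
  if (strand_mode == "ignore")
    return(GenomicRanges::countOverlaps(regions, reads, ignore.strand = TRUE))
  rstr <- strand_chr(regions)
  if (any(rstr == "*"))
    stop("contract error: strand_mode=", strand_mode,
         " requires stranded regions")
  cnt <- integer(length(regions))
  reads_str <- strand_chr(reads)
  for (s in c("+", "-")) {
    idx <- which(rstr == s)
    if (length(idx) == 0) next
    target <- if (strand_mode == "same") s else flip_strand(s)
    cnt[idx] <- GenomicRanges::countOverlaps(
      regions[idx], reads[reads_str == target], ignore.strand = TRUE)
  }
  cnt
}

#' Fraction of interval `a` covered by interval `b`
#'
#' Asymmetric by design: returns `length(a intersect b) / length(a)`.
#' Vectorized over pairs (`b` may be length 1).
#'
#' @param a,b `GRanges` of equal length (or `b` of length 1).
#' @return Numeric in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  validate_intervals(a, "a")
  validate_intervals(b, "b")
  if (length(b) == 1) b <- rep(b, length(a))
  if (length(a) != length(b))
    stop("overlap_fraction: a and b must have equal length (or b length 1)")
  same_chrom <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  inter <- pmax(0, pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
                  pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1)
  ifelse(same_chrom, inter / GenomicRanges::width(a), 0)
}

#' Transcription start sites of a gene set
#'
#' The TSS is the 5' base of the gene: `start` for `+` genes, `end` for `-`
#' genes (1-based internal coordinates).
#'
#' @param genes A gene `GRanges` with strand `+`/`-`.
#' @return Numeric vector of TSS positions (1-based).
#' @export
gene_tss <- function(genes) {
  validate_genes(genes)
  ifelse(strand_chr(genes) == "+",
         GenomicRanges::start(genes), GenomicRanges::end(genes))
}

validate_genes <- function(genes) {
  validate_intervals(genes, "genes")
  if (length(genes) && any(strand_chr(genes) == "*"))
    stop("genes must be stranded (+/-)")
  if (is.null(mcols(genes)$gene_id))
    stop("genes must carry a gene_id metadata column")
  if (anyDuplicated(mcols(genes)$gene_id))
    stop("duplicated gene_id")
  invisible(genes)
}

#' Non-overlapping strand-aware TSS windows
#'
#' Builds, per gene, the window spanning `upstream` bp 5' of the TSS and
#' `downstream` bp from the TSS onward (strand-aware, so `-` genes extend
#' upstream to the right). Genes whose window would extend past the
#' chromosome are dropped, and any pair of genes whose windows overlap are
#' BOTH dropped, so the retained windows are pairwise disjoint.
#'
#' @param genes Gene `GRanges` (strand `+`/`-`, `gene_id` column).
#' @param genome A [genome_spec()].
#' @param upstream,downstream Window extent in bp.
#' @return `GRanges` of windows with `gene_id` and `tss` columns, strand set
#'   to the gene strand.
#' @export
nonoverlapping_tss_regions <- function(genes, genome,
                                       upstream = 3000, downstream = 5000) {
  validate_genes(genes)
  if (length(genes) == 0) return(GenomicRanges::GRanges())
  tss <- gene_tss(genes)
  minus <- strand_chr(genes) == "-"
  ws <- ifelse(minus, tss - downstream + 1, tss - upstream)
  we <- ifelse(minus, tss + upstream, tss + downstream - 1)
  len <- chrom_length(genome, GenomicRanges::seqnames(genes))
  in_bounds <- ws >= 1 & we <= len
  if (any(!in_bounds))
    message(sum(!in_bounds), " gene(s) dropped: TSS window out of bounds")
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes)[in_bounds],
    IRanges::IRanges(ws[in_bounds], we[in_bounds]),
    strand = GenomicRanges::strand(genes)[in_bounds])
  mcols(win)$gene_id <- mcols(genes)$gene_id[in_bounds]
  mcols(win)$tss <- tss[in_bounds]
  keep <- GenomicRanges::countOverlaps(win, win, ignore.strand = TRUE) == 1
  win[keep]
}
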