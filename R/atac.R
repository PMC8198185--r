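# Reproducible-peak merging and condition peak-set comparison. Peak calling
# itself is upstream (inputs are per-replicate and pooled peak interval
# files); this module applies the study's own reproducibility rule: a
# pooled peak survives only if every replicate's merged peak coverage spans
# strictly more than half of it.

#' Replicate-reproducible peaks
#'
#' A pooled peak is retained iff, for every replicate, the union of that
#' replicate's peaks covers strictly more than `min_fraction` of the pooled
#' peak's length. Coverage-based (the replicate's peaks are merged first),
#' so the rule is independent of how the replicate fragments its calls.
#'
#' @param replicate_sets List (length >= 2) of `GRanges` peak sets.
#' @param pooled `GRanges` of pooled peaks.
#' @param min_fraction Strict lower bound on covered fraction (default 0.5).
#' @return Sorted, non-overlapping `GRanges` of retained pooled peaks.
#' @export
reproducible_peaks <- function(replicate_sets, pooled, min_fraction = 0.5) {
  if (length(replicate_sets) < 2)
    stop("reproducible_peaks: need >= 2 replicate sets")
  if (length(pooled) == 0) return(GenomicRanges::GRanges())
  pooled <- merge_intervals(pooled)
  keep <- rep(TRUE, length(pooled))
  for (rep_set in replicate_sets) {
    cov <- merge_intervals(rep_set)
    frac <- covered_fraction(pooled, cov)
    keep <- keep & frac > min_fraction
  }
  pooled[keep]
}

# Fraction of each interval in `x` covered by the (disjoint) set `cov`.
covered_fraction <- function(x, cov) {
  if (length(cov) == 0) return(rep(0, length(x)))
  ov <- GenomicRanges::findOverlaps(x, cov, ignore.strand = TRUE)
  q <- queryHits(ov); s <- subjectHits(ov)
  inter <- pmin(GenomicRanges::end(x)[q], GenomicRanges::end(cov)[s]) -
    pmax(GenomicRanges::start(x)[q], GenomicRanges::start(cov)[s]) + 1
  covered <- rep(0, length(x))
  if (length(q)) {
    agg <- tapply(inter, q, sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / GenomicRanges::width(x)
}

#' Shared and unique peaks between two conditions
#'
#' A peak of one set is shared iff it overlaps (>= 1 bp) any peak of the
#' other set; shared counts are reported from each side since the sets'
#' peak boundaries differ.
#'
#' @param set_a,set_b Merged `GRanges` peak sets.
#' @return List: `shared_a`, `unique_a`, `shared_b`, `unique_b` (`GRanges`)
#'   and a one-row `summary` data.frame of counts.
#' @export
condition_peak_comparison <- function(set_a, set_b) {
  validate_intervals(set_a, "set_a")
  validate_intervals(set_b, "set_b")
  in_b <- GenomicRanges::countOverlaps(set_a, set_b, ignore.strand = TRUE) > 0
  in_a <- GenomicRanges::countOverlaps(set_b, set_a, ignore.strand = TRUE) > 0
  list(shared_a = set_a[in_b], unique_a = set_a[!in_b],
       shared_b = set_b[in_a], unique_b = set_b[!in_a],
       summary = data.frame(n_a = length(set_a), n_b = length(set_b),
                            shared_a = sum(in_b), unique_a = sum(!in_b),
                            shared_b = sum(in_a), unique_b = sum(!in_a)))
}

#' Accessibility profile over shared peaks
#'
#' Delegates to [peak_profile()] with ATAC fragments as the reads (strands
#' pooled).
#'
#' @param fragments `GRanges` of ATAC fragments.
#' @param shared_peaks Strandless `GRanges`.
#' @param flank,bin,body_bins,total_reads As in [peak_profile()].
#' @return A binned-profile data.frame; see [peak_profile()].
#' @export
shared_peak_profile <- function(fragments, shared_peaks, flank = 3000,
                                bin = 30, body_bins = NULL,
                                total_reads = length(fragments)) {
  if (length(shared_peaks) == 0) stop("shared_peaks must be nonempty")
  peak_profile(fragments, shared_peaks, flank = flank, bin = bin,
               body_bins = body_bins, total_reads = total_reads)
}
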