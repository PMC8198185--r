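# Independent brute-force oracles for interval algebra, written against
# per-base boolean occupancy on small genomes. Deliberately naive and
# separate from the package's GRanges-based implementations.

# Boolean occupancy vector (1-based, length L) for intervals on one chrom.
occupancy <- function(starts, ends, L) {
  v <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] >= starts[i]) v[starts[i]:min(ends[i], L)] <- TRUE
  }
  v
}

gr_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# Oracle merge: the set of occupied bases, per chrom (and per strand when
# strand_aware), as a sorted integer vector keyed by group.
oracle_base_set <- function(gr, L, strand_aware = FALSE) {
  df <- gr_df(gr)
  key <- if (strand_aware) paste(df$chrom, df$strand) else df$chrom
  lapply(split(df, key), function(d) which(occupancy(d$start, d$end, L)))
}

# The base set of a merged result must equal the oracle's, and the result
# must be disjoint.
expect_same_base_set <- function(merged, original, L, strand_aware = FALSE) {
  expect_equal(oracle_base_set(merged, L, strand_aware),
               oracle_base_set(original, L, strand_aware))
  df <- gr_df(merged)
  key <- if (strand_aware) paste(df$chrom, df$strand) else df$chrom
  for (d in split(df, key)) {
    cov <- integer(L)
    for (i in seq_len(nrow(d))) cov[d$start[i]:d$end[i]] <-
        cov[d$start[i]:d$end[i]] + 1L
    expect_true(all(cov <= 1L))
  }
}

# Oracle pairwise overlap counting (double loop, >= 1 bp, half-open BED
# semantics are already encoded in the 1-based closed GRanges).
oracle_coverage <- function(reads, regions, mode) {
  rd <- gr_df(reads); rg <- gr_df(regions)
  out <- integer(nrow(rg))
  for (i in seq_len(nrow(rg))) {
    for (j in seq_len(nrow(rd))) {
      if (rd$chrom[j] != rg$chrom[i]) next
      if (rd$start[j] > rg$end[i] || rd$end[j] < rg$start[i]) next
      ok <- switch(mode,
                   ignore = TRUE,
                   same = rd$strand[j] == rg$strand[i],
                   opposite = rd$strand[j] == chartr("+-", "-+", rg$strand[i]))
      if (ok) out[i] <- out[i] + 1L
    }
  }
  out
}

oracle_overlap_fraction <- function(a, b, L) {
  da <- gr_df(a); db <- gr_df(b)
  if (da$chrom != db$chrom) return(0)
  va <- occupancy(da$start, da$end, L)
  vb <- occupancy(db$start, db$end, L)
  sum(va & vb) / sum(va)
}

# Oracle reproducible-peak rule: per-base coverage fraction of each pooled
# peak under every replicate's occupancy, strict > threshold for all.
oracle_reproducible <- function(replicate_sets, pooled, L, thr = 0.5) {
  pd <- gr_df(pooled)
  keep <- rep(TRUE, nrow(pd))
  for (rs in replicate_sets) {
    rd <- gr_df(rs)
    for (ch in unique(pd$chrom)) {
      v <- occupancy(rd$start[rd$chrom == ch], rd$end[rd$chrom == ch], L)
      idx <- which(pd$chrom == ch)
      for (i in idx) {
        frac <- sum(v[pd$start[i]:pd$end[i]]) / (pd$end[i] - pd$start[i] + 1)
        if (frac <= thr) keep[i] <- FALSE
      }
    }
  }
  keep
}

# Random stranded intervals on a toy genome (BED coordinates in, GRanges out).
rand_intervals <- function(n, chroms = c("chr1", "chr2"), L = 10000,
                           max_w = 500, stranded = TRUE) {
  start <- sample.int(L - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  bed_ranges(sample(chroms, n, replace = TRUE), start, start + w,
             if (stranded) sample(c("+", "-"), n, TRUE) else ".")
}

toy_genes <- function(chrom, start, end, strand, ids = NULL) {
  g <- bed_ranges(chrom, start, end, strand)
  S4Vectors::mcols(g)$gene_id <- ids %||% sprintf("g%03d", seq_along(g))
  S4Vectors::mcols(g)$name <- NULL
  S4Vectors::mcols(g)$score <- NULL
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
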