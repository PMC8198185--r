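# Synthetic-data generators. They emulate the statistical structure of a
# paired sensitive/resistant cell-line study of cisplatin response:
#  * a genome where damage substrate (G-G dinucleotides) is roughly uniform,
#  * excision-repair reads drawn from a two-component mixture:
#      TCR — expression-weighted, transcribed-strand only;
#      GGR — accessibility-weighted, strand-symmetric;
#  * negative-binomial RNA-seq counts over four conditions
#    (sensitive/resistant x control/cisplatin) with planted treatment-
#    responsive and "primed" (resistant-baseline-elevated) genes;
#  * replicate ATAC peak sets with detection dropout, boundary jitter and
#    false positives.
# Every generator is deterministic under config$seed; sub-generators use
# fixed small seed offsets so they are independently reproducible.

#' Simulation configuration
#'
#' Defaults describe a desk-scale study with the structure the analysis
#' assumes: a two-chromosome 4 Mb genome, a few hundred genes with
#' log-normal lengths and expression, NB dispersion 0.1, triplicate RNA-seq
#' per condition, ~26 nt excision reads (the length of the oligomer released
#' by nucleotide excision repair), and a TCR mixture fraction `tcr_fraction`.
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Number of genes to place (non-overlapping).
#' @param gene_meanlog,gene_sdlog Log-normal gene-length parameters (bp).
#' @param expr_meanlog,expr_sdlog Log-normal baseline expression parameters.
#' @param dispersion NB dispersion alpha (>= 0; 0 = Poisson).
#' @param n_replicates RNA-seq replicates per condition.
#' @param tcr_fraction Mixture weight theta of the TCR component in `[0,1]`.
#' @param n_repair_reads,read_length Excision-read depth and length.
#' @param n_primed,primed_log2fc,treatment_log2fc Primed-gene planting:
#'   primed genes gain `treatment_log2fc` in sensitive-treated and
#'   `primed_log2fc` at resistant baseline.
#' @param n_up,n_down,de_log2fc Additional treatment-only up/down genes.
#' @param down_by_length Plant downregulation with probability proportional
#'   to gene length (damage-load proxy: longer genes are likelier to carry a
#'   polymerase-blocking adduct).
#' @param gg_rate Target G-G dinucleotide density of the genome.
#' @param lib_sdlog Log-normal sd of library-size factors.
#' @param n_peaks,peak_width True accessibility peaks.
#' @param p_detect,jitter_sd,n_false_peaks Replicate peak-calling model.
#' @param atac_enrichment Mean accessibility weight inside peaks vs
#'   baseline.
#' @param access_sdlog Log-normal sd of per-peak accessibility multipliers
#'   (mean 1, so `atac_enrichment` stays the expected in-peak weight).
#' @param n_atac_replicates,n_fragments,fragment_length ATAC read model.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2, chrom_length = 2e6,
                       n_genes = 300,
                       gene_meanlog = log(2000), gene_sdlog = 0.6,
                       expr_meanlog = 4, expr_sdlog = 1,
                       dispersion = 0.1,
                       n_replicates = 3,
                       tcr_fraction = 0.6,
                       n_repair_reads = 5e4, read_length = 26,
                       n_primed = 20, primed_log2fc = 2, treatment_log2fc = 2,
                       n_up = 30, n_down = 60, de_log2fc = 2,
                       down_by_length = TRUE,
                       gg_rate = 0.042,
                       lib_sdlog = 0.1,
                       n_peaks = 150, peak_width = 600,
                       p_detect = 0.9, jitter_sd = 50, n_false_peaks = 10,
                       atac_enrichment = 10, access_sdlog = 0.5,
                       n_atac_replicates = 2, n_fragments = 2e4,
                       fragment_length = 100) {
  cfg <- as.list(environment())
  if (cfg$tcr_fraction < 0 || cfg$tcr_fraction > 1)
    stop("sim_config: tcr_fraction must be in [0, 1]")
  if (cfg$dispersion < 0) stop("sim_config: dispersion must be >= 0")
  if (cfg$gg_rate < 0 || cfg$gg_rate > 1)
    stop("sim_config: gg_rate must be in [0, 1]")
  counts <- c("n_chroms", "n_genes", "n_replicates", "n_repair_reads",
              "n_primed", "n_up", "n_down", "n_peaks", "n_false_peaks",
              "n_atac_replicates", "n_fragments")
  for (k in counts) if (cfg[[k]] < 0) stop("sim_config: ", k, " must be >= 0")
  if (cfg$n_primed + cfg$n_up + cfg$n_down > cfg$n_genes)
    stop("sim_config: more planted genes than genes")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome, its sequence, and a non-overlapping gene annotation
#'
#' The sequence is i.i.d. with P(G) chosen so the expected G-G dinucleotide
#' density equals `gg_rate` (the substrate density that makes cisplatin
#' damage roughly uniform genome-wide). Genes have log-normal lengths, are
#' placed uniformly without overlap, and get Bernoulli(0.5) strands.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([genome_spec()]), `sequence`
#'   (`DNAStringSet`), and `genes` (`GRanges` with `gene_id`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- sqrt(config$gg_rate)
  probs <- c(A = (1 - g) / 3, C = (1 - g) / 3, G = g, T = (1 - g) / 3)
  L <- as.integer(config$chrom_length)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = ""), ""))
  names(seqs) <- chroms
  genome <- genome_spec(stats::setNames(rep(L, length(chroms)), chroms))

  n <- config$n_genes
  lens <- pmax(200L, as.integer(round(stats::rlnorm(
    n, config$gene_meanlog, config$gene_sdlog))))
  # margin keeps TSS windows (3 kb up / 5 kb down) inside the chromosome
  margin <- 5100L
  placed <- place_nonoverlapping(genome, lens, margin,
                                 what = sprintf("%d non-overlapping genes", n))
  placed_chrom <- placed$chrom; placed_start <- placed$start
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- GenomicRanges::GRanges(
    placed_chrom,
    IRanges::IRanges(placed_start, placed_start + lens - 1L),
    strand = strand)
  mcols(genes)$gene_id <- sprintf("gene_%04d", seq_len(n))
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  mcols(genes)$gene_id <- sprintf("gene_%04d", seq_len(n))
  list(genome = genome, sequence = seqs, genes = genes)
}

# Uniform random placement of n intervals of given lengths, pairwise
# non-overlapping, keeping `margin` bp clear of both chromosome ends.
# Bounded retries; errors when the genome is too crowded.
place_nonoverlapping <- function(genome, lens, margin, what = "intervals",
                                 spacing = 0) {
  chroms <- names(genome)
  n <- length(lens)
  occ <- stats::setNames(lapply(chroms, function(x)
    list(s = numeric(0), e = numeric(0))), chroms)
  out_chrom <- character(n); out_start <- numeric(n)
  attempts <- 0L; max_attempts <- 100L * max(1L, n)
  i <- 1L
  while (i <= n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("capacity error: cannot place ", what, " on this genome")
    ch <- if (length(chroms) > 1) sample(chroms, 1) else chroms
    L <- chrom_length(genome, ch)
    room <- L - lens[i] - 2 * margin
    if (room < 1) stop("capacity error: interval longer than chromosome")
    s <- sample.int(room, 1) + margin
    e <- s + lens[i] - 1
    o <- occ[[ch]]
    if (!any(s - spacing <= o$e & e + spacing >= o$s)) {
      out_chrom[i] <- ch; out_start[i] <- s
      occ[[ch]]$s <- c(o$s, s); occ[[ch]]$e <- c(o$e, e)
      i <- i + 1L
    }
  }
  data.frame(chrom = out_chrom, start = out_start)
}

# Sample n positions from a genome with elevated weight inside `peaks` and
# weight 1 elsewhere. Per-peak weights come from an `accessibility` metadata
# column when present (peaks must then be non-overlapping), otherwise the
# scalar `enrichment`. Returns data.frame(chrom, pos), 1-based.
sample_weighted_positions <- function(genome, peaks, n, enrichment = 1) {
  chroms <- names(genome)
  pw <- if (!is.null(peaks)) mcols(peaks)$accessibility else NULL
  if (is.null(peaks) || length(peaks) == 0 ||
      (is.null(pw) && enrichment == 1)) {
    segs <- data.frame(chrom = chroms, start = 1,
                       end = as.numeric(genome), w = 1)
  } else {
    if (is.null(pw)) {
      pk <- merge_intervals(peaks)
      pw <- rep(enrichment, length(pk))
    } else {
      pk <- GenomicRanges::sort(peaks, ignore.strand = TRUE)
      pw <- mcols(pk)$accessibility
      if (any(GenomicRanges::countOverlaps(pk, pk) > 1))
        stop("per-peak accessibility requires non-overlapping peaks")
    }
    segs <- do.call(rbind, lapply(chroms, function(ch) {
      L <- chrom_length(genome, ch)
      sel <- as.character(GenomicRanges::seqnames(pk)) == ch
      ps <- GenomicRanges::start(pk)[sel]
      pe <- pmin(GenomicRanges::end(pk)[sel], L)
      bg <- data.frame(chrom = ch, start = c(1, pe + 1),
                       end = c(ps - 1, L), w = 1)
      bg <- bg[bg$end >= bg$start, , drop = FALSE]
      if (length(ps) == 0) return(bg)
      rbind(data.frame(chrom = ch, start = ps, end = pe, w = pw[sel]), bg)
    }))
  }
  seg_len <- segs$end - segs$start + 1
  idx <- sample.int(nrow(segs), n, replace = TRUE, prob = seg_len * segs$w)
  offset <- floor(stats::runif(n) * seg_len[idx])
  data.frame(chrom = segs$chrom[idx], pos = segs$start[idx] + offset)
}

#' Simulate excision-repair (XR-seq) reads from the TCR/GGR mixture
#'
#' Each read is, with probability `theta`, a TCR read: a gene is sampled
#' proportionally to expression, the position is uniform in the gene body,
#' and the read strand is the transcribed (template) strand, i.e. the
#' opposite of the gene's annotated strand. Otherwise it is a GGR read:
#' position sampled proportionally to accessibility (weight
#' `atac_enrichment` inside `peaks`, 1 elsewhere) with a Bernoulli(0.5)
#' strand. The generating component of each read is recorded.
#'
#' @param genome A [genome_spec()].
#' @param genes Gene `GRanges`.
#' @param expression Non-negative per-gene sampling weight.
#' @param peaks Accessibility peaks (`GRanges`) or `NULL` for uniform GGR.
#' @param config A [sim_config()]; `tcr_fraction`, `n_repair_reads`,
#'   `read_length`, `atac_enrichment` are used.
#' @param theta,n_reads,seed Optional overrides of the config values
#'   (`seed` defaults to `config$seed + 1`).
#' @return `GRanges` reads with a `component` column (`"TCR"`/`"GGR"`).
#' @export
simulate_xrseq_reads <- function(genome, genes, expression, peaks, config,
                                 theta = config$tcr_fraction,
                                 n_reads = config$n_repair_reads,
                                 seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (theta < 0 || theta > 1) stop("config error: theta must be in [0,1]")
  if (theta > 0 && (length(genes) == 0 || all(expression <= 0)))
    stop("config error: TCR component requires genes with positive expression")
  set.seed(seed)
  rl <- as.integer(config$read_length)
  n_reads <- as.integer(n_reads)
  is_tcr <- stats::runif(n_reads) < theta
  chrom <- character(n_reads); start <- integer(n_reads)
  strand <- character(n_reads)
  n_t <- sum(is_tcr)
  if (n_t > 0) {
    gi <- sample.int(length(genes), n_t, replace = TRUE, prob = expression)
    gs <- GenomicRanges::start(genes)[gi]
    gw <- GenomicRanges::width(genes)[gi]
    start[is_tcr] <- gs + floor(stats::runif(n_t) * pmax(1, gw - rl + 1))
    chrom[is_tcr] <- as.character(GenomicRanges::seqnames(genes))[gi]
    strand[is_tcr] <- flip_strand(strand_chr(genes)[gi])
  }
  n_g <- n_reads - n_t
  if (n_g > 0) {
    pos <- sample_weighted_positions(genome, peaks, n_g,
                                     config$atac_enrichment)
    chrom[!is_tcr] <- pos$chrom
    start[!is_tcr] <- pos$pos
    strand[!is_tcr] <- sample(c("+", "-"), n_g, replace = TRUE)
  }
  # keep reads inside their chromosome
  maxs <- chrom_length(genome, chrom) - rl + 1
  start <- pmin(pmax(start, 1), maxs)
  reads <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, width = rl), strand = strand)
  mcols(reads)$component <- ifelse(is_tcr, "TCR", "GGR")
  reads
}

#' Simulate negative-binomial RNA-seq counts with planted structure
#'
#' Four conditions (sensitive/resistant cell line, control/cisplatin
#' treatment) with `n_replicates` each. Gene means are
#' `size factor x baseline expression x condition effect`; counts are
#' NB(mu, 1/alpha) (Poisson when alpha = 0). Planted genes: primed genes
#' gain `treatment_log2fc` in sensitive-treated and `primed_log2fc` in both
#' resistant conditions (a baseline elevation); `n_up`/`n_down` genes gain
#' +/- `de_log2fc` in sensitive-treated only. When `down_by_length`,
#' downregulated genes are drawn with probability proportional to gene
#' length, emulating the higher adduct load of long genes.
#'
#' @param config A [sim_config()].
#' @param genes Optional gene `GRanges` (for lengths and ids); if `NULL`,
#'   generic genes of log-normal length are invented.
#' @param seed Stream seed (default `config$seed + 2`).
#' @return List with `counts` (integer matrix genes x samples), `meta`
#'   (sample metadata data.frame), `gene_lengths`, and `truth` (baseline
#'   expression, planted id sets, true size factors, effect matrix).
#' @export
simulate_rnaseq_counts <- function(config, genes = NULL,
                                   seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_genes
  if (!is.null(genes)) {
    n <- length(genes)
    ids <- mcols(genes)$gene_id
    lens <- GenomicRanges::width(genes)
  } else {
    ids <- sprintf("gene_%04d", seq_len(n))
    lens <- pmax(200, round(stats::rlnorm(n, config$gene_meanlog,
                                          config$gene_sdlog)))
  }
  q <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)

  pool <- seq_len(n)
  primed <- sort(sample(pool, config$n_primed))
  pool <- setdiff(pool, primed)
  up <- sort(sample(pool, min(config$n_up, length(pool))))
  pool <- setdiff(pool, up)
  wdown <- if (config$down_by_length) lens[pool] else rep(1, length(pool))
  down <- sort(pool[sample.int(length(pool), min(config$n_down, length(pool)),
                               prob = wdown)])

  conds <- c("sensitive_control", "sensitive_cisplatin",
             "resistant_control", "resistant_cisplatin")
  E <- matrix(1, n, 4, dimnames = list(ids, conds))
  E[primed, "sensitive_cisplatin"] <- 2^config$treatment_log2fc
  E[primed, "resistant_control"] <- 2^config$primed_log2fc
  E[primed, "resistant_cisplatin"] <- 2^config$primed_log2fc
  E[up, "sensitive_cisplatin"] <- E[up, "sensitive_cisplatin"] *
    2^config$de_log2fc
  E[down, "sensitive_cisplatin"] <- E[down, "sensitive_cisplatin"] *
    2^(-config$de_log2fc)

  r <- config$n_replicates
  meta <- data.frame(
    sample = paste(rep(conds, each = r), rep(seq_len(r), 4), sep = "_r"),
    cell_line = rep(rep(c("sensitive", "resistant"), each = 2 * r)),
    treatment = rep(rep(c("control", "cisplatin"), each = r), 2),
    condition = rep(conds, each = r),
    replicate = rep(seq_len(r), 4),
    stringsAsFactors = FALSE)
  sf <- stats::rlnorm(nrow(meta), 0, config$lib_sdlog)
  mu <- sapply(seq_len(nrow(meta)), function(j)
    sf[j] * q * E[, meta$condition[j]])
  counts <- if (config$dispersion == 0) {
    matrix(stats::rpois(length(mu), mu), n)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion), n)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(ids, meta$sample)
  list(counts = counts, meta = meta, gene_lengths = stats::setNames(lens, ids),
       truth = list(expression = stats::setNames(q, ids),
                    primed_ids = ids[primed], up_ids = ids[up],
                    down_ids = ids[down], size_factors = sf, effects = E))
}

#' Simulate replicate ATAC-seq peak sets and fragments
#'
#' True peaks of width `peak_width` are placed non-overlapping and interior
#' to the genome. Each replicate reports each true peak with probability
#' `p_detect`, with start/end jittered by round(N(0, jitter_sd)), plus
#' Poisson(`n_false_peaks`) false peaks. A pooled call is simulated the same
#' way with `p_detect = 1`. Each true peak carries a log-normal
#' `accessibility` weight with mean `atac_enrichment`; fragments are placed
#' proportionally to it (weight 1 outside peaks).
#'
#' @param genome A [genome_spec()].
#' @param config A [sim_config()].
#' @param true_peaks Optional `GRanges` of true peaks to reuse (so two
#'   conditions can share most of their peaks).
#' @param seed_offset Stream offset, default 3.
#' @return List with `true_peaks`, `replicates` (list of `GRanges`),
#'   `pooled`, and `fragments`.
#' @export
simulate_atac_replicates <- function(genome, config, true_peaks = NULL,
                                     seed_offset = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_atac_replicates < 2)
    stop("config error: need >= 2 ATAC replicates")
  set.seed(config$seed + seed_offset)
  w <- as.integer(config$peak_width)
  margin <- 3100L
  if (is.null(true_peaks)) {
    # peaks are kept >= 3 kb apart so profile flanks are background, the
    # typical geometry of merged reproducible ATAC peaks
    placed <- place_nonoverlapping(genome, rep(w, config$n_peaks), margin,
                                   what = sprintf("%d peaks", config$n_peaks),
                                   spacing = 3000)
    true_peaks <- GenomicRanges::sort(GenomicRanges::GRanges(
      placed$chrom, IRanges::IRanges(placed$start, width = w)),
      ignore.strand = TRUE)
    # heterogeneous true accessibility per peak, mean atac_enrichment
    mcols(true_peaks)$accessibility <- config$atac_enrichment *
      stats::rlnorm(length(true_peaks), -config$access_sdlog^2 / 2,
                    config$access_sdlog)
  }
  jitter_peaks <- function(pk, p_detect) {
    keep <- stats::runif(length(pk)) < p_detect
    pk <- pk[keep]
    if (config$jitter_sd > 0 && length(pk) > 0) {
      ds <- round(stats::rnorm(length(pk), 0, config$jitter_sd))
      de <- round(stats::rnorm(length(pk), 0, config$jitter_sd))
      s <- pmax(1, GenomicRanges::start(pk) + ds)
      e <- pmin(chrom_length(genome, GenomicRanges::seqnames(pk)),
                GenomicRanges::end(pk) + de)
      bad <- e <= s
      s[bad] <- GenomicRanges::start(pk)[bad]; e[bad] <- GenomicRanges::end(pk)[bad]
      GenomicRanges::ranges(pk) <- IRanges::IRanges(s, e)
    }
    pk
  }
  false_peaks <- function() {
    k <- stats::rpois(1, config$n_false_peaks)
    if (k == 0) return(GenomicRanges::GRanges())
    pos <- sample_weighted_positions(genome, NULL, k)
    s <- pmax(1, pos$pos - w %/% 2L)
    e <- pmin(chrom_length(genome, pos$chrom), s + w - 1L)
    GenomicRanges::GRanges(pos$chrom, IRanges::IRanges(s, e))
  }
  replicates <- lapply(seq_len(config$n_atac_replicates), function(r)
    GenomicRanges::sort(suppressWarnings(
      c(jitter_peaks(true_peaks, config$p_detect), false_peaks())),
      ignore.strand = TRUE))
  pooled <- GenomicRanges::sort(jitter_peaks(true_peaks, 1),
                                ignore.strand = TRUE)
  fl <- as.integer(config$fragment_length)
  pos <- sample_weighted_positions(genome, true_peaks,
                                   as.integer(config$n_fragments),
                                   config$atac_enrichment)
  fs <- pmin(pmax(pos$pos, 1), chrom_length(genome, pos$chrom) - fl + 1)
  fragments <- GenomicRanges::GRanges(pos$chrom,
                                      IRanges::IRanges(fs, width = fl))
  list(true_peaks = true_peaks, replicates = replicates, pooled = pooled,
       fragments = fragments)
}
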