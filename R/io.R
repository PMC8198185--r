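# File formats: BED3/BED6, bedGraph, FASTA, TSV count/metadata tables, and a
# flat key-value config format. Readers validate line by line and name the
# offending line in their error messages; writers accept optional "# " header
# comment lines (tool version / seed / config hash provenance).

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

is_comment <- function(lines) {
  grepl("^#", lines) | grepl("^track($|[ \t])", lines) | lines == ""
}

#' Read a BED3/BED6 file into a GRanges
#'
#' Accepts 3- to 6-column tab-separated BED; `.` strand maps to `*`.
#' Comment (`#`), `track`, and blank lines are skipped. Malformed lines are
#' reported with their line number.
#'
#' @param path Path to a BED file.
#' @return `GRanges` with `name` and `score` metadata columns.
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  keep <- !is_comment(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("parse error: line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 BED fields")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  chrom <- get(1, NA)
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop("parse error: line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start < 0 | end <= start)
  if (length(bad))
    stop("parse error: line ", lineno[bad[1]],
         ": invalid interval (need 0 <= start < end)")
  name <- get(4, ".")
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[!is.finite(score)] <- 0
  strand <- get(6, ".")
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad))
    stop("parse error: line ", lineno[bad[1]], ": unknown strand symbol '",
         strand[bad[1]], "'")
  bed_ranges(chrom, start, end, strand, name, score)
}

#' Write a GRanges as BED6
#'
#' @param gr `GRanges`; `name`/`score` metadata used when present.
#' @param path Output path.
#' @param header Optional character vector of `# ` comment lines.
#' @export
write_bed <- function(gr, path, header = NULL) {
  name <- mcols(gr)$name %||% rep(".", length(gr))
  score <- mcols(gr)$score %||% rep(0, length(gr))
  strand <- strand_chr(gr)
  strand[strand == "*"] <- "."
  body <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                  as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                  as.character(name), format(score, trim = TRUE, digits = 10),
                  strand)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a windowed signal track as bedGraph
#'
#' @param gr `GRanges` with a numeric `score` column.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_bedgraph <- function(gr, path, header = NULL) {
  if (is.null(mcols(gr)$score)) stop("bedGraph requires a score column")
  body <- sprintf("%s\t%d\t%d\t%s",
                  as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                  format(mcols(gr)$score, trim = TRUE, digits = 10))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a 4-column bedGraph file.
#' @return `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) {
  lines <- read_text_lines(path)
  keep <- !is_comment(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4))
    stop("parse error: line ", lineno[which(lengths(fields) != 4)[1]],
         ": bedGraph needs exactly 4 fields")
  m <- do.call(rbind, fields)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  score <- as.numeric(m[, 4])
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(score) |
                 start < 0 | end <= start)
  if (length(bad))
    stop("parse error: line ", lineno[bad[1]], ": invalid bedGraph record")
  gr <- bed_ranges(m[, 1], start, end)
  mcols(gr)$name <- NULL
  mcols(gr)$score <- score
  gr
}

#' Write a gene table as BED6 (gene_id in the name field)
#' @param genes Gene `GRanges` with a `gene_id` column.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_genes_bed <- function(genes, path, header = NULL) {
  validate_genes(genes)
  out <- genes
  mcols(out)$name <- mcols(genes)$gene_id
  mcols(out)$score <- 0
  write_bed(out, path, header)
}

#' Read a BED6 gene table (name field = gene id)
#' @param path Path to a BED6 file; strand must be `+`/`-`.
#' @return Gene `GRanges` with `gene_id`.
#' @export
read_genes_bed <- function(path) {
  gr <- read_bed(path)
  mcols(gr)$gene_id <- mcols(gr)$name
  mcols(gr)$name <- NULL
  mcols(gr)$score <- NULL
  validate_genes(gr)
  gr
}

#' Write / read a count matrix TSV
#'
#' Genes as rows (first column `gene_id`), samples as columns.
#' @param counts Integer matrix with gene row names and sample column names.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_counts <- function(counts, path, header = NULL) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @return `read_counts`: an integer matrix.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(m != round(m)) || any(m < 0))
    stop("parse error: counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write / read a TSV table with optional header comments
#' @param df A data.frame.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write a flat key-value configuration file
#'
#' One `key<TAB>value` (or `key = value`) pair per line; `#` comments
#' allowed. Values that parse as numbers are returned numeric.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!is_comment(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(sub("=", "\t", lines[i], fixed = TRUE), "\t")[[1]]
    parts <- trimws(parts)
    parts <- parts[parts != ""]
    if (length(parts) != 2)
      stop("parse error: config line ", i, ": expected key value pair")
    val <- suppressWarnings(as.numeric(parts[2]))
    out[[parts[1]]] <- if (is.finite(val)) val else parts[2]
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @param header Optional comment lines.
#' @export
write_config <- function(config, path, header = NULL) {
  body <- vapply(names(config), function(k)
    paste(k, format(config[[k]], trim = TRUE, digits = 12), sep = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}
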