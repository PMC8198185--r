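#' Construct a genome specification
#'
#' A genome specification is a named numeric vector mapping chromosome name
#' to length in bp. It bounds all window/slop arithmetic.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp).
#' @return A validated named numeric vector of class `genome_spec`.
#' @examples
#' genome_spec(c(chr1 = 1e5, chr2 = 5e4))
#' @export
genome_spec <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("genome_spec: all chromosomes must be named")
  if (anyDuplicated(names(lengths)))
    stop("genome_spec: duplicated chromosome names")
  nm <- names(lengths)
  lengths <- as.numeric(round(lengths))
  names(lengths) <- nm
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("genome_spec: chromosome lengths must be positive")
  structure(lengths, class = "genome_spec")
}

chrom_length <- function(genome, chrom) {
  idx <- match(as.character(chrom), names(genome))
  if (anyNA(idx))
    stop("unknown chromosome(s): ",
         paste(unique(as.character(chrom)[is.na(idx)]), collapse = ", "))
  unname(as.numeric(genome)[idx])
}
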