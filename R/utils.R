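#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

# Cheap deterministic fingerprint of a character vector (config provenance in
# output headers). Not cryptographic.
rp_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

rp_version <- function() {
  as.character(utils::packageVersion("repairprime"))
}

# Standard header comment lines for output files.
rp_header <- function(seed = NA, config_hash = NA) {
  c(sprintf("# repairprime %s", rp_version()),
    sprintf("# seed=%s config=%s", as.character(seed), as.character(config_hash)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flip "+"/"-"; "*" stays "*".
flip_strand <- function(s) chartr("+-", "-+", s)
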