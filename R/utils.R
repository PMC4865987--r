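# Shared low-level helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the run's
#' master seed so that stages can be re-run in isolation and the whole run
#' stays bit-reproducible. Kept strictly below 2^31.
#'
#' @param seed master integer seed (non-negative)
#' @param stage small integer stage code (0-99)
#' @param index within-stage index (0-999), e.g. a sample number
#' @return an integer seed
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), seed >= 0, stage >= 0, stage < 100,
            index >= 0, index < 1000)
  as.integer(((seed %% 20000) * 100000 + stage * 1000 + index) %% 2147483647)
}

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector of DNA strings
#' @return character vector
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s) at a given GC content; vectorised over `n`.
random_dna <- function(lengths, gc = 0.41) {
  at <- (1 - gc) / 2
  probs <- c(at, gc / 2, gc / 2, at)
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

# GC fraction of character sequences.
gc_fraction <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x), "GC")
  as.numeric(f) / nchar(x)
}

# 1-based inclusive substring of a single long reference string.
ref_substr <- function(chrom_seq, start, end) {
  if (start < 1 || end < start || end > nchar(chrom_seq))
    stop("substring outside chromosome bounds", call. = FALSE)
  substr(chrom_seq, start, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_parse <- function(line, msg) {
  stop(sprintf("parse error at line %d: %s", line, msg), call. = FALSE)
}
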