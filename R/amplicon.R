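# Amplicon table model and I/O.
#
# One row per primer pair's product: amplicon_id, chrom, start, end
# (0-based half-open product interval), fwd_primer, rev_primer, length,
# gc_fraction, target_ids (comma-joined; a junction amplicon carries its
# rearrangement mutation_id), is_junction, is_length_outlier.
# Primers are prefixes of the two product strands. Junction amplicons
# amplify only the mutant chimeric haplotype; their interval records the
# left-breakpoint locus.

AMPLICON_COLS <- c("amplicon_id", "chrom", "start", "end", "fwd_primer",
                   "rev_primer", "length", "gc_fraction", "target_ids",
                   "is_junction", "is_length_outlier")

STD_AMPLICON_RANGE <- c(64L, 200L)

validate_amplicons <- function(amp) {
  stopifnot(all(AMPLICON_COLS %in% names(amp)))
  if (anyDuplicated(amp$amplicon_id))
    stop("duplicate amplicon ids", call. = FALSE)
  if (any(amp$end <= amp$start)) stop("empty amplicon interval")
  if (any(amp$length != amp$end - amp$start))
    stop("amplicon length must equal end - start")
  bad <- !amp$is_length_outlier &
    (amp$length < STD_AMPLICON_RANGE[1] | amp$length > STD_AMPLICON_RANGE[2])
  if (any(bad))
    stop("amplicon length outside [64,200] without is_length_outlier: ",
         paste(amp$amplicon_id[bad], collapse = ","))
  invisible(amp)
}

#' Load an amplicon table from TSV
#' @param path path to amplicon TSV written by [write_amplicons()]
#' @return data.frame with one row per amplicon
#' @export
load_amplicons <- function(path) {
  amp <- read.delim(path, comment.char = "", stringsAsFactors = FALSE)
  names(amp)[1] <- sub("^X\\.", "", names(amp)[1])
  amp$is_junction <- as.logical(amp$is_junction)
  amp$is_length_outlier <- as.logical(amp$is_length_outlier)
  validate_amplicons(amp)
  amp
}

#' Write an amplicon table to TSV
#' @param amplicons amplicon data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_amplicons <- function(amplicons, path) {
  validate_amplicons(amplicons)
  write.table(amplicons[, AMPLICON_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Split the comma-joined target_ids column into a list.
amplicon_target_list <- function(amplicons) {
  strsplit(amplicons$target_ids, ",", fixed = TRUE)
}

# Reference-strand product sequence of a standard amplicon.
amplicon_ref_product <- function(amp_row, reference) {
  chrom_seq <- reference_chrom(reference, amp_row$chrom)
  ref_substr(chrom_seq, amp_row$start + 1L, amp_row$end)
}
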