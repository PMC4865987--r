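# Mutation panel model and I/O.
#
# A panel is a data.frame (class "mutation_panel") with one row per mutation:
#   mutation_id, gene, disorder, chrom, pos (1-based anchor), ref, alt,
#   class in {SNV, INS, DEL, LARGE_REARRANGEMENT}, breakpoint1, breakpoint2,
#   inserted_seq, label.
# SNV/INS/DEL use VCF-style anchor-base alleles; large rearrangements carry
# breakpoints (deletion: deleted interval; insertion: insertion point twice)
# and an optional inserted sequence, with empty ref/alt.

MUT_CLASSES <- c("SNV", "INS", "DEL", "LARGE_REARRANGEMENT")

PANEL_COLS <- c("mutation_id", "gene", "disorder", "chrom", "pos", "ref",
                "alt", "class", "breakpoint1", "breakpoint2", "inserted_seq",
                "label")

valid_alleles <- function(x) grepl("^[ACGT]+$", x)

# Validate one parsed panel row; returns NULL or an error message.
check_panel_row <- function(row) {
  if (is.na(row$pos) || row$pos < 1) return("pos must be a positive integer")
  if (!row$class %in% MUT_CLASSES)
    return(sprintf("unknown mutation class '%s'", row$class))
  if (row$class == "LARGE_REARRANGEMENT") {
    if (nzchar(row$ref) || nzchar(row$alt))
      return("rearrangement rows must have empty ref/alt alleles")
    if (is.na(row$breakpoint1) || is.na(row$breakpoint2) ||
        row$breakpoint1 < 1 || row$breakpoint2 < row$breakpoint1)
      return("rearrangement needs ordered 1-based breakpoints")
    if (nzchar(row$inserted_seq) && !valid_alleles(row$inserted_seq))
      return("inserted_seq contains non-ACGT characters")
    return(NULL)
  }
  if (!valid_alleles(row$ref) || !valid_alleles(row$alt))
    return("ref/alt alleles must be non-empty uppercase ACGT strings")
  if (row$class == "SNV") {
    if (nchar(row$ref) != 1L || nchar(row$alt) != 1L)
      return("SNV alleles must be single bases")
    if (row$ref == row$alt) return("SNV with ref == alt")
  }
  if (row$class == "INS" &&
      !(nchar(row$alt) > nchar(row$ref) && nchar(row$ref) == 1L))
    return("INS must have single-base ref anchor and longer alt")
  if (row$class == "DEL" &&
      !(nchar(row$ref) > nchar(row$alt) && nchar(row$alt) == 1L))
    return("DEL must have single-base alt anchor and longer ref")
  if (row$class %in% c("INS", "DEL") &&
      substr(row$ref, 1, 1) != substr(row$alt, 1, 1))
    return("indel ref and alt must share the anchor base")
  NULL
}

new_mutation_panel <- function(df, version = "0", provenance = "") {
  rownames(df) <- NULL
  structure(df, class = c("mutation_panel", "data.frame"),
            version = version, provenance = provenance)
}

#' Load a mutation panel from a TSV file
#'
#' The file is tab-separated with a leading `#`-prefixed header line naming
#' the columns `mutation_id, gene, disorder, chrom, pos, ref, alt, class,
#' breakpoint1, breakpoint2, inserted_seq, label`. Row order is preserved.
#' Malformed rows, duplicate mutation ids, invalid allele strings and
#' SNVs with identical alleles raise an error naming the offending line.
#'
#' @param path path to the panel TSV
#' @return a `mutation_panel` data.frame, one row per mutation
#' @seealso [write_panel()], [collapse_targets()]
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "#"))
    abort_parse(1, "missing '#'-prefixed header line")
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (!identical(header, PANEL_COLS))
    abort_parse(1, paste("unexpected columns:", paste(header, collapse = ",")))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    warning("panel file contains no mutations", call. = FALSE)
    df <- as.data.frame(setNames(
      c(list(character(0)), list(character(0)), list(character(0)),
        list(character(0)), list(integer(0)), list(character(0)),
        list(character(0)), list(character(0)), list(integer(0)),
        list(integer(0)), list(character(0)), list(character(0))),
      PANEL_COLS), stringsAsFactors = FALSE)
    return(new_mutation_panel(df))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  rows <- vector("list", length(body))
  ids <- character(length(body))
  for (i in seq_along(body)) {
    line_no <- i + 1L
    f <- fields[[i]]
    if (length(f) != length(PANEL_COLS))
      abort_parse(line_no, sprintf("expected %d tab-separated fields, got %d",
                                   length(PANEL_COLS), length(f)))
    row <- list(
      mutation_id = f[1], gene = f[2], disorder = f[3], chrom = f[4],
      pos = suppressWarnings(as.integer(f[5])), ref = f[6], alt = f[7],
      class = f[8],
      breakpoint1 = suppressWarnings(as.integer(f[9])),
      breakpoint2 = suppressWarnings(as.integer(f[10])),
      inserted_seq = f[11], label = f[12])
    msg <- check_panel_row(row)
    if (!is.null(msg)) abort_parse(line_no, msg)
    if (row$mutation_id %in% ids[seq_len(i - 1L)])
      abort_parse(line_no, paste("duplicate mutation_id", row$mutation_id))
    ids[i] <- row$mutation_id
    rows[[i]] <- row
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  new_mutation_panel(df)
}

#' Write a mutation panel to a TSV file
#'
#' Inverse of [load_panel()]; the round trip preserves all fields.
#'
#' @param panel a `mutation_panel`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, PANEL_COLS]
  df$breakpoint1[is.na(df$breakpoint1)] <- ""
  df$breakpoint2[is.na(df$breakpoint2)] <- ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(PANEL_COLS, collapse = "\t")), con)
  if (nrow(df) > 0)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' @export
print.mutation_panel <- function(x, ...) {
  cls <- table(factor(x$class, levels = MUT_CLASSES))
  cat(sprintf(
    "mutation panel: %d mutations in %d genes (%d disorders)\n",
    nrow(x), length(unique(x$gene)), length(unique(x$disorder))))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "),
      "\n")
  invisible(x)
}

#' Collapse panel mutations into unique genomic target positions
#'
#' Distinct alternative alleles at the same genomic nucleotide (multi-allelic
#' sites) are counted as a single target position, so a panel can have fewer
#' targets than mutations. Large rearrangements are skipped: they are probed
#' through junction references, not positional pileups.
#'
#' @param panel a `mutation_panel`
#' @return data.frame with columns `target_id`, `chrom`, `pos`,
#'   `mutation_ids` (list column) and `n_mutations`, ordered by first
#'   appearance in the panel
#' @export
collapse_targets <- function(panel) {
  small <- panel[panel$class != "LARGE_REARRANGEMENT", , drop = FALSE]
  if (nrow(small) == 0L)
    return(data.frame(target_id = character(0), chrom = character(0),
                      pos = integer(0), n_mutations = integer(0)))
  key <- paste(small$chrom, small$pos, sep = ":")
  first <- !duplicated(key)
  ord_keys <- key[first]
  ids <- split(small$mutation_id, factor(key, levels = ord_keys))
  out <- data.frame(
    target_id = sprintf("T%04d", seq_along(ord_keys)),
    chrom = small$chrom[first],
    pos = small$pos[first],
    n_mutations = lengths(ids),
    stringsAsFactors = FALSE)
  out$mutation_ids <- unname(ids)
  out
}

#' Build a chimeric junction reference for a large rearrangement
#'
#' For a deletion of the interval `[b1, b2]` the junction sequence is the
#' `flank_len` bases ending at `b1 - 1` followed by the `flank_len` bases
#' starting at `b2 + 1`. For an insertion at point `b1` it is the flank
#' ending at `b1`, the inserted sequence, then the flank starting at
#' `b1 + 1`. The `core_kmer` straddles the (left) junction with
#' `min_anchor` bases on each side and is checked, on both strands, to be
#' absent from the unmutated reference: it can only occur in reads from a
#' carrier haplotype.
#'
#' @param mut single-row slice of a `mutation_panel` with class
#'   `LARGE_REARRANGEMENT`
#' @param reference a named `DNAStringSet` genome (or list of character
#'   chromosome strings)
#' @param flank_len flank length in bp on each side of the junction
#' @param min_anchor minimum bases of the core k-mer on each side of the
#'   junction
#' @return a list of class `junction_reference` with elements
#'   `mutation_id`, `sequence`, `flank_len`, `core_kmer`
#' @export
build_junction_reference <- function(mut, reference, flank_len = 60L,
                                     min_anchor = 20L) {
  if (nrow(as.data.frame(mut)) != 1L)
    stop("build_junction_reference expects a single panel row")
  mut <- as.list(as.data.frame(mut))
  if (mut$class != "LARGE_REARRANGEMENT")
    stop("junction references are only defined for LARGE_REARRANGEMENT ",
         "mutations")
  chrom_seq <- reference_chrom(reference, mut$chrom)
  b1 <- mut$breakpoint1; b2 <- mut$breakpoint2
  ins <- if (is.na(mut$inserted_seq) || !nzchar(mut$inserted_seq)) ""
         else mut$inserted_seq
  is_insertion <- (b1 == b2)
  if (is_insertion && !nzchar(ins))
    stop("insertion rearrangement without inserted_seq")
  if (b1 - flank_len < 1)
    stop("flank does not fit within the chromosome")
  if (is_insertion) {
    if (b1 + flank_len > nchar(chrom_seq))
      stop("flank does not fit within the chromosome")
    left <- ref_substr(chrom_seq, b1 - flank_len + 1L, b1)
    right <- ref_substr(chrom_seq, b1 + 1L, b1 + flank_len)
    sequence <- paste0(left, ins, right)
  } else {
    if (b2 + flank_len > nchar(chrom_seq))
      stop("flank does not fit within the chromosome")
    left <- ref_substr(chrom_seq, b1 - flank_len, b1 - 1L)
    right <- ref_substr(chrom_seq, b2 + 1L, b2 + flank_len)
    sequence <- paste0(left, ins, right)
  }
  # core k-mer straddles the left junction (flank end -> inserted/right start)
  if (flank_len < min_anchor)
    stop("flank_len must be at least min_anchor")
  core <- substr(sequence, flank_len - min_anchor + 1L,
                 flank_len + min_anchor)
  if (junction_kmer_hits(core, reference) > 0L)
    stop("ambiguous junction: core_kmer occurs in the unmutated reference")
  structure(list(mutation_id = mut$mutation_id, sequence = sequence,
                 flank_len = as.integer(flank_len), core_kmer = core),
            class = "junction_reference")
}

# Count occurrences of a k-mer in the reference genome, both strands.
junction_kmer_hits <- function(kmer, reference) {
  genome <- as_dnastringset(reference)
  fwd <- sum(Biostrings::vcountPattern(kmer, genome))
  rev <- sum(Biostrings::vcountPattern(revcomp(kmer), genome))
  fwd + rev
}

# Accept DNAStringSet or named character list/vector genomes.
as_dnastringset <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  Biostrings::DNAStringSet(unlist(reference))
}

reference_chrom <- function(reference, chrom) {
  if (methods::is(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference))
      stop("chromosome not in reference: ", chrom)
    return(as.character(reference[[chrom]]))
  }
  if (!chrom %in% names(reference))
    stop("chromosome not in reference: ", chrom)
  as.character(reference[[chrom]])
}

#' Write target positions as a BED file
#'
#' Emits 6-column BED (0-based half-open intervals of width 1) with the
#' target id in the name column, the member-mutation count as score, and
#' `.` strand.
#'
#' @param targets data.frame from [collapse_targets()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_targets_bed <- function(targets, path) {
  if (nrow(targets) == 0L) stop("no targets to write", call. = FALSE)
  bed <- data.frame(chrom = targets$chrom,
                    start = targets$pos - 1L,
                    end = targets$pos,
                    name = targets$target_id,
                    score = targets$n_mutations,
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
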