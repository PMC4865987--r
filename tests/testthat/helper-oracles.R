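# Independent brute-force oracles. These deliberately re-derive results
# by the most direct method available (exhaustive enumeration, full-string
# editing, naive pairwise checks) and never call the code paths they
# check.

# Distinct (chrom, pos) count among non-rearrangement mutations.
oracle_target_count <- function(panel) {
  small <- panel[panel$class != "LARGE_REARRANGEMENT", ]
  length(unique(paste(small$chrom, small$pos)))
}

# Junction sequence by editing the full chromosome string and cutting a
# window around the junction.
oracle_junction_seq <- function(mut, chrom_seq, flank_len) {
  b1 <- mut$breakpoint1; b2 <- mut$breakpoint2
  if (b1 == b2 && nzchar(mut$inserted_seq)) {
    mutant <- paste0(substr(chrom_seq, 1, b1), mut$inserted_seq,
                     substr(chrom_seq, b1 + 1, nchar(chrom_seq)))
    substr(mutant, b1 - flank_len + 1,
           b1 + nchar(mut$inserted_seq) + flank_len)
  } else {
    mutant <- paste0(substr(chrom_seq, 1, b1 - 1),
                     substr(chrom_seq, b2 + 1, nchar(chrom_seq)))
    substr(mutant, b1 - flank_len, b1 - 1 + flank_len)
  }
}

# Exhaustive pairwise + aggregate constraint count over a pooling plan.
oracle_pool_violations <- function(plan, amps, params) {
  n_bad <- 0L
  for (ids in plan$pools) {
    rows <- amps[match(ids, amps$amplicon_id), , drop = FALSE]
    if (nrow(rows) > params$max_pool_size) n_bad <- n_bad + 1L
    if (nrow(rows) >= 1) {
      mean_len <- mean(rows$length)
      n_bad <- n_bad + sum(abs(rows$length - mean_len) >
                             params$size_tolerance * mean_len)
      if ((max(rows$gc_fraction) - min(rows$gc_fraction)) * 100 >
            params$gc_span_max)
        n_bad <- n_bad + 1L
    }
    if (nrow(rows) > 1) {
      for (i in 1:(nrow(rows) - 1)) {
        for (j in (i + 1):nrow(rows)) {
          if (rows$chrom[i] != rows$chrom[j]) next
          gap <- max(rows$start[i], rows$start[j]) -
            min(rows$end[i], rows$end[j])
          if (gap < params$min_gap_bp) n_bad <- n_bad + 1L
        }
      }
    }
  }
  n_bad
}

# Exhaustive minimum number of feasible pools (set-partition search).
oracle_min_pools <- function(amps, params) {
  n <- nrow(amps)
  feasible <- function(rows) {
    if (nrow(rows) > params$max_pool_size) return(FALSE)
    mean_len <- mean(rows$length)
    if (any(abs(rows$length - mean_len) >
              params$size_tolerance * mean_len)) return(FALSE)
    if ((max(rows$gc_fraction) - min(rows$gc_fraction)) * 100 >
          params$gc_span_max) return(FALSE)
    if (nrow(rows) > 1) {
      for (i in 1:(nrow(rows) - 1)) for (j in (i + 1):nrow(rows)) {
        if (rows$chrom[i] != rows$chrom[j]) next
        gap <- max(rows$start[i], rows$start[j]) -
          min(rows$end[i], rows$end[j])
        if (gap < params$min_gap_bp) return(FALSE)
      }
    }
    TRUE
  }
  best <- n
  recurse <- function(i, groups) {
    if (length(groups) >= best) return()
    if (i > n) { best <<- min(best, length(groups)); return() }
    for (g in seq_along(groups)) {
      cand <- c(groups[[g]], i)
      if (feasible(amps[cand, , drop = FALSE])) {
        groups[[g]] <- cand
        recurse(i + 1, groups)
        groups[[g]] <- groups[[g]][-length(groups[[g]])]
      }
    }
    recurse(i + 1, c(groups, list(i)))
  }
  recurse(1L, list())
  best
}

# Haplotype string-match vote oracle: spanning mates are matched, as full
# strings (either orientation), against the complete reference and
# alternative amplicon products.
oracle_haplotype_votes <- function(r1, r2, assign, amp_row, ref_product,
                                   alt_product, target_pos,
                                   read_len = 150L) {
  sel <- which(assign$amplicon_id == amp_row$amplicon_id)
  o <- target_pos - 1L - amp_row$start
  L <- amp_row$length
  counts <- c(ref = 0L, alt = 0L, other = 0L)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  for (k in sel) {
    fwd <- if (assign$fwd_read[k] == 1L) r1[k] else r2[k]
    rev <- if (assign$fwd_read[k] == 1L) r2[k] else r1[k]
    for (mate in c("fwd", "rev")) {
      spans <- if (mate == "fwd")
        o >= 15L && (o + 27L) <= min(read_len, L) - 1L
      else (o - 27L) >= max(0L, L - read_len) && (o + 15L) <= L - 1L
      if (!spans) next
      read <- if (mate == "fwd") fwd else rev
      hits_ref <- grepl(read, ref_product, fixed = TRUE) ||
        grepl(rc(read), ref_product, fixed = TRUE)
      hits_alt <- grepl(read, alt_product, fixed = TRUE) ||
        grepl(rc(read), alt_product, fixed = TRUE)
      if (hits_ref && !hits_alt) counts["ref"] <- counts["ref"] + 1L
      else if (hits_alt && !hits_ref) counts["alt"] <- counts["alt"] + 1L
      else counts["other"] <- counts["other"] + 1L
    }
  }
  counts
}
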