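# Genotyping: primer-anchored read assignment, haplotype-vote pileups,
# threshold calling, and junction-based rearrangement detection.
#
# Read pairs are assigned to amplicons by their primer prefixes (at most
# one mismatch), replacing genome alignment for a panel-anchored assay.
# Each target is genotyped by exact-context voting: a read spanning the
# target window votes for the reference or an alternative haplotype
# context (the window with the allele applied), indels included through
# the same mechanism over the adjacent interval.

#' Genotype-calling thresholds
#'
#' Heterozygotes require a depth of at least `min_dp` and a mutant allele
#' fraction between `het_af_low` and `het_af_high` (bounds inclusive).
#' `hom_af_min` and `suspect_af_low` are this toolkit's configurable
#' additions: fractions at or above `hom_af_min` call homozygous, and
#' fractions in `[suspect_af_low, het_af_low)` are reported REF with a
#' `LOW_AF_SUSPECT` flag (the paralog-dilution signature); fractions in
#' `(het_af_high, hom_af_min)` are reported REF with `AF_BAND_GAP`.
#'
#' @param min_dp minimum informative depth for any call
#' @param het_af_low,het_af_high inclusive heterozygote AF band
#' @param hom_af_min minimum AF for a homozygous call
#' @param suspect_af_low lower edge of the suspicious sub-het band
#' @param min_junction_support reads containing the junction k-mer needed
#'   to call a rearrangement carrier
#' @return list of class `call_thresholds`
#' @export
call_thresholds <- function(min_dp = 50L, het_af_low = 0.30,
                            het_af_high = 0.70, hom_af_min = 0.85,
                            suspect_af_low = 0.15,
                            min_junction_support = 10L) {
  stopifnot(0 < suspect_af_low, suspect_af_low < het_af_low,
            het_af_low < het_af_high, het_af_high < hom_af_min,
            hom_af_min <= 1, min_dp > 0, min_junction_support > 0)
  structure(list(min_dp = as.integer(min_dp), het_af_low = het_af_low,
                 het_af_high = het_af_high, hom_af_min = hom_af_min,
                 suspect_af_low = suspect_af_low,
                 min_junction_support = as.integer(min_junction_support)),
            class = "call_thresholds")
}

#' Read a gzipped FASTQ pair into memory
#' @param r1_path,r2_path FASTQ(.gz) paths
#' @return list with named character vectors `r1`, `r2`
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    out <- as.character(x)
    names(out) <- sub("/[12]$", "", names(x))
    out
  }
  r1 <- rd(r1_path); r2 <- rd(r2_path)
  if (length(r1) != length(r2))
    stop("FASTQ mates differ in read count", call. = FALSE)
  list(r1 = r1, r2 = r2)
}

#' Assign read pairs to amplicons by primer match
#'
#' A pair is assigned to amplicon A iff R1 or R2 begins with A's forward
#' or reverse primer with at most one mismatch. Pairs matching no primer
#' are `OFF_TARGET` (`NO_PRIMER`); pairs matching primers of two different
#' amplicons are `OFF_TARGET` with reason `AMBIGUOUS`.
#'
#' @param reads list with `r1` and `r2` character vectors (or a
#'   [read_fastq_pair()] result)
#' @param amplicons amplicon data.frame
#' @return data.frame `pair`, `amplicon_id` (or `"OFF_TARGET"`), `reason`
#'   (`ASSIGNED`, `NO_PRIMER`, `AMBIGUOUS`), `fwd_read` (1 or 2: which
#'   mate carries the forward primer and so covers the product start)
#' @export
assign_reads <- function(reads, amplicons) {
  res <- cpp_assign_reads(unname(reads$r1), unname(reads$r2),
                          amplicons$fwd_primer, amplicons$rev_primer)
  amp_id <- ifelse(res$amplicon > 0,
                   amplicons$amplicon_id[pmax(res$amplicon, 1L)],
                   "OFF_TARGET")
  reason <- ifelse(res$amplicon > 0, "ASSIGNED",
                   ifelse(res$amplicon < 0, "AMBIGUOUS", "NO_PRIMER"))
  data.frame(pair = seq_along(amp_id), amplicon_id = amp_id,
             reason = reason, fwd_read = res$fwd_read,
             stringsAsFactors = FALSE)
}

# Precompute per-target voting contexts: the reference window and one
# alternative window per member mutation, each `window` bp of flank around
# the allele.
target_contexts <- function(panel, targets, reference, window = 15L) {
  reference <- as.list(as.character(as_dnastringset(reference)))
  out <- vector("list", nrow(targets))
  names(out) <- targets$target_id
  for (i in seq_len(nrow(targets))) {
    pos <- targets$pos[i]
    chrom_seq <- reference[[targets$chrom[i]]]
    mids <- targets$mutation_ids[[i]]
    pm <- panel[match(mids, panel$mutation_id), , drop = FALSE]
    maxref <- max(nchar(pm$ref))
    ref_ctx <- ref_substr(chrom_seq, pos - window, pos + maxref - 1L + window)
    alt_ctx <- vapply(seq_along(mids), function(k) {
      paste0(ref_substr(chrom_seq, pos - window, pos - 1L),
             pm$alt[k],
             ref_substr(chrom_seq, pos + nchar(pm$ref[k]),
                        pos + nchar(pm$ref[k]) + window - 1L))
    }, character(1))
    out[[i]] <- list(target_id = targets$target_id[i],
                     mutation_ids = mids, ref_ctx = ref_ctx,
                     alt_ctx = alt_ctx)
  }
  out
}

# Which mates span the voting window of a target at product offset `o`
# (0-based) in an amplicon of length L. 12 bp of slack absorbs indel
# allele-length changes and the window flanks.
mate_spans <- function(o, L, read_len, is_fwd_mate) {
  ifelse(is_fwd_mate,
         o >= 15L & (o + 27L) <= pmin(read_len, L) - 1L,
         (o - 27L) >= pmax(0L, L - read_len) & (o + 15L) <= L - 1L)
}

#' Pile up haplotype votes for one target in one sample
#'
#' @param reads list with `r1`, `r2` character vectors
#' @param assign assignment data.frame from [assign_reads()]
#' @param target_row single-row slice of [collapse_targets()] output
#' @param panel `mutation_panel`
#' @param amplicons amplicon data.frame
#' @param reference genome
#' @param sample_id sample name recorded in the result
#' @param window flank bp of the voting context
#' @param read_len read length used for span checks
#' @return data.frame with one row per member mutation: `target_id`,
#'   `sample_id`, `mutation_id`, `DP`, `ref_count`, `alt_count`,
#'   `other_count`, `af`, `uncaptured`
#' @export
pileup_target <- function(reads, assign, target_row, panel, amplicons,
                          reference, sample_id = "sample", window = 15L,
                          read_len = 150L) {
  ctx <- target_contexts(panel, target_row, reference, window)[[1]]
  pileup_target_impl(reads, assign, target_row, ctx, amplicons, sample_id,
                     read_len)
}

pileup_target_impl <- function(reads, assign, target_row, ctx, amplicons,
                               sample_id, read_len) {
  tl <- amplicon_target_list(amplicons)
  cover <- which(vapply(tl, function(t)
    target_row$target_id[1] %in% t, logical(1)) & !amplicons$is_junction)
  mids <- ctx$mutation_ids
  empty <- data.frame(target_id = target_row$target_id[1],
                      sample_id = sample_id, mutation_id = mids,
                      DP = 0L, ref_count = 0L, alt_count = 0L,
                      other_count = 0L, af = NA_real_,
                      uncaptured = length(cover) == 0L,
                      stringsAsFactors = FALSE)
  if (length(cover) == 0L) return(empty)    # structured uncaptured result
  votes_total <- integer(length(mids) + 2L)
  for (ai in cover) {
    sel <- which(assign$amplicon_id == amplicons$amplicon_id[ai])
    if (length(sel) == 0L) next
    o <- target_row$pos[1] - 1L - amplicons$start[ai]
    L <- amplicons$length[ai]
    fwd_is_r1 <- assign$fwd_read[sel] == 1L
    fwd_mate <- ifelse(fwd_is_r1, reads$r1[sel], reads$r2[sel])
    rev_mate <- ifelse(fwd_is_r1, reads$r2[sel], reads$r1[sel])
    mates <- c(fwd_mate, rev_mate)
    spans <- c(rep(mate_spans(o, L, read_len, TRUE), length(sel)),
               rep(mate_spans(o, L, read_len, FALSE), length(sel)))
    votes <- cpp_vote_counts(unname(mates), spans,
                             c(ctx$ref_ctx, ctx$alt_ctx))
    votes_total <- votes_total + votes
  }
  ref_n <- votes_total[1]
  alt_n <- votes_total[1L + seq_along(mids)]
  other_n <- votes_total[length(votes_total)]
  dp <- sum(votes_total)
  data.frame(target_id = target_row$target_id[1], sample_id = sample_id,
             mutation_id = mids, DP = dp, ref_count = ref_n,
             alt_count = alt_n, other_count = other_n,
             af = if (dp > 0) alt_n / dp else NA_real_,
             uncaptured = FALSE, stringsAsFactors = FALSE)
}

# All targets for one sample; contexts and read groupings precomputed once.
pileup_sample <- function(reads, assign, targets, contexts, amplicons,
                          sample_id, read_len = 150L) {
  tl <- amplicon_target_list(amplicons)
  by_amp <- split(seq_len(nrow(assign)), assign$amplicon_id)
  # target -> covering standard amplicon indices
  cover_map <- vector("list", nrow(targets))
  names(cover_map) <- targets$target_id
  for (ai in which(!amplicons$is_junction)) {
    for (t in tl[[ai]]) cover_map[[t]] <- c(cover_map[[t]], ai)
  }
  fwd_is_r1 <- assign$fwd_read == 1L
  fwd_mate <- unname(reads$r2); rev_mate <- unname(reads$r1)
  fwd_mate[fwd_is_r1] <- reads$r1[fwd_is_r1]
  rev_mate[fwd_is_r1] <- reads$r2[fwd_is_r1]
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tid <- targets$target_id[i]
    ctx <- contexts[[tid]]
    mids <- ctx$mutation_ids
    cover <- cover_map[[tid]]
    votes_total <- integer(length(mids) + 2L)
    uncaptured <- is.null(cover)
    if (!uncaptured) {
      for (ai in cover) {
        sel <- by_amp[[amplicons$amplicon_id[ai]]]
        if (is.null(sel)) next
        o <- targets$pos[i] - 1L - amplicons$start[ai]
        L <- amplicons$length[ai]
        mates <- c(fwd_mate[sel], rev_mate[sel])
        spans <- c(rep(mate_spans(o, L, read_len, TRUE), length(sel)),
                   rep(mate_spans(o, L, read_len, FALSE), length(sel)))
        votes_total <- votes_total +
          cpp_vote_counts(unname(mates), spans, c(ctx$ref_ctx, ctx$alt_ctx))
      }
    }
    dp <- sum(votes_total)
    out[[i]] <- data.frame(
      target_id = tid, sample_id = sample_id, mutation_id = mids,
      DP = dp, ref_count = votes_total[1],
      alt_count = votes_total[1L + seq_along(mids)],
      other_count = votes_total[length(votes_total)],
      af = if (dp > 0) votes_total[1L + seq_along(mids)] / dp else NA_real_,
      uncaptured = uncaptured, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Call genotypes from pileups
#'
#' Applies the calling criteria per (target, sample, allele): depth below
#' `min_dp` gives `NO_CALL` with a `LOW_DP` flag; otherwise an allele
#' fraction within the inclusive het band calls `HET`, at or above
#' `hom_af_min` calls `HOM`, within `[suspect_af_low, het_af_low)` gives
#' `REF` flagged `LOW_AF_SUSPECT`, within `(het_af_high, hom_af_min)`
#' gives `REF` flagged `AF_BAND_GAP`, else `REF`. At multi-allelic
#' targets every member allele is called separately. Non-REF calls absent
#' from `expected_known` (a data.frame of `sample_id`, `mutation_id`)
#' are flagged `VALIDATION_REQUIRED`.
#'
#' @param pileups pileup data.frame ([pileup_sample()] rows)
#' @param thresholds a [call_thresholds()] list
#' @param expected_known optional data.frame of expected carrier cells
#' @return calls data.frame: pileup columns plus `genotype` and `flags`
#' @export
call_genotypes <- function(pileups, thresholds = call_thresholds(),
                           expected_known = NULL) {
  dp <- pileups$DP
  af <- ifelse(is.na(pileups$af), 0, pileups$af)
  low_dp <- dp < thresholds$min_dp
  genotype <- rep("REF", nrow(pileups))
  genotype[af >= thresholds$het_af_low & af <= thresholds$het_af_high] <- "HET"
  genotype[af >= thresholds$hom_af_min] <- "HOM"
  genotype[low_dp] <- "NO_CALL"
  flags <- character(nrow(pileups))
  flags[low_dp] <- "LOW_DP"
  suspect <- !low_dp & af >= thresholds$suspect_af_low &
    af < thresholds$het_af_low
  flags[suspect] <- "LOW_AF_SUSPECT"
  band_gap <- !low_dp & af > thresholds$het_af_high &
    af < thresholds$hom_af_min
  flags[band_gap] <- "AF_BAND_GAP"
  calls <- cbind(pileups,
                 data.frame(genotype = genotype, flags = flags,
                            stringsAsFactors = FALSE))
  if (!is.null(expected_known)) {
    known_key <- paste(expected_known$sample_id, expected_known$mutation_id)
    unexpected <- calls$genotype %in% c("HET", "HOM") &
      !(paste(calls$sample_id, calls$mutation_id) %in% known_key)
    calls$flags[unexpected] <- ifelse(
      nzchar(calls$flags[unexpected]),
      paste(calls$flags[unexpected], "VALIDATION_REQUIRED", sep = "|"),
      "VALIDATION_REQUIRED")
  }
  calls
}

#' Call one pileup
#' @param pileup one target's pileup rows
#' @param thresholds a [call_thresholds()] list
#' @return single-target calls data.frame
#' @export
call_genotype <- function(pileup, thresholds = call_thresholds()) {
  call_genotypes(pileup, thresholds)
}

#' Detect a large rearrangement from junction-spanning reads
#'
#' Counts reads containing the junction reference's core k-mer as an
#' exact substring on either strand; the sample is a carrier iff the
#' count reaches `min_support`.
#'
#' @param reads character vector of reads to scan (typically both mates
#'   of the pairs assigned to the junction amplicon)
#' @param junction_ref a [build_junction_reference()] result
#' @param min_support minimum supporting reads
#' @param sample_id sample name recorded in the result
#' @return data.frame `mutation_id`, `sample_id`, `supporting_reads`,
#'   `carrier`
#' @export
detect_junction <- function(reads, junction_ref, min_support = 10L,
                            sample_id = "sample") {
  support <- cpp_count_support(unname(reads), junction_ref$core_kmer)
  data.frame(mutation_id = junction_ref$mutation_id, sample_id = sample_id,
             supporting_reads = support, carrier = support >= min_support,
             stringsAsFactors = FALSE)
}

# One sample end to end: assignment, pileups, junction calls, stats.
genotype_sample <- function(sample_id, reads, panel, amplicons, reference,
                            targets, contexts, junction_refs,
                            thresholds = call_thresholds(),
                            read_len = 150L) {
  assign <- assign_reads(reads, amplicons)
  pil <- pileup_sample(reads, assign, targets, contexts, amplicons,
                       sample_id, read_len)
  jx <- lapply(junction_refs, function(jr) {
    amp_id <- amplicons$amplicon_id[
      amplicons$is_junction & amplicons$target_ids == jr$mutation_id]
    sel <- which(assign$amplicon_id %in% amp_id)
    detect_junction(c(reads$r1[sel], reads$r2[sel]), jr,
                    thresholds$min_junction_support, sample_id)
  })
  jx <- if (length(jx)) do.call(rbind, jx) else NULL
  stats <- data.frame(
    sample_id = sample_id,
    n_pairs = nrow(assign),
    n_assigned = sum(assign$reason == "ASSIGNED"),
    n_ambiguous = sum(assign$reason == "AMBIGUOUS"),
    n_off_target = sum(assign$amplicon_id == "OFF_TARGET"),
    stringsAsFactors = FALSE)
  list(pileups = pil, junction_calls = jx, stats = stats)
}

#' Genotype a cohort of samples
#'
#' Runs assignment, pileups, genotype calling and junction detection for
#' every sample, either from per-sample FASTQ pairs (`fastq` data.frame
#' with `sample_id`, `r1`, `r2` columns) or from in-memory read sets
#' (named list of `list(r1=, r2=)`).
#'
#' @param samples FASTQ table or in-memory read list (named by sample)
#' @param panel `mutation_panel`
#' @param amplicons amplicon data.frame
#' @param reference genome
#' @param thresholds a [call_thresholds()] list
#' @param expected_known optional data.frame of expected carrier cells
#'   (`sample_id`, `mutation_id`); other non-REF calls are flagged
#'   `VALIDATION_REQUIRED`
#' @param vcf_path optional path for a multi-sample VCF of non-REF calls
#' @param read_len read length for span checks
#' @return list of class `screen_run`: `calls`, `junction_calls`,
#'   `pileups`, `sample_stats`, `targets`, `thresholds`
#' @export
genotype_run <- function(samples, panel, amplicons, reference,
                         thresholds = call_thresholds(),
                         expected_known = NULL, vcf_path = NULL,
                         read_len = 150L) {
  targets <- collapse_targets(panel)
  contexts <- target_contexts(panel, targets, reference)
  junction_refs <- junction_references(panel, reference)
  from_files <- is.data.frame(samples)
  ids <- if (from_files) samples$sample_id else names(samples)
  acc <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    reads <- if (from_files)
      read_fastq_pair(samples$r1[i], samples$r2[i])
    else samples[[i]]
    acc[[i]] <- genotype_sample(ids[i], reads, panel, amplicons, reference,
                                targets, contexts, junction_refs,
                                thresholds, read_len)
  }
  collect_run(acc, targets, panel, thresholds, expected_known, vcf_path)
}

# Shared collection step (also used by the fused simulate+genotype driver).
collect_run <- function(acc, targets, panel, thresholds, expected_known,
                        vcf_path = NULL) {
  clean <- function(df) { if (!is.null(df)) rownames(df) <- NULL; df }
  pileups <- clean(do.call(rbind, lapply(acc, `[[`, "pileups")))
  junction_calls <- clean(do.call(rbind, lapply(acc, `[[`,
                                                "junction_calls")))
  sample_stats <- clean(do.call(rbind, lapply(acc, `[[`, "stats")))
  calls <- call_genotypes(pileups, thresholds, expected_known)
  run <- structure(list(calls = calls, junction_calls = junction_calls,
                        pileups = pileups, sample_stats = sample_stats,
                        targets = targets, thresholds = thresholds),
                   class = "screen_run")
  if (!is.null(vcf_path)) write_vcf(run, panel, vcf_path)
  run
}

#' @export
print.screen_run <- function(x, ...) {
  nz <- x$calls[x$calls$genotype %in% c("HET", "HOM"), ]
  cat(sprintf(
    "screening run: %d samples, %d targets; %d HET and %d HOM calls\n",
    nrow(x$sample_stats), nrow(x$targets),
    sum(nz$genotype == "HET"), sum(nz$genotype == "HOM")))
  if (!is.null(x$junction_calls))
    cat(sprintf("  rearrangement carriers: %d\n",
                sum(x$junction_calls$carrier)))
  invisible(x)
}

# Junction references for all rearrangement mutations of a panel.
junction_references <- function(panel, reference, flank_len = 60L,
                                min_anchor = 20L) {
  lr <- panel[panel$class == "LARGE_REARRANGEMENT", , drop = FALSE]
  if (nrow(lr) == 0L) return(list())
  out <- lapply(seq_len(nrow(lr)), function(i)
    build_junction_reference(lr[i, ], reference, flank_len, min_anchor))
  names(out) <- lr$mutation_id
  out
}

#' Write non-REF calls as a multi-sample VCF (v4.2)
#'
#' One record per panel mutation called HET or HOM in at least one
#' sample; FORMAT carries GT, DP, AF and FLAGS per sample.
#'
#' @param run a `screen_run`
#' @param panel `mutation_panel`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_vcf <- function(run, panel, path) {
  calls <- run$calls
  nz <- calls[calls$genotype %in% c("HET", "HOM"), , drop = FALSE]
  samples <- sort(unique(calls$sample_id))
  muts <- unique(nz$mutation_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ampliscreen",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=DISORDER,Number=1,Type=String,Description="Disorder">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Informative depth">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Mutant allele fraction">',
    '##FORMAT=<ID=FL,Number=1,Type=String,Description="Call flags">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  pm <- panel[match(muts, panel$mutation_id), , drop = FALSE]
  ord <- order(pm$chrom, pm$pos)
  for (i in ord) {
    m <- pm[i, ]
    percall <- calls[calls$mutation_id == m$mutation_id, , drop = FALSE]
    fmt <- vapply(samples, function(s) {
      row <- percall[percall$sample_id == s, , drop = FALSE]
      if (nrow(row) == 0L) return("./.:0:.:.")
      gt <- c(NO_CALL = "./.", REF = "0/0", HET = "0/1",
              HOM = "1/1")[[row$genotype[1]]]
      sprintf("%s:%d:%s:%s", gt, row$DP[1],
              ifelse(is.na(row$af[1]), ".", sprintf("%.4f", row$af[1])),
              ifelse(nzchar(row$flags[1]), row$flags[1], "."))
    }, character(1))
    writeLines(paste(c(
      m$chrom, m$pos, m$mutation_id, m$ref, m$alt, ".", "PASS",
      sprintf("GENE=%s;DISORDER=%s", m$gene, m$disorder),
      "GT:DP:AF:FL", fmt), collapse = "\t"), con)
  }
  invisible(path)
}
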