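# Synthetic study universe: reference genome, panel/amplicon fixtures at
# the published study's scale, planted carrier genotypes, and per-sample
# paired-end reads with depth, error, off-target and paralog-interference
# models. Everything is driven by a master seed through derive_seed(), so
# the whole universe is bit-reproducible.

#' Fixture preset definitions
#'
#' `"paper-scale"` mirrors the published assay's structure: 370 small
#' mutations (two same-position allele pairs, hence 368 target positions)
#' in 148 genes and 120 disorders, 345 standard amplicons of 64-200 bp,
#' 4 junction amplicons for large rearrangements (one of them a 418 bp
#' length outlier), and 48 samples. `"pilot-cohort"` is the same fixture;
#' the name selects the positive-control planting in [planting_preset()].
#' `"tiny"` is a fast smoke-test universe.
#'
#' @param name preset name
#' @return list of preset parameters
#' @export
fixture_preset <- function(name = c("paper-scale", "pilot-cohort", "tiny")) {
  name <- match.arg(name)
  if (name == "tiny") {
    return(list(
      name = "tiny", n_mutations = 12L, n_same_position_pairs = 1L,
      n_genes = 6L, n_disorders = 5L, n_standard_amplicons = 11L,
      n_junction_amplicons = 1L, n_samples = 4L,
      amplicon_length_range = c(64L, 200L), outlier_lengths = integer(0),
      indel_fraction = 0.25, n_multi_target_amplicons = 1L,
      n_redundant_amplicons = 1L, n_conflict_pairs = 1L,
      rearrangements = data.frame(type = "DEL", size = 2000L,
                                  outlier_junction = FALSE),
      reference = list(n_chrom = 2L, chrom_len = 60000L, gc = 0.41)))
  }
  list(
    name = name, n_mutations = 370L, n_same_position_pairs = 2L,
    n_genes = 148L, n_disorders = 120L, n_standard_amplicons = 345L,
    n_junction_amplicons = 4L, n_samples = 48L,
    amplicon_length_range = c(64L, 200L), outlier_lengths = 418L,
    indel_fraction = 0.15, n_multi_target_amplicons = 43L,
    n_redundant_amplicons = 20L, n_conflict_pairs = 6L,
    # deletion/insertion loci with characterised breakpoints; the 6.7 kb
    # deletion's junction amplicon is the 418 bp length outlier
    rearrangements = data.frame(
      type = c("DEL", "DEL", "DEL", "INS"),
      size = c(5000L, 6700L, 12000L, 353L),
      outlier_junction = c(FALSE, TRUE, FALSE, FALSE)),
    reference = list(n_chrom = 4L, chrom_len = 800000L, gc = 0.41))
}

#' Depth model parameters
#'
#' Fragment counts per (amplicon, sample) are negative-binomial around
#' `mean_depth_per_assay` times a per-amplicon capture efficiency drawn
#' once per run: log-normal for most amplicons, with a small fraction of
#' systematically poor amplicons and a few dead ones (capture failure),
#' reproducing the observed pattern that low-coverage targets are
#' consistent across samples rather than random per cell. `dropout_prob`
#' adds independent per-cell dropout and defaults to 0 because coverage in
#' the emulated assay was uniform across samples.
#'
#' @param mean_depth_per_assay mean fragments per standard amplicon per
#'   sample (desk-scale; the emulated experiment averaged 2511x reads)
#' @param dispersion negative-binomial size parameter
#' @param dropout_prob probability an (amplicon, sample) cell yields zero
#'   fragments
#' @param off_target_fraction fraction of a sample's fragments drawn from
#'   random genome positions
#' @param efficiency_sdlog log-sd of per-amplicon capture efficiency
#' @param poor_amplicon_frac fraction of standard amplicons with
#'   systematically poor capture
#' @param poor_efficiency efficiency of poor amplicons
#' @param n_dead_amplicons standard amplicons with zero capture
#' @param junction_efficiency_range uniform range of junction-amplicon
#'   efficiency (the emulated junction assays were under-amplified)
#' @return list of class `depth_model`
#' @export
depth_model <- function(mean_depth_per_assay = 500L, dispersion = 20,
                        dropout_prob = 0, off_target_fraction = 0.05,
                        efficiency_sdlog = 0.4, poor_amplicon_frac = 0.015,
                        poor_efficiency = 0.02, n_dead_amplicons = 3L,
                        junction_efficiency_range = c(0.1, 0.3)) {
  stopifnot(mean_depth_per_assay > 0, dispersion > 0,
            dropout_prob >= 0, dropout_prob <= 1,
            off_target_fraction >= 0, off_target_fraction < 1)
  structure(list(mean_depth_per_assay = mean_depth_per_assay,
                 dispersion = dispersion, dropout_prob = dropout_prob,
                 off_target_fraction = off_target_fraction,
                 efficiency_sdlog = efficiency_sdlog,
                 poor_amplicon_frac = poor_amplicon_frac,
                 poor_efficiency = poor_efficiency,
                 n_dead_amplicons = as.integer(n_dead_amplicons),
                 junction_efficiency_range = junction_efficiency_range),
            class = "depth_model")
}

#' Read-simulation parameters
#' @param read_length read length in bp (150 bp paired-end protocol)
#' @param paired paired-end flag (single-end is not modelled)
#' @param per_base_error substitution error probability per base
#' @param randomize_orientation swap R1/R2 with probability 1/2 per
#'   fragment
#' @return list of class `read_sim_params`
#' @export
read_sim_params <- function(read_length = 150L, paired = TRUE,
                            per_base_error = 0.001,
                            randomize_orientation = TRUE) {
  stopifnot(read_length > 0, per_base_error >= 0, per_base_error < 1,
            isTRUE(paired))
  structure(list(read_length = as.integer(read_length), paired = TRUE,
                 per_base_error = per_base_error,
                 randomize_orientation = randomize_orientation),
            class = "read_sim_params")
}

#' Generate a reproducible random reference genome
#'
#' @param seed master seed
#' @param n_chrom number of chromosomes
#' @param chrom_len length of each chromosome (bp)
#' @param gc genome GC content
#' @return a named `DNAStringSet` (chr1, chr2, ...)
#' @export
generate_reference <- function(seed, n_chrom = 4L, chrom_len = 800000L,
                               gc = 0.41) {
  stopifnot(chrom_len >= 10000L)
  set.seed(derive_seed(seed, 1L))
  seqs <- random_dna(rep(chrom_len, n_chrom), gc = gc)
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  Biostrings::DNAStringSet(seqs)
}

# ---------------------------------------------------------------------------
# Panel + amplicon fixture generation

PRIMER_LEN <- 20L
TARGET_EDGE_MIN <- 22L   # min target offset from product start (past primer)
TARGET_EDGE_MAX <- 40L   # min distance from product end (indel headroom)

#' Generate a panel and amplicon fixture on a reference
#'
#' Lays out amplicons along the genome with inter-amplicon gaps mostly
#' above the pooling proximity limit (a configurable number of engineered
#' proximity conflicts excepted), assigns one or two new target positions
#' to each primary amplicon, adds redundant amplicons that re-cover
#' existing targets (overlap conflicts), plants the preset's same-position
#' allele pairs, and reserves a region of the last chromosome for large
#' rearrangements with characterised breakpoints probed by junction
#' amplicons.
#'
#' @param reference genome from [generate_reference()]
#' @param preset a [fixture_preset()] list
#' @param seed master seed
#' @return list with `panel` (a `mutation_panel`) and `amplicons`
#'   (amplicon data.frame)
#' @export
generate_panel_fixture <- function(reference, preset, seed) {
  set.seed(derive_seed(seed, 2L))
  chrom_names <- names(reference)
  chrom_len <- nchar(as.character(reference[[1]]))
  n_chrom <- length(chrom_names)
  lr <- preset$rearrangements
  n_junction <- preset$n_junction_amplicons
  stopifnot(nrow(lr) == n_junction)

  reserve <- sum(lr$size) + n_junction * 8000L + 4000L
  n_primary <- preset$n_standard_amplicons - preset$n_redundant_amplicons
  n_multi <- preset$n_multi_target_amplicons
  n_targets <- 2L * n_multi + (n_primary - n_multi)

  # --- place primary amplicons -------------------------------------------
  multi_flag <- rep(FALSE, n_primary)
  multi_flag[sample(n_primary, n_multi)] <- TRUE
  conflict_partner <- rep(FALSE, n_primary)
  if (preset$n_conflict_pairs > 0) {
    # partner amplicons placed close (proximity conflict) to the previous one
    conflict_partner[sample(2:n_primary, preset$n_conflict_pairs)] <- TRUE
  }
  chrom_idx <- 1L
  cursor <- sample(2000:4000, 1)
  amp <- vector("list", n_primary)
  limit_for <- function(ci) {
    if (ci == n_chrom) chrom_len - reserve - 300L else chrom_len - 300L
  }
  for (i in seq_len(n_primary)) {
    L <- if (multi_flag[i]) sample(110:200, 1) else sample(64:200, 1)
    gap <- if (conflict_partner[i] && i > 1) sample(1000:4000, 1)
           else sample(5200:9000, 1)
    start <- cursor + gap
    if (start + L > limit_for(chrom_idx)) {
      chrom_idx <- chrom_idx + 1L
      if (chrom_idx > n_chrom)
        stop("reference too small for the requested fixture", call. = FALSE)
      start <- sample(2000:4000, 1)
    }
    amp[[i]] <- list(chrom = chrom_names[chrom_idx], start = start,
                     length = L, multi = multi_flag[i])
    cursor <- start + L
  }

  # --- targets within primaries ------------------------------------------
  targets <- list()
  for (i in seq_len(n_primary)) {
    a <- amp[[i]]
    lo <- TARGET_EDGE_MIN
    hi <- a$length - TARGET_EDGE_MAX
    if (a$multi) {
      o1 <- sample(lo:(hi - 9L), 1)
      o2 <- o1 + sample(8:(hi - o1), 1)
      offs <- c(o1, o2)
    } else {
      offs <- sample(lo:hi, 1)
    }
    targets[[i]] <- offs
  }
  target_tab <- do.call(rbind, lapply(seq_len(n_primary), function(i) {
    a <- amp[[i]]
    data.frame(primary = i, chrom = a$chrom,
               pos = a$start + targets[[i]] + 1L,  # 1-based
               stringsAsFactors = FALSE)
  }))
  stopifnot(nrow(target_tab) == n_targets)
  target_tab$tkey <- seq_len(n_targets)

  # --- redundant amplicons re-covering single-target positions ------------
  single_primaries <- which(!multi_flag)
  redundant_of <- sample(single_primaries, preset$n_redundant_amplicons)
  red <- vector("list", length(redundant_of))
  for (k in seq_along(redundant_of)) {
    i <- redundant_of[k]
    pos <- target_tab$pos[target_tab$primary == i]
    repeat {
      L2 <- sample(64:200, 1)
      o2 <- sample(TARGET_EDGE_MIN:(L2 - TARGET_EDGE_MAX), 1)
      start2 <- pos - 1L - o2
      # distinct endpoints keep the redundant amplicon's primers distinct
      # from the primary's, so read assignment stays unambiguous
      if (start2 != amp[[i]]$start &&
          start2 + L2 != amp[[i]]$start + amp[[i]]$length) break
    }
    red[[k]] <- list(chrom = amp[[i]]$chrom, start = start2,
                     length = L2, covers = target_tab$tkey[
                       target_tab$primary == i])
  }

  # --- mutations -----------------------------------------------------------
  # classes per target; same-position pairs add a second allele
  n_pairs <- preset$n_same_position_pairs
  pairable <- target_tab$tkey[target_tab$primary %in% single_primaries]
  pair_tkeys <- if (n_pairs > 0) sort(sample(pairable, n_pairs)) else integer(0)
  classes <- sample(c("SNV", "INS", "DEL"), n_targets, replace = TRUE,
                    prob = c(1 - preset$indel_fraction,
                             preset$indel_fraction / 2,
                             preset$indel_fraction / 2))
  classes[pair_tkeys] <- "SNV"  # pair primary alleles are substitutions
  # force canonical indel fixtures: a 4 bp TATC insertion, a 3 bp deletion
  forced_ins <- which(classes == "INS")[1]
  forced_del <- which(classes == "DEL")[1]

  # gene/disorder assignment along genomic order
  ord <- order(match(target_tab$chrom, chrom_names), target_tab$pos)
  n_small_genes <- preset$n_genes - n_junction
  gene_of_target <- integer(n_targets)
  gene_of_target[ord] <- sort(rep_len(seq_len(n_small_genes), n_targets))
  gene_names <- sprintf("GENE%03d", seq_len(preset$n_genes))
  disorder_of_gene <- sprintf("DIS%03d",
                              rep_len(seq_len(preset$n_disorders),
                                      preset$n_genes))

  mut_rows <- list()
  mut_counter <- 0L
  add_mut <- function(gene_i, chrom, pos, ref, alt, class,
                      b1 = NA_integer_, b2 = NA_integer_, ins_seq = "",
                      label = "") {
    mut_counter <<- mut_counter + 1L
    mut_rows[[mut_counter]] <<- data.frame(
      mutation_id = sprintf("M%04d", mut_counter),
      gene = gene_names[gene_i], disorder = disorder_of_gene[gene_i],
      chrom = chrom, pos = pos, ref = ref, alt = alt, class = class,
      breakpoint1 = b1, breakpoint2 = b2, inserted_seq = ins_seq,
      label = label, stringsAsFactors = FALSE)
  }

  base_at <- function(chrom, pos) {
    ref_substr(reference_chrom(reference, chrom), pos, pos)
  }
  other_base <- function(b) sample(setdiff(DNA_BASES, b), 1)

  for (r in ord) {
    chrom <- target_tab$chrom[r]; pos <- target_tab$pos[r]
    gi <- gene_of_target[r]
    anchor <- base_at(chrom, pos)
    cls <- classes[r]
    if (cls == "SNV") {
      add_mut(gi, chrom, pos, anchor, other_base(anchor), "SNV",
              label = sprintf("%s>%s@%d", anchor, "", pos))
    } else if (cls == "INS") {
      ins <- if (identical(r, forced_ins)) "TATC"
             else random_dna(sample(1:12, 1))
      add_mut(gi, chrom, pos, anchor, paste0(anchor, ins), "INS",
              label = sprintf("ins%s@%d", ins, pos))
    } else {
      k <- if (identical(r, forced_del)) 3L else sample(1:12, 1)
      refseq <- ref_substr(reference_chrom(reference, chrom), pos, pos + k)
      add_mut(gi, chrom, pos, refseq, anchor, "DEL",
              label = sprintf("del%d@%d", k, pos))
    }
    if (r %in% pair_tkeys) {
      # second pathogenic allele at the same nucleotide; one pair is a
      # substitution pair, the other substitution + insertion
      if (r == pair_tkeys[1] || length(pair_tkeys) == 1L) {
        first_alt <- mut_rows[[mut_counter]]$alt
        add_mut(gi, chrom, pos, anchor,
                sample(setdiff(DNA_BASES, c(anchor, first_alt)), 1), "SNV",
                label = sprintf("pair_snv@%d", pos))
      } else {
        add_mut(gi, chrom, pos, anchor, paste0(anchor, random_dna(1)), "INS",
                label = sprintf("pair_ins@%d", pos))
      }
    }
  }

  # --- large rearrangements on the reserved tail --------------------------
  lr_chrom <- chrom_names[n_chrom]
  lr_cursor <- chrom_len - reserve + 2000L
  junction_meta <- list()
  for (j in seq_len(n_junction)) {
    gi <- n_small_genes + j
    if (lr$type[j] == "DEL") {
      b1 <- lr_cursor
      b2 <- b1 + lr$size[j] - 1L
      lab <- sprintf("Del%.3gKb", lr$size[j] / 1000)
      add_mut(gi, lr_chrom, b1, "", "", "LARGE_REARRANGEMENT", b1, b2, "",
              lab)
      lr_cursor <- b2 + 8000L
    } else {
      b1 <- lr_cursor
      ins_seq <- random_dna(lr$size[j])
      lab <- sprintf("Ins%dbp", lr$size[j])
      add_mut(gi, lr_chrom, b1, "", "", "LARGE_REARRANGEMENT", b1, b1,
              ins_seq, lab)
      lr_cursor <- b1 + 8000L
    }
    junction_meta[[j]] <- list(mutation_id = sprintf("M%04d", mut_counter),
                               outlier = lr$outlier_junction[j])
  }

  panel <- new_mutation_panel(do.call(rbind, mut_rows),
                              version = preset$name,
                              provenance = sprintf("synthetic fixture, seed %d",
                                                   seed))
  stopifnot(sum(panel$class != "LARGE_REARRANGEMENT") == preset$n_mutations)

  # --- amplicon table ------------------------------------------------------
  tgt <- collapse_targets(panel)
  tkey_of <- function(chrom, pos) {
    tgt$target_id[match(paste(chrom, pos), paste(tgt$chrom, tgt$pos))]
  }
  amp_rows <- list()
  amp_counter <- 0L
  add_amp <- function(chrom, start, length, target_ids, is_junction = FALSE,
                      is_outlier = FALSE, product = NULL) {
    amp_counter <<- amp_counter + 1L
    end <- start + length
    if (is.null(product))
      product <- ref_substr(reference_chrom(reference, chrom),
                            start + 1L, end)
    amp_rows[[amp_counter]] <<- data.frame(
      amplicon_id = sprintf("A%04d", amp_counter), chrom = chrom,
      start = start, end = end,
      fwd_primer = substr(product, 1, PRIMER_LEN),
      rev_primer = revcomp(substr(product, length - PRIMER_LEN + 1L, length)),
      length = length, gc_fraction = gc_fraction(product),
      target_ids = paste(target_ids, collapse = ","),
      is_junction = is_junction, is_length_outlier = is_outlier,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_primary)) {
    a <- amp[[i]]
    rows <- target_tab[target_tab$primary == i, , drop = FALSE]
    add_amp(a$chrom, a$start, a$length, tkey_of(rows$chrom, rows$pos))
  }
  for (k in seq_along(red)) {
    r <- red[[k]]
    rows <- target_tab[target_tab$tkey %in% r$covers, , drop = FALSE]
    add_amp(r$chrom, r$start, r$length, tkey_of(rows$chrom, rows$pos))
  }
  # junction amplicons: product is the mutant chimeric haplotype around the
  # left breakpoint; the interval records the left-flank locus
  for (j in seq_len(n_junction)) {
    meta <- junction_meta[[j]]
    mut <- panel[panel$mutation_id == meta$mutation_id, ]
    L <- if (meta$outlier) 418L else sample(140:180, 1)
    flankL <- sample(60:110, 1)
    start <- mut$breakpoint1 - 1L - flankL
    product <- junction_product_seq(mut, reference, start, L)
    add_amp(mut$chrom, start, L, mut$mutation_id, is_junction = TRUE,
            is_outlier = meta$outlier, product = product)
  }
  amplicons <- do.call(rbind, amp_rows)
  validate_amplicons(amplicons)
  list(panel = panel, amplicons = amplicons)
}

# Mutant-haplotype product of a junction amplicon: left genomic flank up to
# the left breakpoint, then (insertion) the inserted sequence or (deletion)
# the sequence resuming after the deleted interval.
junction_product_seq <- function(mut, reference, start, length) {
  chrom_seq <- reference_chrom(reference, mut$chrom)
  b1 <- mut$breakpoint1; b2 <- mut$breakpoint2
  if (b1 == b2 && nzchar(mut$inserted_seq)) {       # insertion
    left <- ref_substr(chrom_seq, start + 1L, b1)
    need <- length - nchar(left)
    stopifnot(need >= 1, need <= nchar(mut$inserted_seq))
    paste0(left, substr(mut$inserted_seq, 1, need))
  } else {                                          # deletion
    left <- ref_substr(chrom_seq, start + 1L, b1 - 1L)
    need <- length - nchar(left)
    paste0(left, ref_substr(chrom_seq, b2 + 1L, b2 + need))
  }
}

# ---------------------------------------------------------------------------
# Capture efficiencies, planting, genotypes

#' Draw per-amplicon capture efficiencies for a run
#'
#' Log-normal efficiency for standard amplicons, with `n_dead_amplicons`
#' set to zero and a `poor_amplicon_frac` fraction set to
#' `poor_efficiency`; dead and poor amplicons are chosen among amplicons
#' that are their target's only coverage, so that the resulting
#' low-coverage targets are consistent across samples. Junction amplicons
#' draw from `junction_efficiency_range`.
#'
#' @param amplicons amplicon data.frame
#' @param model a [depth_model()]
#' @param seed master seed
#' @return named numeric vector of efficiencies (amplicon_id names)
#' @export
draw_amplicon_efficiency <- function(amplicons, model, seed) {
  set.seed(derive_seed(seed, 3L))
  n <- nrow(amplicons)
  eff <- rlnorm(n, meanlog = 0, sdlog = model$efficiency_sdlog)
  names(eff) <- amplicons$amplicon_id
  std <- which(!amplicons$is_junction)
  # amplicons that are the sole coverage of all their targets
  tl <- amplicon_target_list(amplicons)
  cover_count <- table(unlist(tl[std]))
  sole <- std[vapply(std, function(i)
    all(cover_count[tl[[i]]] == 1L), logical(1))]
  n_dead <- min(model$n_dead_amplicons, length(sole))
  dead <- if (n_dead > 0) sample(sole, n_dead) else integer(0)
  remaining <- setdiff(sole, dead)
  n_poor <- min(round(model$poor_amplicon_frac * length(std)),
                length(remaining))
  poor <- if (n_poor > 0) sample(remaining, n_poor) else integer(0)
  eff[dead] <- 0
  eff[poor] <- model$poor_efficiency
  jx <- which(amplicons$is_junction)
  if (length(jx))
    eff[jx] <- runif(length(jx), model$junction_efficiency_range[1],
                     model$junction_efficiency_range[2])
  eff
}

# Targets whose best covering amplicon reaches a workable efficiency;
# plantings are restricted to these (the emulated study's positive controls
# sat at captured positions).
eligible_targets <- function(amplicons, eff, min_eff = 0.3) {
  std <- amplicons[!amplicons$is_junction, , drop = FALSE]
  tl <- amplicon_target_list(std)
  best <- tapply(rep(eff[std$amplicon_id], lengths(tl)), unlist(tl), max)
  names(best)[best >= min_eff]
}

#' Build the positive-control planting specification
#'
#' For `"pilot-cohort"`: 50 known heterozygous plantings across 40
#' samples, 2 of them at paralog-dilution loci; 15 unexpected singleton
#' carriers; 4 recurrent variants carried by 7, 8, 11 and 23 samples
#' (with 2 and 5 homozygotes among the first and last); 5 large-
#' rearrangement carriers over 3 of the 4 junction mutations; and three
#' engineered QC-failure samples (two read-starved, one with 44 dropout
#' targets).
#'
#' @param name planting preset name (only `"pilot-cohort"` is defined)
#' @param panel `mutation_panel`
#' @param amplicons amplicon data.frame
#' @param eff efficiencies from [draw_amplicon_efficiency()]
#' @param seed master seed
#' @return list of class `planting_spec`
#' @export
planting_preset <- function(name = "pilot-cohort", panel, amplicons, eff,
                            seed) {
  stopifnot(name == "pilot-cohort")
  set.seed(derive_seed(seed, 4L))
  n_samples <- 48L
  samples <- sprintf("S%02d", seq_len(n_samples))
  low_reads <- c("S02", "S27")
  many_low <- "S36"
  included <- setdiff(samples, c(low_reads, many_low))

  tgt <- collapse_targets(panel)
  ok_targets <- eligible_targets(amplicons, eff)
  # plant only at single-mutation targets for unambiguous expectations
  single <- tgt[tgt$n_mutations == 1L & tgt$target_id %in% ok_targets, ]
  pool <- unlist(single$mutation_ids)
  mut_class <- panel$class[match(pool, panel$mutation_id)]

  # paralog loci: SNVs covered by exactly one amplicon
  tl <- amplicon_target_list(amplicons)
  cover_count <- table(unlist(tl[!amplicons$is_junction]))
  t_of <- single$target_id[match(pool, unlist(single$mutation_ids))]
  para_ok <- pool[mut_class == "SNV" & cover_count[t_of] == 1L]
  paralog_mutations <- sample(para_ok, 2L)

  known_m <- c(paralog_mutations,
               sample(setdiff(pool, paralog_mutations), 48L))
  known_samples_pool <- sample(included, 40L)
  known_s <- c(known_samples_pool,
               sample(known_samples_pool, 10L))
  # paralog plantings first so they land in distinct samples
  known <- data.frame(sample_id = known_s, mutation_id = known_m,
                      stringsAsFactors = FALSE)

  rest <- setdiff(pool, known_m)
  singleton_m <- sample(rest, 15L)
  singleton <- data.frame(sample_id = sample(included, 15L, replace = TRUE),
                          mutation_id = singleton_m,
                          stringsAsFactors = FALSE)

  rest <- setdiff(rest, singleton_m)
  rec_m <- sample(rest[panel$class[match(rest, panel$mutation_id)] == "SNV"],
                  4L)
  rec_counts <- c(7L, 8L, 11L, 23L)
  rec_hom <- c(2L, 0L, 0L, 5L)
  recurrent <- lapply(seq_len(4L), function(i) {
    carriers <- sample(included, rec_counts[i])
    list(mutation_id = rec_m[i], carriers = carriers,
         hom = carriers[seq_len(rec_hom[i])])
  })

  lr_muts <- panel$mutation_id[panel$class == "LARGE_REARRANGEMENT"]
  lr_sizes <- abs(panel$breakpoint2 - panel$breakpoint1)[
    panel$class == "LARGE_REARRANGEMENT"]
  ins_mut <- lr_muts[panel$inserted_seq[match(lr_muts, panel$mutation_id)] != ""]
  del_muts <- setdiff(lr_muts, ins_mut)
  rear <- data.frame(
    sample_id = sample(included, 5L),
    mutation_id = c(rep(ins_mut[1], 3L), del_muts[1:2]),
    stringsAsFactors = FALSE)

  # 44 engineered dropout targets for the many-low sample, at otherwise
  # well-captured, unplanted, solely-covered positions
  planted_mut <- c(known$mutation_id, singleton$mutation_id, rec_m)
  planted_tgt <- t_of[match(planted_mut, pool)]
  cand <- setdiff(single$target_id[cover_count[single$target_id] == 1L],
                  planted_tgt)
  dropout_targets <- sample(cand, 44L)

  structure(list(
    n_samples = n_samples, sample_ids = samples,
    known_het = known, paralog_mutations = paralog_mutations,
    singletons = singleton, recurrent = recurrent,
    rearrangement_carriers = rear,
    failure_samples = list(low_reads = low_reads, many_low = many_low,
                           low_reads_scale = 0.003,
                           dropout_targets = dropout_targets),
    technical_replicates = NULL), class = "planting_spec")
}

#' Empty planting specification
#' @param sample_ids cohort sample ids
#' @return a `planting_spec` with no planted carriers
#' @export
planting_none <- function(sample_ids) {
  structure(list(
    n_samples = length(sample_ids), sample_ids = sample_ids,
    known_het = data.frame(sample_id = character(0),
                           mutation_id = character(0)),
    paralog_mutations = character(0),
    singletons = data.frame(sample_id = character(0),
                            mutation_id = character(0)),
    recurrent = list(),
    rearrangement_carriers = data.frame(sample_id = character(0),
                                        mutation_id = character(0)),
    failure_samples = list(low_reads = character(0), many_low = character(0),
                           low_reads_scale = 1,
                           dropout_targets = character(0)),
    technical_replicates = NULL), class = "planting_spec")
}

#' Realise a planting specification as a genotype table
#'
#' Returns the sparse sample-by-mutation genotype table (non-REF cells
#' only); every (sample, mutation) cell absent from the table is REF.
#' Technical replicates, when present in the spec, copy the source
#' sample's genotypes under the replicate's sample id (independent read
#' noise is applied later, at simulation time).
#'
#' @param panel `mutation_panel`
#' @param spec a `planting_spec`
#' @param sample_ids cohort sample ids (defaults to the spec's)
#' @return data.frame `sample_id`, `mutation_id`, `genotype` of class
#'   `genotype_table`
#' @export
assign_genotypes <- function(panel, spec, sample_ids = spec$sample_ids) {
  rows <- list(
    data.frame(sample_id = spec$known_het$sample_id,
               mutation_id = spec$known_het$mutation_id,
               genotype = rep("HET", nrow(spec$known_het)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = spec$singletons$sample_id,
               mutation_id = spec$singletons$mutation_id,
               genotype = rep("HET", nrow(spec$singletons)),
               stringsAsFactors = FALSE))
  for (r in spec$recurrent) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = r$carriers, mutation_id = r$mutation_id,
      genotype = ifelse(r$carriers %in% r$hom, "HOM", "HET"),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sample_id = spec$rearrangement_carriers$sample_id,
    mutation_id = spec$rearrangement_carriers$mutation_id,
    genotype = rep("HET", nrow(spec$rearrangement_carriers)),
    stringsAsFactors = FALSE)
  geno <- do.call(rbind, rows)
  if (!is.null(spec$technical_replicates)) {
    for (k in seq_len(nrow(spec$technical_replicates))) {
      src <- spec$technical_replicates$source[k]
      repl <- spec$technical_replicates$replicate[k]
      copy <- geno[geno$sample_id == src, , drop = FALSE]
      if (nrow(copy)) {
        copy$sample_id <- repl
        geno <- rbind(geno, copy)
      }
    }
  }
  unknown_m <- setdiff(geno$mutation_id, panel$mutation_id)
  if (length(unknown_m))
    stop("planting references unknown mutations: ",
         paste(unknown_m, collapse = ","), call. = FALSE)
  unknown_s <- setdiff(geno$sample_id, sample_ids)
  if (length(unknown_s))
    stop("planting references unknown samples: ",
         paste(unknown_s, collapse = ","), call. = FALSE)
  if (anyDuplicated(paste(geno$sample_id, geno$mutation_id)))
    stop("planting places two genotypes in one (sample, mutation) cell",
         call. = FALSE)
  rownames(geno) <- NULL
  structure(geno, class = c("genotype_table", "data.frame"),
            sample_ids = sample_ids)
}

# ---------------------------------------------------------------------------
# Read simulation

# Apply anchor-style variants (0-based anchor offsets within the product)
# to a product string; offsets must be pre-sorted ascending.
apply_variants <- function(product, offsets0, refs, alts) {
  for (k in rev(seq_along(offsets0))) {
    o <- offsets0[k]
    product <- paste0(substr(product, 1L, o),
                      alts[k],
                      substr(product, o + nchar(refs[k]) + 1L,
                             nchar(product)))
  }
  product
}

#' Simulate one sample's paired-end amplicon reads
#'
#' Per amplicon, the fragment count is negative-binomial around the
#' depth model's mean times the amplicon's capture efficiency; each
#' fragment is drawn uniformly from the sample's two haplotypes. At
#' paralog-interference loci half of the fragments are drawn instead from
#' a co-captured paralog haplotype carrying the reference base
#' (`paralog_mode = "dilute"`, so a heterozygote's expected mutant
#' fraction is 0.25) or the mutant base (`"enrich"`). Junction amplicons
#' amplify only carrier haplotypes. An `off_target_fraction` of fragments
#' comes from random genome positions. Read names encode the ground-truth
#' origin (`sample:amplicon:serial` or `sample:OFFTGT:serial`).
#'
#' @param sample_id sample name
#' @param genotypes `genotype_table` (the whole cohort's; filtered here)
#' @param panel `mutation_panel`
#' @param amplicons amplicon data.frame
#' @param reference genome
#' @param eff amplicon efficiencies
#' @param model [depth_model()]
#' @param params [read_sim_params()]
#' @param paralog_mutations mutation ids with even-ratio paralog capture
#' @param seed integer seed for this sample's draws
#' @param depth_scale extra per-sample depth multiplier (read starvation)
#' @param dropout_targets target ids whose amplicons yield zero fragments
#'   in this sample
#' @param paralog_mode `"dilute"` or `"enrich"`
#' @return list with `r1`, `r2` (named character vectors of reads) and
#'   `truth` (per-amplicon fragment counts, off-target count)
#' @export
simulate_sample_reads <- function(sample_id, genotypes, panel, amplicons,
                                  reference, eff, model = depth_model(),
                                  params = read_sim_params(),
                                  paralog_mutations = character(0),
                                  seed = 0L, depth_scale = 1,
                                  dropout_targets = character(0),
                                  paralog_mode = c("dilute", "enrich")) {
  paralog_mode <- match.arg(paralog_mode)
  set.seed(seed)
  # one-off conversion: chromosome-string lookups below are hot
  reference <- as.list(as.character(as_dnastringset(reference)))
  geno <- genotypes[genotypes$sample_id == sample_id, , drop = FALSE]
  geno_of <- setNames(geno$genotype, geno$mutation_id)
  tgt <- collapse_targets(panel)
  tl <- amplicon_target_list(amplicons)
  n_amp <- nrow(amplicons)

  templates <- character(0)
  tmpl_idx <- integer(0)
  origin <- character(0)
  truth_counts <- integer(n_amp)

  for (i in seq_len(n_amp)) {
    a <- amplicons[i, ]
    mu <- model$mean_depth_per_assay * eff[[a$amplicon_id]] * depth_scale
    if (a$is_junction) {
      lr_id <- a$target_ids
      if (is.na(geno_of[lr_id])) next  # junction product only in carriers
      n_frag <- rnbinom(1L, size = model$dispersion, mu = mu)
      if (n_frag == 0L) next
      mut <- panel[panel$mutation_id == lr_id, ]
      prod <- junction_product_seq(mut, reference, a$start, a$length)
      templates <- c(templates, prod)
      tmpl_idx <- c(tmpl_idx, rep.int(length(templates), n_frag))
      origin <- c(origin, rep.int(a$amplicon_id, n_frag))
      truth_counts[i] <- n_frag
      next
    }
    covered <- tl[[i]]
    if (any(covered %in% dropout_targets)) next
    if (model$dropout_prob > 0 && runif(1) < model$dropout_prob) next
    n_frag <- rnbinom(1L, size = model$dispersion, mu = mu)
    if (n_frag == 0L) next
    # member mutations with non-REF genotype in this sample
    rows <- tgt[match(covered, tgt$target_id), , drop = FALSE]
    mids <- unlist(rows$mutation_ids)
    mg <- geno_of[mids]
    carried <- mids[!is.na(mg)]
    ref_prod <- amplicon_ref_product(a, reference)
    if (length(carried) == 0L) {
      variants <- ref_prod
      weights <- 1
    } else {
      pm <- panel[match(carried, panel$mutation_id), , drop = FALSE]
      off0 <- pm$pos - 1L - a$start
      ok <- order(off0)
      hom <- carried[geno_of[carried] == "HOM"]
      het <- carried[geno_of[carried] == "HET"]
      mk <- function(ids) {
        if (length(ids) == 0L) return(ref_prod)
        sel <- match(ids, carried)[order(off0[match(ids, carried)])]
        apply_variants(ref_prod, off0[sel], pm$ref[sel], pm$alt[sel])
      }
      # same-position het alleles (compound het) go on opposite haplotypes
      het_pos <- pm$pos[match(het, carried)]
      dup <- duplicated(het_pos)
      hap1 <- mk(c(hom, het[dup]))
      hap2 <- mk(c(hom, het[!dup]))
      has_para <- any(carried %in% paralog_mutations)
      if (has_para) {
        para_hap <- if (paralog_mode == "dilute") mk(hom) else mk(c(hom, het))
        variants <- c(hap1, hap2, para_hap)
        weights <- c(0.25, 0.25, 0.5)
      } else {
        variants <- c(hap1, hap2)
        weights <- c(0.5, 0.5)
      }
    }
    base <- length(templates)
    templates <- c(templates, variants)
    pick <- if (length(variants) == 1L) rep.int(1L, n_frag)
            else sample.int(length(variants), n_frag, replace = TRUE,
                            prob = weights)
    tmpl_idx <- c(tmpl_idx, base + pick)
    origin <- c(origin, rep.int(a$amplicon_id, n_frag))
    truth_counts[i] <- n_frag
  }

  n_on <- length(tmpl_idx)
  n_off <- if (model$off_target_fraction > 0)
    rbinom(1L, size = round(n_on / (1 - model$off_target_fraction)),
           prob = model$off_target_fraction)
  else 0L
  if (n_off > 0L) {
    ref_vec <- unlist(reference)
    lens <- nchar(ref_vec)
    oc <- sample.int(length(ref_vec), n_off, replace = TRUE)
    flen <- sample(150:350, n_off, replace = TRUE)
    ostart <- 1L + floor(runif(n_off) * (lens[oc] - flen))
    off_seq <- substring(ref_vec[oc], ostart, ostart + flen - 1L)
    base <- length(templates)
    templates <- c(templates, off_seq)
    tmpl_idx <- c(tmpl_idx, base + seq_len(n_off))
    origin <- c(origin, rep.int("OFFTGT", n_off))
  }

  if (length(tmpl_idx) == 0L) {
    return(list(sample_id = sample_id,
                r1 = setNames(character(0), character(0)),
                r2 = setNames(character(0), character(0)),
                truth = list(per_amplicon = setNames(truth_counts,
                                                     amplicons$amplicon_id),
                             n_on_target = 0L, n_off_target = 0L,
                             n_total = 0L)))
  }
  reads <- cpp_make_reads(templates, tmpl_idx, params$read_length,
                          params$per_base_error,
                          params$randomize_orientation)
  nm <- sprintf("%s:%s:%d", sample_id, origin, seq_along(tmpl_idx))
  r1 <- setNames(reads$r1, nm)
  r2 <- setNames(reads$r2, nm)
  list(sample_id = sample_id, r1 = r1, r2 = r2,
       truth = list(per_amplicon = setNames(truth_counts,
                                            amplicons$amplicon_id),
                    n_on_target = n_on, n_off_target = n_off,
                    n_total = n_on + n_off))
}

#' Simulate a whole cohort
#'
#' Orchestrates [simulate_sample_reads()] for every sample of the
#' planting spec, applying the engineered QC failures (read-starved
#' samples, dropout targets), optionally writing per-sample gzipped
#' FASTQ pairs and a ground-truth manifest JSON, and optionally streaming
#' each sample's reads to a callback (used to fuse simulation with
#' genotyping without holding the whole cohort in memory).
#'
#' @param reference genome
#' @param panel `mutation_panel`
#' @param amplicons amplicon data.frame
#' @param spec a `planting_spec`
#' @param model [depth_model()]
#' @param params [read_sim_params()]
#' @param seed master seed
#' @param out_dir if non-NULL, write FASTQs and `manifest.json` here
#' @param callback if non-NULL, `callback(sample_reads)` is invoked per
#'   sample with the [simulate_sample_reads()] result
#' @param eff optional precomputed efficiencies (defaults to
#'   [draw_amplicon_efficiency()] under the same seed)
#' @param paralog_mode paralog capture model, `"dilute"` or `"enrich"`
#' @return list with `manifest` and, when writing, `fastq` (data.frame of
#'   per-sample R1/R2 paths)
#' @export
simulate_cohort <- function(reference, panel, amplicons, spec,
                            model = depth_model(),
                            params = read_sim_params(), seed = 1L,
                            out_dir = NULL, callback = NULL, eff = NULL,
                            paralog_mode = "dilute") {
  if (is.null(eff)) eff <- draw_amplicon_efficiency(amplicons, model, seed)
  geno <- assign_genotypes(panel, spec)
  tgt <- collapse_targets(panel)
  samples <- spec$sample_ids
  fq <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fq <- data.frame(sample_id = samples,
                     r1 = file.path(out_dir, paste0(samples, "_R1.fastq.gz")),
                     r2 = file.path(out_dir, paste0(samples, "_R2.fastq.gz")),
                     stringsAsFactors = FALSE)
  }
  per_sample <- vector("list", length(samples))
  names(per_sample) <- samples
  for (si in seq_along(samples)) {
    s <- samples[si]
    scale <- if (s %in% spec$failure_samples$low_reads)
      spec$failure_samples$low_reads_scale else 1
    drop_t <- if (identical(s, spec$failure_samples$many_low) ||
                  s %in% spec$failure_samples$many_low)
      spec$failure_samples$dropout_targets else character(0)
    sr <- simulate_sample_reads(
      s, geno, panel, amplicons, reference, eff, model, params,
      paralog_mutations = spec$paralog_mutations,
      seed = derive_seed(seed, 10L, si), depth_scale = scale,
      dropout_targets = drop_t, paralog_mode = paralog_mode)
    if (!is.null(fq)) write_fastq_pair(sr, fq$r1[si], fq$r2[si])
    if (!is.null(callback)) callback(sr)
    per_sample[[si]] <- list(n_on_target = sr$truth$n_on_target,
                             n_off_target = sr$truth$n_off_target,
                             n_total = sr$truth$n_total)
  }
  manifest <- list(
    seed = seed, preset = attr(spec, "name") %||% "custom",
    n_samples = length(samples), sample_ids = samples,
    known_het = spec$known_het,
    paralog_mutations = spec$paralog_mutations,
    singletons = spec$singletons,
    recurrent = lapply(spec$recurrent, function(r)
      list(mutation_id = r$mutation_id, carriers = r$carriers, hom = r$hom)),
    rearrangement_carriers = spec$rearrangement_carriers,
    failure_samples = spec$failure_samples,
    genotypes = as.data.frame(geno),
    per_sample = per_sample,
    n_targets = nrow(tgt),
    n_small_mutations = sum(panel$class != "LARGE_REARRANGEMENT"))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest, fastq = fq)
}

#' Write one sample's reads as a gzipped FASTQ pair
#' @param sample_reads result of [simulate_sample_reads()]
#' @param r1_path,r2_path output paths
#' @return invisibly, `c(r1_path, r2_path)`
#' @export
write_fastq_pair <- function(sample_reads, r1_path, r2_path) {
  write_one <- function(reads, mate, path) {
    con <- gzfile(path, "wb")
    on.exit(close(con))
    if (length(reads)) {
      qual <- strrep("I", nchar(reads))
      writeLines(paste0("@", names(reads), "/", mate, "\n", reads,
                        "\n+\n", qual), con, sep = "\n")
    }
  }
  write_one(sample_reads$r1, 1L, r1_path)
  write_one(sample_reads$r2, 2L, r2_path)
  invisible(c(r1_path, r2_path))
}
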