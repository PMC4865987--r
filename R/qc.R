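# Run-level QC: the target-by-sample assay depth matrix, sample exclusion
# rules, capture/conclusiveness metrics, on-target specificity, and
# recurrent-variant (benign-candidate) flagging.

#' Compute the assay depth matrix
#'
#' Rows are collapsed target positions, columns samples, cells the
#' informative depth (DP) of that assay; (target, sample) cells without a
#' pileup are 0. The matrix carries the panel's small-mutation count as
#' an attribute so assay accounting can be reported in both conventions
#' (mutations x samples and positions x samples).
#'
#' @param pileups pileup data.frame from a [genotype_run()]
#' @return integer matrix of class `assay_matrix`
#' @export
compute_assay_matrix <- function(pileups) {
  first <- pileups[!duplicated(paste(pileups$target_id,
                                     pileups$sample_id)), ]
  targets <- unique(first$target_id)
  samples <- unique(first$sample_id)
  m <- matrix(0L, nrow = length(targets), ncol = length(samples),
              dimnames = list(targets, samples))
  m[cbind(match(first$target_id, targets),
          match(first$sample_id, samples))] <- first$DP
  structure(m, class = c("assay_matrix", class(m)),
            n_mutations = length(unique(pileups$mutation_id)))
}

#' Assay-count accounting in both conventions
#'
#' The headline convention counts mutations x samples (multi-allelic
#' positions contribute one assay per mutation); the matrix convention
#' counts positions x samples. Both are reported, before and after
#' sample exclusion.
#'
#' @param matrix an `assay_matrix`
#' @param included_samples sample ids retained after QC exclusion
#' @return list with the four assay counts and the dimensions
#' @export
assay_accounting <- function(matrix,
                             included_samples = colnames(matrix)) {
  n_mut <- attr(matrix, "n_mutations")
  n_pos <- nrow(matrix)
  n_all <- ncol(matrix)
  n_inc <- length(included_samples)
  list(n_mutations = n_mut, n_positions = n_pos,
       n_samples = n_all, n_included_samples = n_inc,
       assays_mutations_all = n_mut * n_all,
       assays_positions_all = n_pos * n_all,
       assays_mutations_included = n_mut * n_inc,
       assays_positions_included = n_pos * n_inc)
}

#' Sample-exclusion rules
#' @param low_read_fraction a sample is excluded (`LOW_READS`) when its
#'   total reads fall below this fraction of the median of the other
#'   samples' totals
#' @param max_low_targets a sample is excluded (`MANY_LOW_TARGETS`) when
#'   more than this many targets sit below `low_target_dp`
#' @param low_target_dp the per-target depth defining a low target
#' @return list of class `qc_rules`
#' @export
qc_rules <- function(low_read_fraction = 0.01, max_low_targets = 40L,
                     low_target_dp = 10L) {
  structure(list(low_read_fraction = low_read_fraction,
                 max_low_targets = as.integer(max_low_targets),
                 low_target_dp = as.integer(low_target_dp)),
            class = "qc_rules")
}

#' Apply sample-exclusion rules
#'
#' `LOW_READS` fires first (total reads under `low_read_fraction` of the
#' median of the other samples), then `MANY_LOW_TARGETS` (more than
#' `max_low_targets` targets under `low_target_dp`). Exclusion is applied
#' before all downstream metrics.
#'
#' @param read_counts named vector of per-sample total read pairs
#' @param matrix an `assay_matrix`
#' @param rules a [qc_rules()] list
#' @return data.frame `sample_id`, `total_reads`, `n_low_targets`,
#'   `excluded`, `reason`
#' @export
exclude_samples <- function(read_counts, matrix, rules = qc_rules()) {
  samples <- colnames(matrix)
  stopifnot(all(samples %in% names(read_counts)))
  total <- read_counts[samples]
  n_low <- colSums(matrix < rules$low_target_dp)
  reason <- rep("NONE", length(samples))
  for (i in seq_along(samples)) {
    med_others <- median(total[-i])
    if (total[i] < rules$low_read_fraction * med_others) {
      reason[i] <- "LOW_READS"
    } else if (n_low[i] > rules$max_low_targets) {
      reason[i] <- "MANY_LOW_TARGETS"
    }
  }
  data.frame(sample_id = samples, total_reads = as.integer(total),
             n_low_targets = as.integer(n_low),
             excluded = reason != "NONE", reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Coverage and conclusiveness metrics
#'
#' Over the included samples: the percentage of assays at or above
#' `dp_threshold`; the percentage of targets at or above the threshold
#' in every included sample; the percentage of targets whose average
#' depth per sample reaches `avg_depth_threshold`; each sample's
#' conclusive-test rate (fraction of targets at or above threshold) and
#' its minimum across samples; plus assay accounting in both
#' conventions.
#'
#' @param matrix an `assay_matrix`
#' @param included_samples samples retained after exclusion
#' @param dp_threshold conclusive-call depth threshold
#' @param avg_depth_threshold per-target average-depth threshold
#' @return list of class `run_metrics`
#' @export
coverage_metrics <- function(matrix, included_samples = colnames(matrix),
                             dp_threshold = 50L,
                             avg_depth_threshold = 150L) {
  m <- matrix[, included_samples, drop = FALSE]
  if (length(m) == 0L) stop("empty assay matrix", call. = FALSE)
  pct_assays <- 100 * mean(m >= dp_threshold)
  pct_all_samples <- 100 * mean(apply(m >= dp_threshold, 1, all))
  pct_avg <- 100 * mean(rowMeans(m) >= avg_depth_threshold)
  conclusive <- 100 * colMeans(m >= dp_threshold)
  structure(list(
    dp_threshold = dp_threshold,
    pct_assays_ge_dp = pct_assays,
    pct_targets_covered_all_samples = pct_all_samples,
    pct_targets_avg_ge = pct_avg,
    avg_depth_threshold = avg_depth_threshold,
    per_sample_conclusive_pct = conclusive,
    min_conclusive_pct = min(conclusive),
    mean_assay_depth = mean(m),
    accounting = assay_accounting(matrix, included_samples)),
    class = "run_metrics")
}

#' @export
print.run_metrics <- function(x, ...) {
  a <- x$accounting
  cat(sprintf("assays: %d (mutations x samples, all) / %d (included)\n",
              a$assays_mutations_all, a$assays_mutations_included))
  cat(sprintf("        %d (positions x samples, all) / %d (included)\n",
              a$assays_positions_all, a$assays_positions_included))
  cat(sprintf("%.1f%% of assays >= %dx; mean assay depth %.0fx\n",
              x$pct_assays_ge_dp, x$dp_threshold, x$mean_assay_depth))
  cat(sprintf("%.1f%% of targets >= %dx in all included samples\n",
              x$pct_targets_covered_all_samples, x$dp_threshold))
  cat(sprintf("minimum per-sample conclusive rate %.1f%%\n",
              x$min_conclusive_pct))
  invisible(x)
}

#' On-target read fraction (capture specificity)
#' @param sample_stats per-sample assignment stats from a `screen_run`
#' @return list with `pooled` fraction and per-sample fractions
#' @export
on_target_fraction <- function(sample_stats) {
  per_sample <- setNames(sample_stats$n_assigned / sample_stats$n_pairs,
                         sample_stats$sample_id)
  list(pooled = sum(sample_stats$n_assigned) / sum(sample_stats$n_pairs),
       per_sample = per_sample)
}

#' Partition unexpected calls and flag recurrent variants
#'
#' Non-REF calls (HET/HOM) in included samples that are not in the
#' expected-known list are "unexpected". A variant is flagged as a
#' benign-polymorphism candidate when its carrier fraction of the
#' included cohort reaches `cohort_fraction_threshold` or it is called
#' homozygous in at least two samples. Unexpected calls split into those
#' attributed to flagged recurrent variants and the remaining singletons.
#'
#' @param calls calls data.frame from a `screen_run`
#' @param expected_known data.frame `sample_id`, `mutation_id`
#' @param included_samples samples retained after QC exclusion
#' @param cohort_fraction_threshold recurrent-variant cohort fraction
#' @return list of class `recurrent_report`: `unexpected_calls`, `flags`,
#'   and `counts` (total_unexpected, recurrent_attributed, singleton,
#'   n_flagged)
#' @export
flag_recurrent <- function(calls, expected_known,
                           included_samples = unique(calls$sample_id),
                           cohort_fraction_threshold = 0.10) {
  known_key <- paste(expected_known$sample_id, expected_known$mutation_id)
  nz <- calls[calls$genotype %in% c("HET", "HOM") &
                calls$sample_id %in% included_samples, , drop = FALSE]
  unexpected <- nz[!(paste(nz$sample_id, nz$mutation_id) %in% known_key), ,
                   drop = FALSE]
  n_inc <- length(included_samples)
  by_mut <- split(unexpected, unexpected$mutation_id)
  flags <- do.call(rbind, lapply(by_mut, function(d) {
    data.frame(mutation_id = d$mutation_id[1],
               n_samples_called = nrow(d),
               n_hom = sum(d$genotype == "HOM"),
               cohort_fraction = nrow(d) / n_inc,
               stringsAsFactors = FALSE)
  }))
  if (is.null(flags))
    flags <- data.frame(mutation_id = character(0),
                        n_samples_called = integer(0), n_hom = integer(0),
                        cohort_fraction = numeric(0),
                        flagged_benign_candidate = logical(0))
  else {
    flags$flagged_benign_candidate <-
      flags$cohort_fraction >= cohort_fraction_threshold | flags$n_hom >= 2L
    rownames(flags) <- NULL
  }
  rec_muts <- flags$mutation_id[flags$flagged_benign_candidate]
  attributed <- sum(unexpected$mutation_id %in% rec_muts)
  structure(list(
    unexpected_calls = unexpected, flags = flags,
    counts = list(total_unexpected = nrow(unexpected),
                  recurrent_attributed = attributed,
                  singleton = nrow(unexpected) - attributed,
                  n_flagged = length(rec_muts))),
    class = "recurrent_report")
}

#' @export
print.recurrent_report <- function(x, ...) {
  cat(sprintf(
    "unexpected on-panel calls: %d (%d attributed to %d recurrent variants, %d singletons)\n",
    x$counts$total_unexpected, x$counts$recurrent_attributed,
    x$counts$n_flagged, x$counts$singleton))
  invisible(x)
}

#' Write the assay matrix as TSV (targets x samples)
#' @param matrix an `assay_matrix`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(target_id = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the run QC summary as JSON
#' @param metrics a [coverage_metrics()] result
#' @param exclusions an [exclude_samples()] result
#' @param specificity an [on_target_fraction()] result
#' @param path output path
#' @return invisibly, `path`
#' @export
write_qc_json <- function(metrics, exclusions, specificity, path) {
  jsonlite::write_json(list(
    metrics = unclass(metrics),
    excluded_samples = exclusions[exclusions$excluded, ],
    on_target = specificity), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-sample final reports
#'
#' One TSV per sample listing the mutations identified in it (HET/HOM
#' calls and junction-detected rearrangement carriers) with gene,
#' disorder, genotype, depth, allele fraction and flags.
#'
#' @param run a `screen_run`
#' @param panel `mutation_panel`
#' @param dir output directory
#' @param samples samples to report (default: all in the run)
#' @return invisibly, the report paths
#' @export
write_sample_reports <- function(run, panel, dir,
                                 samples = unique(run$calls$sample_id)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in samples) {
    nz <- run$calls[run$calls$sample_id == s &
                      run$calls$genotype %in% c("HET", "HOM"), ,
                    drop = FALSE]
    rows <- data.frame(
      mutation_id = nz$mutation_id,
      gene = panel$gene[match(nz$mutation_id, panel$mutation_id)],
      disorder = panel$disorder[match(nz$mutation_id, panel$mutation_id)],
      genotype = nz$genotype, DP = nz$DP, AF = round(nz$af, 4),
      flags = nz$flags, stringsAsFactors = FALSE)
    if (!is.null(run$junction_calls)) {
      jx <- run$junction_calls[run$junction_calls$sample_id == s &
                                 run$junction_calls$carrier, , drop = FALSE]
      if (nrow(jx))
        rows <- rbind(rows, data.frame(
          mutation_id = jx$mutation_id,
          gene = panel$gene[match(jx$mutation_id, panel$mutation_id)],
          disorder = panel$disorder[match(jx$mutation_id,
                                          panel$mutation_id)],
          genotype = "CARRIER_JUNCTION", DP = jx$supporting_reads,
          AF = NA_real_, flags = "", stringsAsFactors = FALSE))
    }
    p <- file.path(dir, paste0(s, "_report.tsv"))
    write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Basic depth heat map of an assay matrix
#'
#' Targets in ranked order of average depth; cells below `threshold`
#' highlighted.
#'
#' @param matrix an `assay_matrix`
#' @param threshold highlight depth
#' @return invisibly, the reordered matrix
#' @export
plot_assay_matrix <- function(matrix, threshold = 100L) {
  ord <- order(rowMeans(matrix))
  m <- matrix[ord, , drop = FALSE]
  cols <- c("#B2182B", grDevices::colorRampPalette(
    c("white", "#2166AC"))(63))
  breaks <- c(-1, threshold, seq(threshold + 1, max(m, threshold + 64),
                                 length.out = 63))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(unclass(m)),
                  col = cols, breaks = breaks, xlab = "sample",
                  ylab = "target (ranked by mean depth)", useRaster = TRUE)
  invisible(m)
}
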