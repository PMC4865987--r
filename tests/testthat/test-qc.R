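# QC: assay matrix, exclusion rules, coverage metrics, recurrent flags.

fake_pileups <- function(dp_matrix, n_mut_extra = 0L) {
  targets <- rownames(dp_matrix)
  samples <- colnames(dp_matrix)
  df <- expand.grid(target_id = targets, sample_id = samples,
                    stringsAsFactors = FALSE)
  df$mutation_id <- paste0("M_", df$target_id)
  df$DP <- as.integer(dp_matrix[cbind(df$target_id, df$sample_id)])
  df$ref_count <- df$DP
  df$alt_count <- 0L
  df$other_count <- 0L
  df$af <- 0
  df$uncaptured <- FALSE
  if (n_mut_extra > 0) {
    # extra alleles at the first target (multi-allelic convention)
    extra <- df[df$target_id == targets[1], ]
    extra$mutation_id <- paste0(extra$mutation_id, "_b")
    df <- rbind(df, extra)
  }
  df
}

test_that("the assay matrix reproduces the pileup grid and both accounting conventions", {
  set.seed(2)
  m0 <- matrix(rpois(5 * 3, 200), 5, 3,
               dimnames = list(paste0("T", 1:5), paste0("S", 1:3)))
  pil <- fake_pileups(m0, n_mut_extra = 1L)
  m <- compute_assay_matrix(pil)
  expect_equal(unclass(m)[rownames(m0), colnames(m0)], m0)
  acc <- assay_accounting(m, included_samples = c("S1", "S3"))
  expect_equal(acc$assays_mutations_all, 6 * 3)   # 5 targets + 1 extra allele
  expect_equal(acc$assays_positions_all, 5 * 3)
  expect_equal(acc$assays_mutations_included, 6 * 2)
  expect_equal(acc$assays_positions_included, 5 * 2)
  # 1x1 degenerate run
  m1 <- compute_assay_matrix(fake_pileups(matrix(7L, 1, 1,
    dimnames = list("T1", "S1"))))
  expect_equal(as.vector(m1), 7L)
})

test_that("exclusion rules fire on hand-computed medians and low-target counts", {
  m <- matrix(100L, nrow = 60, ncol = 5,
              dimnames = list(sprintf("T%02d", 1:60), sprintf("S%d", 1:5)))
  m[1:45, 3] <- 5L    # S3: 45 targets below 10x
  rc <- c(S1 = 100000, S2 = 120000, S3 = 110000, S4 = 900, S5 = 105000)
  # S4: median of others = 107500; threshold 1075 > 900 -> LOW_READS
  qc <- exclude_samples(rc, m, qc_rules())
  expect_equal(qc$reason, c("NONE", "NONE", "MANY_LOW_TARGETS",
                            "LOW_READS", "NONE"))
  expect_equal(qc$n_low_targets[3], 45L)
  # healthy cohort: nothing excluded
  qc2 <- exclude_samples(rc[-4], m[, -4], qc_rules())
  expect_true(all(!qc2$excluded[qc2$sample_id != "S3"]))
  # idempotence: re-running on the filtered cohort excludes nothing new
  keep <- qc$sample_id[!qc$excluded]
  qc3 <- exclude_samples(rc[keep], m[, keep], qc_rules())
  expect_true(all(!qc3$excluded))
  # boundary: exactly max_low_targets low targets does not fire
  m4 <- m
  m4[1:45, 3] <- 100L
  m4[1:40, 3] <- 5L
  qc4 <- exclude_samples(rc[-4], m4[, -4], qc_rules())
  expect_equal(qc4$reason[qc4$sample_id == "S3"], "NONE")
})

test_that("coverage metrics match a direct cell-counting oracle", {
  set.seed(3)
  m0 <- matrix(sample(c(0L, 30L, 200L, 1000L), 40 * 6, TRUE,
                      prob = c(.05, .1, .5, .35)), 40, 6,
               dimnames = list(sprintf("T%02d", 1:40), sprintf("S%d", 1:6)))
  pil <- fake_pileups(m0)
  m <- compute_assay_matrix(pil)
  met <- coverage_metrics(m, dp_threshold = 50L)
  k <- sum(m0 < 50)
  expect_equal(met$pct_assays_ge_dp, 100 * (1 - k / length(m0)))
  expect_equal(met$pct_targets_covered_all_samples,
               100 * mean(rowSums(m0 >= 50) == ncol(m0)))
  expect_equal(unname(met$per_sample_conclusive_pct["S2"]),
               100 * mean(m0[, "S2"] >= 50))
  expect_equal(met$min_conclusive_pct,
               min(100 * colMeans(m0 >= 50)))
  # all-saturated matrix: everything 100%
  msat <- compute_assay_matrix(fake_pileups(matrix(1000L, 3, 3,
    dimnames = list(paste0("T", 1:3), paste0("S", 1:3)))))
  mets <- coverage_metrics(msat)
  expect_equal(mets$pct_assays_ge_dp, 100)
  expect_equal(mets$pct_targets_covered_all_samples, 100)
  expect_equal(mets$min_conclusive_pct, 100)
  # monotonicity: raising the threshold never increases the assay rate
  ths <- c(10L, 50L, 100L, 500L, 2000L)
  rates <- vapply(ths, function(t)
    coverage_metrics(m, dp_threshold = t)$pct_assays_ge_dp, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("percentages are recomputable from the matrix TSV", {
  set.seed(4)
  m0 <- matrix(sample(c(5L, 500L), 30, TRUE), 10, 3,
               dimnames = list(sprintf("T%02d", 1:10), paste0("S", 1:3)))
  m <- compute_assay_matrix(fake_pileups(m0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read.delim(path, check.names = FALSE)
  cells <- as.matrix(back[, -1])
  expect_equal(100 * mean(cells >= 50),
               coverage_metrics(m)$pct_assays_ge_dp)
})

test_that("on-target fraction aggregates assignment stats", {
  st <- data.frame(sample_id = c("S1", "S2"), n_pairs = c(1000L, 4000L),
                   n_assigned = c(950L, 3800L), n_ambiguous = c(0L, 0L),
                   n_off_target = c(50L, 200L))
  ot <- on_target_fraction(st)
  expect_equal(ot$pooled, 4750 / 5000)
  expect_equal(unname(ot$per_sample), c(0.95, 0.95))
})

recurrent_calls_fixture <- function() {
  # 45 included samples; known list covers 2 cells; plant 1 recurrent
  # variant in 9 samples (2 hom) + 3 singleton variants
  samples <- sprintf("S%02d", 1:45)
  calls <- rbind(
    make_pileup(DP = 500L, alt = 250L, sample_id = "S01",
                mutation_id = "Mknown", target_id = "T1"),
    do.call(rbind, lapply(1:9, function(i)
      make_pileup(DP = 500L, alt = if (i <= 2) 495L else 250L,
                  sample_id = samples[i + 1], mutation_id = "Mrec",
                  target_id = "T2"))),
    do.call(rbind, lapply(1:3, function(i)
      make_pileup(DP = 400L, alt = 200L, sample_id = samples[20 + i],
                  mutation_id = paste0("Msing", i),
                  target_id = paste0("T", 2 + i)))))
  list(calls = call_genotypes(calls), samples = samples,
       known = data.frame(sample_id = "S01", mutation_id = "Mknown"))
}

test_that("recurrent flagging partitions unexpected calls (recount oracle)", {
  fx <- recurrent_calls_fixture()
  rep <- flag_recurrent(fx$calls, fx$known, fx$samples)
  expect_equal(rep$counts$total_unexpected, 12L)       # 9 + 3
  expect_equal(rep$counts$recurrent_attributed, 9L)
  expect_equal(rep$counts$singleton, 3L)
  expect_equal(rep$counts$total_unexpected,
               rep$counts$recurrent_attributed + rep$counts$singleton)
  f <- rep$flags
  expect_true(f$flagged_benign_candidate[f$mutation_id == "Mrec"])
  expect_equal(f$n_hom[f$mutation_id == "Mrec"], 2L)
  expect_equal(f$cohort_fraction[f$mutation_id == "Mrec"], 9 / 45)
  expect_true(all(!f$flagged_benign_candidate[grepl("Msing",
                                                    f$mutation_id)]))
  # no unexpected plantings -> empty partition
  none <- flag_recurrent(fx$calls[fx$calls$mutation_id == "Mknown", ],
                         fx$known, fx$samples)
  expect_equal(none$counts$total_unexpected, 0L)
  # homozygosity in two samples flags even below the cohort fraction
  few <- flag_recurrent(fx$calls, fx$known, fx$samples,
                        cohort_fraction_threshold = 0.5)
  expect_true(few$flags$flagged_benign_candidate[
    few$flags$mutation_id == "Mrec"])
})

test_that("the depth heat map ranks targets by mean depth", {
  set.seed(6)
  m0 <- matrix(sample(c(10L, 300L, 900L), 24, TRUE), 8, 3,
               dimnames = list(sprintf("T%02d", 1:8), paste0("S", 1:3)))
  m <- compute_assay_matrix(fake_pileups(m0))
  pdf(NULL)
  on.exit(dev.off())
  out <- plot_assay_matrix(m)
  expect_true(all(diff(rowMeans(out)) >= 0))
  expect_setequal(rownames(out), rownames(m0))
})

test_that("per-sample reports list the identified mutations", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  paths <- write_sample_reports(co$run, co$universe$panel, dir)
  carrier <- co$spec$known_het$sample_id[1]
  rep <- read.delim(file.path(dir, paste0(carrier, "_report.tsv")))
  expect_true(co$spec$known_het$mutation_id[1] %in% rep$mutation_id)
  expect_true(all(c("gene", "disorder", "genotype", "DP", "flags") %in%
                    names(rep)))
  jx_carrier <- co$spec$rearrangement_carriers$sample_id[1]
  repj <- read.delim(file.path(dir, paste0(jx_carrier, "_report.tsv")))
  expect_true("CARRIER_JUNCTION" %in% repj$genotype)
})
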