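# Genotyper: read assignment, haplotype-vote pileups vs the string-match
# oracle, threshold calling, junction detection, VCF output.

test_that("read assignment recovers the ground-truth origin", {
  co <- tiny_cohort()
  u <- co$universe
  geno <- assign_genotypes(u$panel, co$spec)
  sr <- simulate_sample_reads("S03", geno, u$panel, u$amplicons,
                              u$reference, co$eff, co$model,
                              read_sim_params(), seed = 31)
  asg <- assign_reads(list(r1 = sr$r1, r2 = sr$r2), u$amplicons)
  truth <- sub("^S03:([^:]+):.*$", "\\1", names(sr$r1))
  on <- truth != "OFFTGT"
  acc <- mean(asg$amplicon_id[on] == truth[on])
  expect_gte(acc, 0.99)
  # off-target fragments never get claimed at a measurable rate
  expect_lt(mean(asg$amplicon_id[!on] != "OFF_TARGET"), 0.01)
  # random-sequence pairs are OFF_TARGET
  set.seed(1)
  rnd <- list(
    r1 = vapply(1:50, function(i) paste(sample(c("A", "C", "G", "T"), 150,
                                               TRUE), collapse = ""),
                character(1)),
    r2 = vapply(1:50, function(i) paste(sample(c("A", "C", "G", "T"), 150,
                                               TRUE), collapse = ""),
                character(1)))
  asg_rnd <- assign_reads(rnd, u$amplicons)
  expect_true(all(asg_rnd$amplicon_id == "OFF_TARGET"))
})

test_that("assignment tolerates one primer mismatch but not two", {
  u <- tiny_universe()
  amp <- u$amplicons[1, ]
  prod <- ampliscreen:::amplicon_ref_product(amp, u$reference)
  flip <- function(s, at) {
    old <- substr(s, at, at)
    substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), old)[1]
    s
  }
  r1 <- substr(prod, 1, 150)
  one_mm <- flip(r1, 5)
  two_mm <- flip(one_mm, 15)
  junk <- strrep("N", 150)
  asg <- assign_reads(list(r1 = c(r1, one_mm, two_mm),
                           r2 = c(junk, junk, junk)), u$amplicons)
  expect_equal(asg$amplicon_id, c(amp$amplicon_id, amp$amplicon_id,
                                  "OFF_TARGET"))
})

test_that("pileup counts equal the full-haplotype string-match oracle", {
  u <- tiny_universe()
  std <- u$amplicons[!u$amplicons$is_junction, ]
  tl <- ampliscreen:::amplicon_target_list(std)
  once <- names(which(table(unlist(tl)) == 1))
  cand <- u$targets[u$targets$target_id %in% once &
                      u$targets$n_mutations == 1, ]
  for (row in seq_len(min(3, nrow(cand)))) {
    trow <- cand[row, , drop = FALSE]
    mut <- trow$mutation_ids[[1]]
    pm <- u$panel[u$panel$mutation_id == mut, ]
    spec <- planting_none("S01")
    spec$known_het <- data.frame(sample_id = "S01", mutation_id = mut)
    geno <- assign_genotypes(u$panel, spec)
    model <- depth_model(mean_depth_per_assay = 120,
                         off_target_fraction = 0, n_dead_amplicons = 0,
                         poor_amplicon_frac = 0)
    eff <- draw_amplicon_efficiency(u$amplicons, model, 1)
    sr <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                                u$reference, eff, model,
                                read_sim_params(per_base_error = 0),
                                seed = 200 + row)
    asg <- assign_reads(list(r1 = sr$r1, r2 = sr$r2), u$amplicons)
    pil <- pileup_target(list(r1 = sr$r1, r2 = sr$r2), asg, trow,
                         u$panel, u$amplicons, u$reference, "S01")
    amp_row <- std[vapply(tl, function(t) trow$target_id %in% t,
                          logical(1)), ]
    ref_prod <- ampliscreen:::amplicon_ref_product(amp_row, u$reference)
    o <- pm$pos - 1L - amp_row$start
    alt_prod <- paste0(substr(ref_prod, 1, o), pm$alt,
                       substr(ref_prod, o + nchar(pm$ref) + 1L,
                              nchar(ref_prod)))
    oc <- oracle_haplotype_votes(sr$r1, sr$r2, asg, amp_row, ref_prod,
                                 alt_prod, pm$pos)
    expect_equal(pil$ref_count, unname(oc["ref"]))
    expect_equal(pil$alt_count, unname(oc["alt"]))
    expect_equal(pil$other_count, unname(oc["other"]))
    expect_equal(pil$DP, sum(oc))
  }
})

test_that("an inserted TATC het is voted through the insertion context", {
  u <- tiny_universe()
  ins <- u$panel[u$panel$class == "INS", ][1, ]
  expect_true(grepl("TATC", ins$alt))  # forced fixture insertion
  trow <- u$targets[vapply(u$targets$mutation_ids, function(m)
    ins$mutation_id %in% m, logical(1)), ]
  spec <- planting_none("S01")
  spec$known_het <- data.frame(sample_id = "S01",
                               mutation_id = ins$mutation_id)
  geno <- assign_genotypes(u$panel, spec)
  model <- depth_model(mean_depth_per_assay = 200, off_target_fraction = 0,
                       n_dead_amplicons = 0, poor_amplicon_frac = 0)
  eff <- draw_amplicon_efficiency(u$amplicons, model, 1)
  sr <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                              u$reference, eff, model,
                              read_sim_params(per_base_error = 0),
                              seed = 8)
  asg <- assign_reads(list(r1 = sr$r1, r2 = sr$r2), u$amplicons)
  pil <- pileup_target(list(r1 = sr$r1, r2 = sr$r2), asg, trow, u$panel,
                       u$amplicons, u$reference, "S01")
  expect_gt(pil$alt_count, 0)
  expect_equal(pil$ref_count + pil$alt_count + pil$other_count, pil$DP)
  expect_gt(pil$af, 0.40)
  expect_lt(pil$af, 0.60)
})

test_that("uncaptured targets return a structured zero-depth result", {
  u <- tiny_universe()
  trow <- u$targets[1, , drop = FALSE]
  other_amps <- u$amplicons[
    !grepl(trow$target_id, u$amplicons$target_ids), ]
  pil <- pileup_target(list(r1 = character(0), r2 = character(0)),
                       data.frame(pair = integer(0),
                                  amplicon_id = character(0),
                                  reason = character(0),
                                  fwd_read = integer(0)),
                       trow, u$panel, other_amps, u$reference, "S01")
  expect_equal(pil$DP, 0L)
  expect_true(pil$uncaptured)
})

test_that("calling thresholds are inclusive at the published boundaries", {
  th <- call_thresholds()
  calls <- call_genotypes(rbind(
    make_pileup(DP = 519L, alt = 254L),  # AF 0.49
    make_pileup(DP = 500L, alt = 130L),  # AF 0.26
    make_pileup(DP = 49L, alt = 24L),
    make_pileup(DP = 50L, alt = 15L),    # AF 0.30 inclusive
    make_pileup(DP = 100L, alt = 70L),   # AF 0.70 inclusive
    make_pileup(DP = 100L, alt = 75L),   # band gap
    make_pileup(DP = 100L, alt = 85L),   # HOM at 0.85 inclusive
    make_pileup(DP = 100L, alt = 5L)), th)
  expect_equal(calls$genotype,
               c("HET", "REF", "NO_CALL", "HET", "HET", "REF", "HOM",
                 "REF"))
  expect_equal(calls$flags,
               c("", "LOW_AF_SUSPECT", "LOW_DP", "", "", "AF_BAND_GAP",
                 "", ""))
})

test_that("calls move monotonically REF -> HET -> flagged REF -> HOM with alt count", {
  th <- call_thresholds()
  stages <- vapply(0:100, function(alt) {
    cl <- call_genotypes(make_pileup(DP = 100L, alt = alt), th)
    paste(cl$genotype, cl$flags)
  }, character(1))
  codes <- c("REF " = 1, "REF LOW_AF_SUSPECT" = 2, "HET " = 3,
             "REF AF_BAND_GAP" = 4, "HOM " = 5)
  expect_true(all(diff(codes[stages]) >= 0))
  # within the het band an increasing alt count never demotes the call
  expect_true(all(stages[31:71] == "HET "))
})

test_that("unexpected non-REF calls are flagged VALIDATION_REQUIRED", {
  known <- data.frame(sample_id = "S01", mutation_id = "M0001")
  pil <- rbind(make_pileup(DP = 500L, alt = 250L),
               make_pileup(DP = 500L, alt = 240L, sample_id = "S02"))
  calls <- call_genotypes(pil, expected_known = known)
  expect_equal(calls$flags, c("", "VALIDATION_REQUIRED"))
})

test_that("compound heterozygotes at a multi-allelic target are both reported", {
  u <- tiny_universe()
  pair_t <- u$targets[u$targets$n_mutations == 2, ][1, , drop = FALSE]
  mids <- pair_t$mutation_ids[[1]]
  spec <- planting_none("S01")
  spec$known_het <- data.frame(sample_id = "S01", mutation_id = mids)
  geno <- assign_genotypes(u$panel, spec)
  model <- depth_model(mean_depth_per_assay = 300, off_target_fraction = 0,
                       n_dead_amplicons = 0, poor_amplicon_frac = 0)
  eff <- draw_amplicon_efficiency(u$amplicons, model, 1)
  sr <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                              u$reference, eff, model,
                              read_sim_params(per_base_error = 0),
                              seed = 12)
  asg <- assign_reads(list(r1 = sr$r1, r2 = sr$r2), u$amplicons)
  pil <- pileup_target(list(r1 = sr$r1, r2 = sr$r2), asg, pair_t,
                       u$panel, u$amplicons, u$reference, "S01")
  calls <- call_genotypes(pil)
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$genotype == "HET"))
  expect_equal(calls$DP[1], calls$DP[2])
})

test_that("junction detection separates carriers from non-carriers", {
  co <- tiny_cohort()
  u <- co$universe
  jr <- ampliscreen:::junction_references(u$panel, u$reference)[[1]]
  carrier <- co$spec$rearrangement_carriers$sample_id[1]
  jx <- co$run$junction_calls
  expect_true(jx$carrier[jx$sample_id == carrier])
  non <- setdiff(co$spec$sample_ids, carrier)
  expect_true(all(!jx$carrier[jx$sample_id %in% non]))
  expect_true(all(jx$supporting_reads[jx$sample_id %in% non] == 0L))
  # direct call on empty reads
  none <- detect_junction(character(0), jr, sample_id = "SX")
  expect_false(none$carrier)
})

test_that("genotype_run from FASTQ files matches the in-memory run", {
  co <- tiny_cohort()
  u <- co$universe
  out <- withr::local_tempdir()
  sim <- simulate_cohort(u$reference, u$panel, u$amplicons, co$spec,
                         co$model, read_sim_params(), seed = TINY_SEED,
                         out_dir = out, eff = co$eff)
  run2 <- genotype_run(sim$fastq, u$panel, u$amplicons, u$reference,
                       expected_known = co$spec$known_het)
  expect_equal(run2$calls, co$run$calls)
  expect_equal(run2$junction_calls, co$run$junction_calls)
})

test_that("an empty sample yields NO_CALL everywhere", {
  u <- tiny_universe()
  empty <- setNames(character(0), character(0))
  run <- genotype_run(list(S01 = list(r1 = empty, r2 = empty)),
                      u$panel, u$amplicons, u$reference)
  expect_true(all(run$calls$genotype == "NO_CALL"))
  expect_true(all(run$calls$flags == "LOW_DP"))
  expect_equal(run$sample_stats$n_pairs, 0L)
})

test_that("technical replicates give concordant calls at adequate depth", {
  u <- tiny_universe()
  spec <- planting_none(sprintf("S%02d", 1:4))
  pool <- unlist(u$targets$mutation_ids[u$targets$n_mutations == 1])
  spec$known_het <- data.frame(sample_id = "S01",
                               mutation_id = pool[c(2, 4)])
  spec$technical_replicates <- data.frame(source = "S01",
                                          replicate = "S04")
  sc <- screen_cohort(u$reference, u$panel, u$amplicons, spec,
                      tiny_model(), read_sim_params(), call_thresholds(),
                      seed = 19)
  calls <- sc$run$calls
  a <- calls[calls$sample_id == "S01", ]
  b <- calls[calls$sample_id == "S04", ]
  key <- a$DP >= 50 & b$DP[match(paste(a$target_id, a$mutation_id),
                                 paste(b$target_id, b$mutation_id))] >= 50
  bg <- b$genotype[match(paste(a$target_id, a$mutation_id),
                         paste(b$target_id, b$mutation_id))]
  expect_true(all(a$genotype[key] == bg[key]))
  expect_equal(sum(a$genotype == "HET"), 2L)
})

test_that("the VCF writer emits valid v4.2 readable by VariantAnnotation", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$run, co$universe$panel, path)
  v <- VariantAnnotation::readVcf(path)
  nz <- co$run$calls[co$run$calls$genotype %in% c("HET", "HOM"), ]
  expect_equal(nrow(v), length(unique(nz$mutation_id)))
  gt <- VariantAnnotation::geno(v)$GT
  for (k in seq_len(nrow(nz))) {
    expect_equal(unname(gt[nz$mutation_id[k], nz$sample_id[k]]),
                 c(HET = "0/1", HOM = "1/1")[[nz$genotype[k]]])
  }
  pos <- BiocGenerics::start(SummarizedExperiment::rowRanges(v))
  pm <- co$universe$panel[match(rownames(v), co$universe$panel$mutation_id), ]
  expect_equal(unname(pos), pm$pos)
})
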