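# Synthetic universe: reference, fixture structure, genotype planting,
# and the read model's allele-fraction laws.

test_that("reference generation is seeded and hits the configured GC", {
  r1 <- generate_reference(3, 2, 20000)
  r2 <- generate_reference(3, 2, 20000)
  r3 <- generate_reference(4, 2, 20000)
  expect_identical(as.character(r1), as.character(r2))
  expect_false(identical(as.character(r1), as.character(r3)))
  gc <- sum(Biostrings::letterFrequency(r1, "GC")) /
    sum(Biostrings::width(r1))
  expect_lt(abs(gc - 0.41), 0.02)
})

test_that("tiny fixture honours its preset counts and length rules", {
  u <- tiny_universe()
  p <- u$preset
  expect_equal(sum(u$panel$class != "LARGE_REARRANGEMENT"), p$n_mutations)
  expect_equal(sum(u$panel$class == "LARGE_REARRANGEMENT"),
               p$n_junction_amplicons)
  expect_equal(nrow(u$targets),
               p$n_mutations - p$n_same_position_pairs)
  std <- u$amplicons[!u$amplicons$is_junction, ]
  expect_equal(nrow(std), p$n_standard_amplicons)
  # length scan oracle: every non-outlier length within [64, 200]
  expect_true(all(std$length >= 64 & std$length <= 200 |
                    std$is_length_outlier))
  # primers are prefixes of the product strands
  for (i in seq_len(nrow(std))) {
    prod <- ampliscreen:::amplicon_ref_product(std[i, ], u$reference)
    expect_identical(substr(prod, 1, 20), std$fwd_primer[i])
    expect_identical(revcomp(substr(prod, std$length[i] - 19,
                                    std$length[i])), std$rev_primer[i])
  }
  # every target covered; targets fall inside their amplicons
  tl <- ampliscreen:::amplicon_target_list(std)
  expect_setequal(unlist(tl), u$targets$target_id)
  for (i in seq_len(nrow(std))) {
    pos <- u$targets$pos[match(tl[[i]], u$targets$target_id)]
    expect_true(all(pos > std$start[i] & pos <= std$end[i]))
  }
})

test_that("planting spec realisation matches its totals (recount oracle)", {
  co <- tiny_cohort()
  u <- co$universe
  geno <- assign_genotypes(u$panel, co$spec)
  expect_equal(nrow(geno), nrow(co$spec$known_het) +
                 nrow(co$spec$rearrangement_carriers))
  # empty spec -> empty table
  none <- planting_none(co$spec$sample_ids)
  expect_equal(nrow(assign_genotypes(u$panel, none)), 0L)
  # unknown ids are rejected
  bad <- none
  bad$known_het <- data.frame(sample_id = "S01", mutation_id = "MNOPE")
  expect_error(assign_genotypes(u$panel, bad), "unknown mutations")
})

test_that("technical replicates copy genotypes but not noise", {
  u <- tiny_universe()
  spec <- planting_none(sprintf("S%02d", 1:4))
  pool <- unlist(u$targets$mutation_ids[u$targets$n_mutations == 1])
  spec$known_het <- data.frame(sample_id = "S01", mutation_id = pool[1])
  spec$technical_replicates <- data.frame(source = "S01",
                                          replicate = "S02")
  geno <- assign_genotypes(u$panel, spec)
  expect_setequal(geno$sample_id[geno$mutation_id == pool[1]],
                  c("S01", "S02"))
  model <- tiny_model()
  eff <- draw_amplicon_efficiency(u$amplicons, model, 1)
  r1 <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                              u$reference, eff, model, seed = 101)
  r2 <- simulate_sample_reads("S02", geno, u$panel, u$amplicons,
                              u$reference, eff, model, seed = 102)
  expect_false(identical(unname(r1$r1), unname(r2$r1)))
})

test_that("heterozygous mutant fraction follows the binomial law", {
  u <- tiny_universe()
  mut <- unlist(u$targets$mutation_ids[u$targets$n_mutations == 1])[2]
  pil <- het_af_at(u, mut, depth = 1000, error = 0)
  expect_equal(pil$other_count, 0L)          # error-free conservation
  expect_equal(pil$ref_count + pil$alt_count, pil$DP)
  expect_gt(pil$af, 0.45)
  expect_lt(pil$af, 0.55)
})

test_that("homozygous targets give mutant fraction 1 at error 0", {
  u <- tiny_universe()
  mut <- unlist(u$targets$mutation_ids[u$targets$n_mutations == 1])[3]
  spec <- planting_none("S01")
  spec$recurrent <- list(list(mutation_id = mut, carriers = "S01",
                              hom = "S01"))
  geno <- assign_genotypes(u$panel, spec)
  model <- depth_model(mean_depth_per_assay = 300, off_target_fraction = 0,
                       n_dead_amplicons = 0, poor_amplicon_frac = 0)
  eff <- draw_amplicon_efficiency(u$amplicons, model, 1)
  sr <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                              u$reference, eff, model,
                              read_sim_params(per_base_error = 0),
                              seed = 5)
  asg <- assign_reads(list(r1 = sr$r1, r2 = sr$r2), u$amplicons)
  trow <- u$targets[vapply(u$targets$mutation_ids, function(m)
    mut %in% m, logical(1)), ]
  pil <- pileup_target(list(r1 = sr$r1, r2 = sr$r2), asg, trow, u$panel,
                       u$amplicons, u$reference, "S01")
  expect_equal(pil$af[pil$mutation_id == mut], 1)
})

test_that("even-ratio paralog dilution halves the het mutant fraction", {
  u <- tiny_universe()
  # a paralog-eligible SNV at a singly-covered target
  std <- u$amplicons[!u$amplicons$is_junction, ]
  tl <- ampliscreen:::amplicon_target_list(std)
  once <- names(which(table(unlist(tl)) == 1))
  cand <- u$targets[u$targets$target_id %in% once &
                      u$targets$n_mutations == 1, ]
  muts <- unlist(cand$mutation_ids)
  mut <- muts[u$panel$class[match(muts, u$panel$mutation_id)] == "SNV"][1]
  afs <- vapply(1:3, function(s)
    het_af_at(u, mut, depth = 600, error = 0, paralog = mut,
              seed = s)$af, numeric(1))
  se <- sqrt(0.25 * 0.75 / 600)
  expect_true(all(abs(afs - 0.25) < 3 * se + 0.01))
  # enrichment mode pushes the fraction up instead
  af_enrich <- het_af_at(u, mut, depth = 600, error = 0, paralog = mut,
                         seed = 1, mode = "enrich")$af
  expect_gt(af_enrich, 0.6)
})

test_that("read accounting is conserved and seeded reruns are identical", {
  co <- tiny_cohort()
  u <- co$universe
  geno <- assign_genotypes(u$panel, co$spec)
  a <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                             u$reference, co$eff, co$model, seed = 77)
  b <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                             u$reference, co$eff, co$model, seed = 77)
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_equal(a$truth$n_on_target + a$truth$n_off_target,
               a$truth$n_total)
  expect_equal(sum(a$truth$per_amplicon), a$truth$n_on_target)
  # read names encode the ground-truth origin
  origins <- sub("^S01:([^:]+):.*$", "\\1", names(a$r1))
  expect_setequal(setdiff(origins, "OFFTGT"),
                  names(a$truth$per_amplicon)[a$truth$per_amplicon > 0])
})

test_that("cohort FASTQ output round-trips and manifest totals match", {
  co <- tiny_cohort()
  u <- co$universe
  out <- withr::local_tempdir()
  sim <- simulate_cohort(u$reference, u$panel, u$amplicons, co$spec,
                         co$model, read_sim_params(), seed = TINY_SEED,
                         out_dir = out, eff = co$eff)
  expect_equal(nrow(sim$fastq), co$spec$n_samples)
  expect_true(all(file.exists(sim$fastq$r1), file.exists(sim$fastq$r2)))
  rr <- read_fastq_pair(sim$fastq$r1[1], sim$fastq$r2[1])
  expect_equal(length(rr$r1), sim$manifest$per_sample[["S01"]]$n_total)
  expect_identical(names(rr$r1), names(rr$r2))
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_targets, nrow(u$targets))
  expect_equal(nrow(man$known_het), nrow(co$spec$known_het))
})
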