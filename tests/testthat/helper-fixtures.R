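# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

TINY_SEED <- 7L

tiny_universe <- function() {
  cached("tiny", function() {
    preset <- fixture_preset("tiny")
    ref <- generate_reference(TINY_SEED, preset$reference$n_chrom,
                              preset$reference$chrom_len)
    fx <- generate_panel_fixture(ref, preset, TINY_SEED)
    list(preset = preset, reference = ref, panel = fx$panel,
         amplicons = fx$amplicons, targets = collapse_targets(fx$panel))
  })
}

# A quiet depth model for tiny runs: no dead/poor amplicons, so every
# planted genotype is observable.
tiny_model <- function(...) {
  depth_model(mean_depth_per_assay = 200L, n_dead_amplicons = 0L,
              poor_amplicon_frac = 0, ...)
}

# Tiny cohort with two planted het carriers and one rearrangement carrier.
tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    u <- tiny_universe()
    model <- tiny_model()
    eff <- draw_amplicon_efficiency(u$amplicons, model, TINY_SEED)
    spec <- ampliscreen:::planting_for_preset("tiny", u$panel, u$amplicons,
                                              eff, TINY_SEED)
    sc <- screen_cohort(u$reference, u$panel, u$amplicons, spec, model,
                        read_sim_params(), call_thresholds(),
                        seed = TINY_SEED, eff = eff)
    c(sc, list(spec = spec, eff = eff, model = model, universe = u))
  })
}

# A small hand-made amplicon table for pooling tests.
make_amps <- function(chrom, start, length, gc = 0.45,
                      id = sprintf("A%03d", seq_along(start))) {
  n <- length(start)
  data.frame(amplicon_id = id, chrom = rep_len(chrom, n), start = start,
             end = start + length, fwd_primer = strrep("A", 20),
             rev_primer = strrep("T", 20), length = length,
             gc_fraction = rep_len(gc, n),
             target_ids = rep("T0001", n), is_junction = FALSE,
             is_length_outlier = length < 64 | length > 200,
             stringsAsFactors = FALSE)
}

# Minimal single-row panel constructor.
make_mut <- function(mutation_id = "M0001", gene = "GENE001",
                     disorder = "DIS001", chrom = "chr1", pos = 100L,
                     ref = "A", alt = "G", class = "SNV",
                     breakpoint1 = NA_integer_, breakpoint2 = NA_integer_,
                     inserted_seq = "", label = "") {
  df <- data.frame(mutation_id = mutation_id, gene = gene,
                   disorder = disorder, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, class = class,
                   breakpoint1 = breakpoint1, breakpoint2 = breakpoint2,
                   inserted_seq = inserted_seq, label = label,
                   stringsAsFactors = FALSE)
  ampliscreen:::new_mutation_panel(df)
}

# Simulate one het carrier at a chosen mutation and return its pileup row
# (near-deterministic depth, no off-target noise).
het_af_at <- function(u, mutation_id, depth, error, paralog = character(0),
                      seed = 1, mode = "dilute") {
  spec <- planting_none("S01")
  spec$known_het <- data.frame(sample_id = "S01", mutation_id = mutation_id)
  spec$paralog_mutations <- paralog
  geno <- assign_genotypes(u$panel, spec)
  model <- depth_model(mean_depth_per_assay = depth, dispersion = 1e6,
                       off_target_fraction = 0, n_dead_amplicons = 0,
                       poor_amplicon_frac = 0, efficiency_sdlog = 1e-9)
  eff <- draw_amplicon_efficiency(u$amplicons, model, 1)
  sr <- simulate_sample_reads("S01", geno, u$panel, u$amplicons,
                              u$reference, eff, model,
                              read_sim_params(per_base_error = error),
                              paralog_mutations = paralog, seed = seed,
                              paralog_mode = mode)
  asg <- assign_reads(list(r1 = sr$r1, r2 = sr$r2), u$amplicons)
  trow <- u$targets[vapply(u$targets$mutation_ids, function(m)
    mutation_id %in% m, logical(1)), ]
  pil <- pileup_target(list(r1 = sr$r1, r2 = sr$r2), asg, trow, u$panel,
                       u$amplicons, u$reference, "S01")
  pil[pil$mutation_id == mutation_id, ]
}

# A paralog-eligible SNV (single amplicon, single allele) of a universe.
paralog_candidate <- function(u) {
  std <- u$amplicons[!u$amplicons$is_junction, ]
  tl <- ampliscreen:::amplicon_target_list(std)
  once <- names(which(table(unlist(tl)) == 1))
  cand <- u$targets[u$targets$target_id %in% once &
                      u$targets$n_mutations == 1, ]
  muts <- unlist(cand$mutation_ids)
  muts[u$panel$class[match(muts, u$panel$mutation_id)] == "SNV"][1]
}

# The pilot-cohort study run (paper-scale fixture, positive-control
# planting), computed once and cached; used by the acceptance suite.
PILOT_SEED <- 1L

pilot_run <- function() {
  cached("pilot", function() {
    preset <- fixture_preset("paper-scale")
    ref <- generate_reference(PILOT_SEED, preset$reference$n_chrom,
                              preset$reference$chrom_len)
    fx <- generate_panel_fixture(ref, preset, PILOT_SEED)
    model <- depth_model()
    eff <- draw_amplicon_efficiency(fx$amplicons, model, PILOT_SEED)
    spec <- planting_preset("pilot-cohort", fx$panel, fx$amplicons, eff,
                            PILOT_SEED)
    sc <- screen_cohort(ref, fx$panel, fx$amplicons, spec, model,
                        read_sim_params(), call_thresholds(),
                        seed = PILOT_SEED, eff = eff)
    m <- compute_assay_matrix(sc$run$pileups)
    rc <- setNames(sc$run$sample_stats$n_pairs,
                   sc$run$sample_stats$sample_id)
    excl <- exclude_samples(rc, m)
    included <- excl$sample_id[!excl$excluded]
    list(reference = ref, panel = fx$panel, amplicons = fx$amplicons,
         preset = preset, model = model, eff = eff, spec = spec,
         run = sc$run, manifest = sc$manifest, matrix = m,
         exclusions = excl, included = included)
  })
}

# Pileup row constructor for calling tests.
make_pileup <- function(DP, alt, ref = DP - alt, other = DP - alt - ref,
                        target_id = "T0001", sample_id = "S01",
                        mutation_id = "M0001") {
  data.frame(target_id = target_id, sample_id = sample_id,
             mutation_id = mutation_id, DP = DP, ref_count = ref,
             alt_count = alt, other_count = other,
             af = if (DP > 0) alt / DP else NA_real_, uncaptured = FALSE,
             stringsAsFactors = FALSE)
}
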