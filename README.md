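# ampliscreen

Desk-scale toolkit for **multiplex-PCR targeted amplicon carrier
screening**: the workflow in which a panel of known recessive-disease
mutations is PCR-captured from dozens of DNA samples on a microfluidic
chip, sequenced with short paired-end reads, and genotyped per
(mutation, sample) assay. The package is aimed at assay developers and
bioinformaticians who want to design, stress-test and reason about such
pipelines — panel bookkeeping, primer-pool multiplexing, expected allele
fractions, QC failure modes — on fully synthetic, reproducible data
before any wet-lab work.

## What it implements

- **Panel model.** Mutations (SNVs, anchor-base indels, large
  rearrangements with known breakpoints) are collapsed into unique
  genomic *target positions*: distinct pathogenic alleles at the same
  nucleotide count as one position (370 mutations → 368 positions in the
  shipped paper-scale preset). Rearrangements get chimeric *junction
  references* whose core k-mer (junction ± 20 bp) provably cannot occur
  in a non-carrier genome.
- **Pool multiplexing.** Primer pairs are assigned to ≤ 48 pools of
  ≤ 12 by a deterministic greedy colouring of a conflict graph: products
  on one chromosome must not overlap or sit < 5 kb apart, pool product
  lengths stay within ±20 % of the pool mean, pool GC span ≤ 15 points.
- **Read simulator.** Per-assay fragment counts are
  NegBin(μ = 500 · ε_amplicon); heterozygote mutant fragments are
  Binomial(n, ½); 5 % of fragments are off-target; 150 bp paired reads
  carry per-base errors and ground-truth names. Paralog-shadowed loci
  (think GBA/GBAP1) draw half of their fragments from a co-captured
  paralog haplotype, diluting a het's expected mutant allele fraction
  (AF) to 0.25.
- **Genotyper.** Primer-anchored read assignment (≤ 1 mismatch) replaces
  alignment; targets are genotyped by exact haplotype-context voting.
  Calls: DP < 50 → NO_CALL; AF ∈ [0.30, 0.70] → HET; AF ≥ 0.85 → HOM;
  AF ∈ [0.15, 0.30) → REF + `LOW_AF_SUSPECT`. Junction carriers need
  ≥ 10 reads containing the junction k-mer.
- **Run QC.** Target × sample depth matrix, sample exclusion (total
  reads < 1 % of the others' median; > 40 targets under 10×),
  conclusiveness and on-target metrics, and recurrent-variant flagging
  (cohort fraction ≥ 10 % or ≥ 2 homozygotes → benign-polymorphism
  candidate).

## Worked example

```r
library(ampliscreen)

reference <- generate_reference(seed = 42, n_chrom = 2, chrom_len = 60000)
fx <- generate_panel_fixture(reference, fixture_preset("tiny"), seed = 42)
print(fx$panel)
#> mutation panel: 13 mutations in 6 genes (5 disorders)
#>   classes: SNV=12 INS=0 DEL=0 LARGE_REARRANGEMENT=1
nrow(collapse_targets(fx$panel))
#> [1] 11        # 12 small mutations, one same-position allele pair

plan <- assign_pools(fx$amplicons[!fx$amplicons$is_junction, ])
print(plan)
#> pooling plan: 11 amplicons in 4 pools (sizes 1-5)
nrow(validate_pooling(plan, fx$amplicons[!fx$amplicons$is_junction, ]))
#> [1] 0         # no constraint violations

# plant two het carriers and one rearrangement carrier, then screen
model <- depth_model(mean_depth_per_assay = 200,
                     n_dead_amplicons = 0, poor_amplicon_frac = 0)
eff <- draw_amplicon_efficiency(fx$amplicons, model, seed = 42)
targets <- collapse_targets(fx$panel)
spec <- planting_none(sprintf("S%02d", 1:4))
pool <- unlist(targets$mutation_ids[targets$n_mutations == 1])
spec$known_het <- data.frame(sample_id = c("S01", "S02"),
                             mutation_id = pool[c(1, 5)])
spec$rearrangement_carriers <- data.frame(
  sample_id = "S03",
  mutation_id = fx$panel$mutation_id[fx$panel$class == "LARGE_REARRANGEMENT"][1])

sc <- screen_cohort(reference, fx$panel, fx$amplicons, spec, model,
                    seed = 42, eff = eff)
print(sc$run)
#> screening run: 4 samples, 11 targets; 2 HET and 0 HOM calls
#>   rearrangement carriers: 1
subset(sc$run$calls, genotype %in% c("HET", "HOM"),
       select = c(sample_id, mutation_id, DP, af, genotype))
#>    sample_id mutation_id   DP        af genotype
#> 1        S01       M0001 1622 0.4790382      HET
#> 17       S02       M0005  320 0.5031250      HET
subset(sc$run$junction_calls, carrier)
#>   mutation_id sample_id supporting_reads carrier
#> 3       M0013       S03               85    TRUE

print(coverage_metrics(compute_assay_matrix(sc$run$pileups)))
#> assays: 48 (mutations x samples, all) / 48 (included)
#>         44 (positions x samples, all) / 44 (included)
#> 100.0% of assays >= 50x; mean assay depth 402x
#> 100.0% of targets >= 50x in all included samples
#> minimum per-sample conclusive rate 100.0%
```

Both planted heterozygotes are called HET at AF ≈ 0.5, the junction
carrier is detected from 85 reads containing the breakpoint k-mer, and
the 11 positions × 4 samples run is fully conclusive. The
mutations × samples vs positions × samples accounting (48 vs 44) is
reported in both conventions because multi-allelic positions make the
two differ.

## Package layout

| Where | What |
|---|---|
| `R/panel.R` | panel I/O, target collapsing, junction references, BED |
| `R/pooling.R` | conflict graph, greedy pool assignment, validator |
| `R/simulate.R` | reference/fixture generators, planting, read simulation |
| `R/genotype.R` | read assignment, pileup voting, calling, junctions, VCF |
| `R/qc.R` | depth matrix, exclusions, metrics, recurrent flags, reports |
| `R/pipeline.R` | config, fused cohort driver, end-to-end runner |
| `src/` | Rcpp kernels: read synthesis, primer index, context voting |
| `vignettes/` | methods vignette (model, parameters, design choices) |
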