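---
title: "Methods: desk-scale multiplex amplicon carrier screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale multiplex amplicon carrier screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`ampliscreen` re-implements, at desk scale, the computational side of a
preconception carrier-screening assay built on multiplex-PCR target
capture of a panel of known disease mutations followed by short-read
sequencing. The pipeline has five parts:

1. **Panel model.** A panel row is one targetable mutation: SNV, short
   insertion/deletion (VCF-style anchor-base alleles), or a large
   rearrangement with characterised breakpoints. Distinct pathogenic
   alleles at the same genomic nucleotide are *collapsed* into one target
   position — depth and capture are a property of the position, while
   calls remain per allele. Rearrangements are not positional targets at
   all; they are probed through *junction references*, chimeric sequences
   spanning the mutant breakpoint that cannot occur in a non-carrier
   genome. Each junction reference carries a core k-mer straddling the
   junction with at least 20 bases on each side; construction verifies,
   on both strands, that this k-mer is absent from the unmutated
   reference.

2. **Pool multiplexing.** Primer pairs are assigned to chip inlets
   (pools) under compatibility constraints: same-chromosome products must
   not overlap nor lie within 5 kb of each other (strictly less than
   5,000 bp conflicts; exactly 5,000 bp is allowed), member product
   lengths must stay within ±20 % of the pool's mean length, the pool's
   product-GC span must stay within 15 percentage points, and a pool
   holds at most 12 pairs on a 48-inlet chip. Assignment is a
   deterministic greedy first-fit colouring of the conflict graph:
   amplicons ordered by conflict degree (descending), then length
   (descending), then id; each is placed in the first pool where every
   constraint still holds. Determinism (no randomness, lexical
   tie-breaks) makes plans byte-reproducible; an exhaustive validator
   re-checks every constraint from scratch.

3. **Read simulation.** Per (amplicon, sample), the fragment count is
   negative-binomial around `mean_depth_per_assay` times a per-amplicon
   capture efficiency. Each fragment is drawn uniformly from the sample's
   two haplotypes, so a heterozygote's mutant fragment count is
   Binomial(n, 1/2). Paired 150 bp reads are cut from the two template
   ends (read-through trimmed to the product), substitution errors are
   applied per base, and a configurable fraction of fragments comes from
   random genome positions (off-target). Read names encode the
   ground-truth origin so any caller can be scored against the manifest
   without re-parsing FASTQs.

4. **Genotyping.** Read pairs are assigned to amplicons by primer
   prefixes (at most one mismatch, pigeonhole-indexed), a desk-scale
   replacement for genome alignment that is exact for a panel-anchored
   assay. Each target is then genotyped by *haplotype-context voting*: a
   read spanning the target window votes for the reference or an
   alternative context (the ±15 bp window with the allele applied) it
   contains exactly; indels vote through the same mechanism over the
   adjacent interval, which subsumes local realignment for panel-anchored
   positions. Calls: depth < 50 is NO_CALL; allele fraction within
   [0.30, 0.70] (inclusive) is HET; ≥ 0.85 is HOM; [0.15, 0.30) is REF
   flagged `LOW_AF_SUSPECT`; (0.70, 0.85) is REF flagged `AF_BAND_GAP`.
   Junction carriers are called by counting reads containing the junction
   core k-mer as an exact substring on either strand (≥ 10 supporting
   reads by default).

5. **QC and reporting.** The targets × samples depth matrix drives all
   run metrics. Samples are excluded when their total reads fall below
   1 % of the median of the other samples (`LOW_READS`) or when more than
   40 targets sit below 10× (`MANY_LOW_TARGETS`); exclusions precede all
   metrics. Coverage metrics report the fraction of assays ≥ 50×, the
   fraction of targets ≥ 50× in every included sample, per-sample
   conclusive rates and their minimum, and the on-target read fraction.
   Non-REF calls absent from the expected-known list are "unexpected";
   variants carried by ≥ 10 % of the included cohort, or homozygous in
   ≥ 2 samples, are flagged as benign-polymorphism candidates, and the
   unexpected calls are partitioned into recurrent-attributed and
   singleton (the latter flagged `VALIDATION_REQUIRED`, modelling Sanger
   confirmation as a flag rather than wet-lab work).

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_dp` | 50 | reads | conclusive-call threshold; "at least 50×" is inclusive |
| `het_af_low/high` | 0.30 / 0.70 | fraction | inclusive het band, symmetric around 1/2 |
| `hom_af_min` | 0.85 | fraction | the assay defines no hom criterion; chosen clear of the het band, GATK-like, configurable |
| `suspect_af_low` | 0.15 | fraction | floor of the sub-het suspicious band (paralog-dilution signature sits near 0.25) |
| `min_junction_support` | 10 | reads | junction assays are under-amplified; 10 exact 40-mer hits are unambiguous |
| `min_gap_bp` | 5000 | bp | strict proximity conflict between co-pooled products |
| `size_tolerance` | 0.20 | fraction | per-pool product-size homogeneity |
| `gc_span_max` | 15 | GC points | "high GC variability" is unquantified upstream; a 15-point max–min span is the testable reading, configurable |
| `max_pool_size` / `max_pools` | 12 / 48 | — | chip geometry |
| `mean_depth_per_assay` | 500 | fragments | desk-scale stand-in for the multi-thousand-fold depths of a production run; one fragment yields two reads, so read depth at a target is roughly 1–2× this |
| `dispersion` | 20 | NB size | moderate per-cell overdispersion |
| `off_target_fraction` | 0.05 | fraction | matches the assay's ~95 % on-target specificity |
| `per_base_error` | 0.001 | /base | Q30-scale substitution noise |

# What the generator emulates — and what it does not

The `paper-scale` preset reproduces the *structure* of the published
assay: 370 small mutations (about 15 % indels) in 148 genes and 120
disorders, exactly two same-position allele pairs (one substitution pair,
one substitution+insertion pair, so 368 target positions), 345 standard
amplicons of 64–200 bp — 43 covering two targets and 20 redundantly
re-covering an already-covered target — plus four junction amplicons for
large rearrangements (5 kb, 6.7 kb and 12 kb deletions and a 353 bp
insertion), the 6.7 kb deletion's junction amplicon being the single
418 bp length outlier, across 48 samples. Canonical indel fixtures (a
4 bp TATC insertion, a 3 bp deletion) are always planted in the panel.

Depth heterogeneity is modelled at the *amplicon* level: log-normal
capture efficiency, with three dead amplicons (capture failure) and
~1.5 % systematically poor ones, because in the emulated assay
low-coverage targets were consistent across samples rather than random
per cell; per-cell dropout is therefore available but defaults to 0. The
`pilot-cohort` planting adds 50 known heterozygous carriers across 40
samples (two at paralog-dilution loci), 15 unexpected singleton carriers,
four recurrent variants in 7, 8, 11 and 23 samples (with 2 and 5
homozygotes among the first and last — the homozygosity pattern of the
real cohort's recurrent polymorphisms), five rearrangement carriers over
three of the four junction mutations, and three engineered QC failures
(two read-starved samples at 0.3 % of normal yield, one sample with 44
dropout targets). Plantings are restricted to positions whose best
amplicon efficiency is workable, as positive controls in a real pilot sit
at captured positions by construction.

Paralog interference is modelled as *reference-allele dilution*: at a
paralog locus half of all fragments are drawn from a co-captured paralog
haplotype carrying the reference base, so a heterozygote's expected
mutant fraction is 0.25 and the call degrades to REF + `LOW_AF_SUSPECT`
— the false-negative mode of pseudogene-shadowed genes such as GBA/GBAP1.
The source material is arithmetically self-contradictory here: even-ratio
capture of a pseudogene whose *normal* base equals the mutant allele
would push the fraction toward 0.75, not the observed ~26 %. The
simulator does not resolve the biology; it exposes both models
(`paralog_mode = "dilute"` (default) or `"enrich"`) and the default is
the one consistent with the observed fraction.

What synthetic data cannot show: real primer thermodynamics and dimer
interactions (not modelled; the conflict graph covers only positional
constraints), context-dependent sequencing error and indel errors
(substitutions only), real pseudogene sequence similarity (the paralog is
modelled as an allele-fraction process, not as a second locus with its
own sequence), contamination, and any clinical content. Passing tests
demonstrate the pipeline's internal correctness and its behaviour under
the modelled failure modes — not performance on clinical libraries.

# Numerical and design choices

- **Coordinates.** Panel TSV and VCF are 1-based; BED and all internal
  interval arithmetic 0-based half-open.
- **Assay accounting.** Counting conventions differ between
  mutations × samples (370 × 48 = 17,760; 370 × 45 = 16,650 after
  exclusion) and positions × samples (368 × 48 = 17,664). The upstream
  report mixes the two; `assay_accounting()` reports both, labelled,
  rather than silently choosing.
- **Size rule.** "Within 20 % of the average size" is read as a
  pool-level constraint (each member within ±20 % of its pool's mean,
  re-checked on every insertion), since an average implies a pool
  aggregate; a panel-level switch (`size_rule = "panel"`) is provided.
- **Junction targets** are kept as a separate, always-reported class
  (they are excluded from the positional target count and depth matrix),
  because the upstream analysis both excluded them from its headline
  accounting and reported their carriers.
- **Voting windows.** Context windows are ±15 bp with a 12 bp slack in
  the span test so that indel allele-length changes never truncate a
  counted read's context; with error-free reads this makes
  ref + alt + other = DP exact and "other" empty. A read matching no
  context (or, pathologically, several) counts as `other`, never as
  evidence.
- **Seeding.** Every stage derives its own 32-bit sub-seed from the
  master seed (`derive_seed(seed, stage, index)`), so stages are
  independently reproducible and whole runs are byte-identical.
- **Degenerate inputs.** Header-only panels load with a warning; empty
  target lists refuse BED export; uncaptured targets yield a structured
  zero-depth pileup (NO_CALL downstream) rather than an error; an
  all-empty FASTQ sample produces NO_CALL everywhere.

# Problem sizes

The shipped study conditions are desk-scale by design: a 3.2 Mb
four-chromosome synthetic genome, 48 samples at ~500 fragments per assay
(≈ 190,000 read pairs per sample), which a full pipeline run processes
in a few minutes on one CPU. The `tiny` preset (12 mutations, 4 samples,
2 × 60 kb genome) runs end to end in seconds and backs most unit tests.

# Known limitations

- The greedy pool assignment is a heuristic; it is validated to be
  constraint-clean and close to optimal on small instances, but is not a
  minimum colouring.
- Phasing is out of scope; multi-allelic compound heterozygotes are
  reported per allele without phase.
- X-linked loci are carried as metadata only; all samples are treated as
  diploid.
- The VCF writer emits one multi-sample VCF of non-REF calls;
  per-(variant, sample) detail lives in the FORMAT fields and per-sample
  report TSVs.
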