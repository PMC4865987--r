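Package: ampliscreen
Title: Targeted Amplicon Carrier-Screening Simulation, Pooling and Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for multiplex-PCR targeted amplicon
    resequencing in preconception carrier screening. Compiles mutation
    panels and collapses co-located alleles into target positions, builds
    chimeric junction references for large rearrangements, assigns primer
    pairs to multiplex pools under compatibility constraints
    (overlap/proximity, product-size tolerance, GC span), simulates
    paired-end amplicon reads with depth, error, off-target and
    pseudogene-interference models, genotypes samples by primer-anchored
    read assignment and haplotype-vote pileups with depth and
    allele-fraction thresholds, detects breakpoint junctions by exact
    k-mer match, and computes run-level QC (assay depth matrix, sample
    exclusion, conclusiveness, recurrent-variant flagging) and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
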