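# End-to-end orchestration: configuration, the fused simulate+genotype
# cohort driver, and the reproducible run directory layout used by the
# command-line interface.

#' Build a run configuration
#'
#' @param preset fixture/planting preset (`"paper-scale"`,
#'   `"pilot-cohort"`, `"tiny"`)
#' @param seed master seed for every stochastic stage
#' @param out_dir output directory
#' @param thresholds [call_thresholds()]
#' @param pooling [pooling_params()]
#' @param depth [depth_model()]
#' @param sim [read_sim_params()]
#' @param rules [qc_rules()]
#' @param paralog_mode `"dilute"` or `"enrich"`
#' @param write_fastq also write per-sample FASTQ pairs
#' @param fastq_dir ingest user FASTQs from this directory instead of
#'   simulating (expects `<sample>_R1.fastq.gz` / `_R2`), with
#'   `panel_path`/`amplicons_path`/`reference_path` supplied
#' @param reference_path,panel_path,amplicons_path optional fixture
#'   inputs; when NULL the preset fixture is generated
#' @return list of class `run_config`
#' @export
run_config <- function(preset = "tiny", seed = 1L, out_dir = "ampliscreen_run",
                       thresholds = call_thresholds(),
                       pooling = pooling_params(), depth = depth_model(),
                       sim = read_sim_params(), rules = qc_rules(),
                       paralog_mode = "dilute", write_fastq = FALSE,
                       fastq_dir = NULL, reference_path = NULL,
                       panel_path = NULL, amplicons_path = NULL) {
  structure(list(preset = preset, seed = as.integer(seed),
                 out_dir = out_dir, thresholds = thresholds,
                 pooling = pooling, depth = depth, sim = sim,
                 rules = rules, paralog_mode = paralog_mode,
                 write_fastq = write_fastq, fastq_dir = fastq_dir,
                 reference_path = reference_path, panel_path = panel_path,
                 amplicons_path = amplicons_path),
            class = "run_config")
}

#' Validate a run configuration
#' @param config a [run_config()] list
#' @return character vector of violations; empty when the config is valid
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(config$preset %in% c("paper-scale", "pilot-cohort", "tiny"),
      sprintf("unknown preset '%s'", config$preset))
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        !is.na(config$seed) && config$seed >= 0,
      "seed must be a single non-negative integer")
  chk(config$paralog_mode %in% c("dilute", "enrich"),
      "paralog_mode must be 'dilute' or 'enrich'")
  th <- config$thresholds
  ord_ok <- tryCatch({
    do.call(call_thresholds, th[names(th) %in% names(formals(call_thresholds))])
    TRUE
  }, error = function(e) FALSE)
  chk(ord_ok, "thresholds must satisfy 0 < suspect < het_low < het_high < hom <= 1 and positive DP")
  pp_ok <- tryCatch({
    do.call(pooling_params, config$pooling[names(config$pooling) %in%
                                             names(formals(pooling_params))])
    TRUE
  }, error = function(e) FALSE)
  chk(pp_ok, "pooling parameters must be positive with size_tolerance < 1")
  dm_ok <- tryCatch({
    do.call(depth_model, config$depth[names(config$depth) %in%
                                        names(formals(depth_model))])
    TRUE
  }, error = function(e) FALSE)
  chk(dm_ok, "depth model must have positive mean/dispersion and fractions in [0,1]")
  if (!is.null(config$fastq_dir))
    chk(dir.exists(config$fastq_dir),
        sprintf("fastq_dir '%s' does not exist", config$fastq_dir))
  v
}

# Planting for a preset name (tiny gets a minimal planting so that an
# end-to-end smoke run produces calls).
planting_for_preset <- function(preset, panel, amplicons, eff, seed) {
  if (preset %in% c("pilot-cohort", "paper-scale"))
    return(planting_preset("pilot-cohort", panel, amplicons, eff, seed))
  set.seed(derive_seed(seed, 5L))
  samples <- sprintf("S%02d", seq_len(fixture_preset("tiny")$n_samples))
  spec <- planting_none(samples)
  ok <- eligible_targets(amplicons, eff)
  tgt <- collapse_targets(panel)
  single <- tgt[tgt$n_mutations == 1L & tgt$target_id %in% ok, ]
  pool <- unlist(single$mutation_ids)
  if (length(pool) >= 2L) {
    spec$known_het <- data.frame(sample_id = samples[1:2],
                                 mutation_id = sample(pool, 2L),
                                 stringsAsFactors = FALSE)
  }
  lr <- panel$mutation_id[panel$class == "LARGE_REARRANGEMENT"]
  if (length(lr))
    spec$rearrangement_carriers <- data.frame(
      sample_id = samples[1], mutation_id = lr[1],
      stringsAsFactors = FALSE)
  spec
}

#' Simulate and genotype a cohort in one streamed pass
#'
#' Fuses [simulate_cohort()] with [genotype_run()]: each sample's reads
#' are generated, assigned, piled up and discarded before the next
#' sample, so the whole cohort never sits in memory.
#'
#' @param reference genome
#' @param panel `mutation_panel`
#' @param amplicons amplicon data.frame
#' @param spec a `planting_spec`
#' @param model [depth_model()]
#' @param params [read_sim_params()]
#' @param thresholds [call_thresholds()]
#' @param seed master seed
#' @param paralog_mode paralog capture model
#' @param out_dir optional directory for FASTQs + manifest
#' @param eff optional precomputed amplicon efficiencies
#' @return list with `run` (a `screen_run`) and `manifest`
#' @export
screen_cohort <- function(reference, panel, amplicons, spec,
                          model = depth_model(),
                          params = read_sim_params(),
                          thresholds = call_thresholds(), seed = 1L,
                          paralog_mode = "dilute", out_dir = NULL,
                          eff = NULL) {
  targets <- collapse_targets(panel)
  contexts <- target_contexts(panel, targets, reference)
  junction_refs <- junction_references(panel, reference)
  acc <- list()
  sink_fun <- function(sr) {
    acc[[sr$sample_id]] <<- genotype_sample(
      sr$sample_id, list(r1 = sr$r1, r2 = sr$r2), panel, amplicons,
      reference, targets, contexts, junction_refs, thresholds,
      params$read_length)
  }
  sim <- simulate_cohort(reference, panel, amplicons, spec, model, params,
                         seed, out_dir = out_dir, callback = sink_fun,
                         eff = eff, paralog_mode = paralog_mode)
  run <- collect_run(acc[spec$sample_ids], targets, panel, thresholds,
                     expected_known = spec$known_het)
  list(run = run, manifest = sim$manifest)
}

#' Run the whole pipeline end to end
#'
#' Stages: fixture design (reference, panel, amplicons, targets BED),
#' primer-pool assignment with validation, cohort simulation (or FASTQ
#' ingestion) fused with genotyping, QC (depth matrix, exclusions,
#' coverage metrics, on-target fraction, recurrent-variant flagging),
#' and reporting (VCF, per-sample reports, QC JSON, run summary). The
#' exact configuration used is echoed into the output directory; a rerun
#' with the same config reproduces every output byte for byte.
#'
#' @param config a [run_config()] list
#' @return invisibly, the output directory
#' @export
run_end_to_end <- function(config) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config_to_list(config), file.path(out, "config.yaml"))
  seed <- config$seed
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    message(sprintf("[ampliscreen] stage %-12s (seed %d)", name, seed))
    r <- force(expr)
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), s,
                                                  units = "secs")), 2)
    r
  }

  preset <- fixture_preset(if (config$preset == "pilot-cohort")
    "paper-scale" else config$preset)
  fx <- stage("design", {
    if (!is.null(config$panel_path)) {
      list(reference = Biostrings::readDNAStringSet(config$reference_path),
           panel = load_panel(config$panel_path),
           amplicons = load_amplicons(config$amplicons_path))
    } else {
      ref <- generate_reference(seed, preset$reference$n_chrom,
                                preset$reference$chrom_len,
                                preset$reference$gc)
      c(list(reference = ref),
        generate_panel_fixture(ref, preset, seed))
    }
  })
  Biostrings::writeXStringSet(fx$reference, file.path(out, "reference.fa"))
  write_panel(fx$panel, file.path(out, "panel.tsv"))
  write_amplicons(fx$amplicons, file.path(out, "amplicons.tsv"))
  targets <- collapse_targets(fx$panel)
  write_targets_bed(targets, file.path(out, "targets.bed"))

  pooling <- stage("design-pools", {
    std <- fx$amplicons[!fx$amplicons$is_junction, , drop = FALSE]
    plan <- assign_pools(std, params = config$pooling)
    viols <- validate_pooling(plan, std)
    if (nrow(viols)) stop("pool assignment produced violations")
    write_pooling_plan(plan, file.path(out, "pools.tsv"))
    plan
  })

  model <- config$depth
  if (config$preset == "tiny") model$mean_depth_per_assay <- 200L
  screened <- stage("simulate+genotype", {
    if (!is.null(config$fastq_dir)) {
      files <- list.files(config$fastq_dir, "_R1\\.fastq(\\.gz)?$",
                          full.names = TRUE)
      fq <- data.frame(
        sample_id = sub("_R1\\.fastq(\\.gz)?$", "", basename(files)),
        r1 = files, r2 = sub("_R1", "_R2", files),
        stringsAsFactors = FALSE)
      run <- genotype_run(fq, fx$panel, fx$amplicons, fx$reference,
                          config$thresholds,
                          read_len = config$sim$read_length)
      list(run = run, manifest = NULL,
           spec = planting_none(fq$sample_id))
    } else {
      eff <- draw_amplicon_efficiency(fx$amplicons, model, seed)
      spec <- planting_for_preset(config$preset, fx$panel, fx$amplicons,
                                  eff, seed)
      sc <- screen_cohort(fx$reference, fx$panel, fx$amplicons, spec,
                          model, config$sim, config$thresholds, seed,
                          config$paralog_mode,
                          out_dir = if (config$write_fastq)
                            file.path(out, "fastq") else NULL,
                          eff = eff)
      if (!config$write_fastq)
        jsonlite::write_json(sc$manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(sc, list(spec = spec))
    }
  })
  run <- screened$run

  qc <- stage("qc", {
    m <- compute_assay_matrix(run$pileups)
    read_counts <- setNames(run$sample_stats$n_pairs,
                            run$sample_stats$sample_id)
    excl <- exclude_samples(read_counts, m, config$rules)
    included <- excl$sample_id[!excl$excluded]
    metrics <- coverage_metrics(m, included)
    spec_frac <- on_target_fraction(run$sample_stats)
    recurrent <- flag_recurrent(run$calls, screened$spec$known_het,
                                included)
    write_matrix_tsv(m, file.path(out, "assay_matrix.tsv"))
    write_qc_json(metrics, excl, spec_frac, file.path(out, "qc.json"))
    list(matrix = m, exclusions = excl, included = included,
         metrics = metrics, on_target = spec_frac, recurrent = recurrent)
  })

  stage("report", {
    write_vcf(run, fx$panel, file.path(out, "calls.vcf"))
    write_sample_reports(run, fx$panel, file.path(out, "reports"),
                         samples = qc$included)
  })
  summary <- list(
    seed = seed, preset = config$preset,
    n_samples = nrow(run$sample_stats),
    n_targets = nrow(targets),
    n_pools = length(pooling$pools),
    excluded_samples = qc$exclusions$sample_id[qc$exclusions$excluded],
    pct_assays_ge_dp = qc$metrics$pct_assays_ge_dp,
    min_conclusive_pct = qc$metrics$min_conclusive_pct,
    on_target_pooled = qc$on_target$pooled,
    unexpected_counts = qc$recurrent$counts,
    stage_seconds = timings,
    total_seconds = round(as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")), 2))
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

# Strip classes / functions for YAML serialisation.
config_to_list <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}
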