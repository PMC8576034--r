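#' Build a pipeline run configuration
#'
#' Collects the per-stage settings of the end-to-end flow
#' (simulate -> phase -> associate -> select -> read QC -> LOF classify
#' -> co-segregation -> burden) into one validated object.  A
#' configuration can also be read from a YAML file with the same field
#' names ([read_run_config()]); values not given fall back to the
#' defaults below.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_case,n_control Simulated cohort sizes.
#' @param coseg_target Optional haplotype allele string to plant a
#'   co-segregating variant for (`NULL`: none).
#' @param genotypes_file Optional path to an existing genotype TSV; when
#'   set, the simulate stage is skipped and phasing starts from this
#'   file.
#' @param em Named list: `tol`, `max_iter` for [em_estimate()].
#' @param selection Named list: `n_total`, `n_reference`,
#'   `common_freq_threshold` for [select_sequencing_samples()].
#' @param reads Named list: `n_reads`, `read_len`, `adapter`,
#'   `frac_adapter`, `frac_lowq`, `frac_highN` for [simulate_reads()] /
#'   [filter_reads()].
#' @param lof_categories Category set for [classify_lof()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_case = 500L, n_control = 500L,
                       coseg_target = NULL, genotypes_file = NULL,
                       em = list(), selection = list(), reads = list(),
                       lof_categories = default_lof_categories()) {
  em <- utils::modifyList(list(tol = 1e-8, max_iter = 1000L), em)
  selection <- utils::modifyList(
    list(n_total = 16L, n_reference = 2L, common_freq_threshold = 0.005),
    selection)
  reads <- utils::modifyList(
    list(n_reads = 2000L, read_len = 100L, adapter = "AGATCGGAAGAGC",
         frac_adapter = 0.05, frac_lowq = 0.05, frac_highN = 0.05),
    reads)
  structure(list(seed = as.integer(seed), n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 coseg_target = coseg_target,
                 genotypes_file = genotypes_file,
                 em = em, selection = selection, reads = reads,
                 lof_categories = lof_categories),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the whole haplotype-association / LOF-burden pipeline
#'
#' Executes, in order: cohort simulation (or genotype-file ingestion),
#' EM phasing, the haplotype association scan, haplotype-guided sample
#' selection, read simulation and QC filtering, LOF classification, the
#' co-segregation scan against the top-associated haplotype, and the
#' gene-level burden test.  Every stage's table is written to `out_dir`
#' as plain text and collected into `summary.json`; identical
#' configurations produce byte-identical summaries.  Any stage error is
#' re-raised with the stage name prefixed.
#'
#' @param cfg A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("hapburden_run_")) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  log_lines <- c(sprintf("seed: %d", cfg$seed))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  scfg <- stage("simulate", default_sim_config(
    n_case = cfg$n_case, n_control = cfg$n_control, seed = cfg$seed,
    coseg_target = cfg$coseg_target))

  # -- simulate (or ingest) genotypes ---------------------------------
  truth <- NULL
  if (is.null(cfg$genotypes_file)) {
    sim <- stage("simulate", simulate_cohort_genotypes(scfg))
    truth <- sim$truth
    stage("simulate", {
      write_genotype_table(sim$genotypes, file.path(out_dir, "genotypes.tsv"))
      utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
    note("simulate: %d case + %d control individuals", cfg$n_case, cfg$n_control)
    gm <- sim$genotypes
  } else {
    gm <- stage("phase", read_genotype_table(cfg$genotypes_file, scfg$panel))
    note("phase: genotypes read from %s", cfg$genotypes_file)
  }

  # -- phase ----------------------------------------------------------
  fit <- stage("phase", em_estimate(gm, tol = cfg$em$tol,
                                    max_iter = cfg$em$max_iter))
  stage("phase", {
    utils::write.table(fit$freqs, file.path(out_dir, "freqs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fit$phased, file.path(out_dir, "phased.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  note("phase: %d haplotypes, logLik %.6f, %d iterations, dropped %d",
       nrow(fit$freqs), fit$log_likelihood, fit$n_iter, fit$n_dropped)

  # -- associate ------------------------------------------------------
  dosage <- stage("assoc", haplotypes_to_biallelic(fit$phased, fit$freqs))
  scan <- stage("assoc", haplotype_assoc_scan(dosage, fit$phased$cohort))
  stage("assoc", utils::write.table(scan, file.path(out_dir, "assoc.tsv"),
                                    sep = "\t", quote = FALSE, row.names = FALSE))
  top_hap <- scan$hap_id[which.min(scan$p)]
  note("assoc: top haplotype %s (p = %.3g)", top_hap, min(scan$p, na.rm = TRUE))

  # -- select ---------------------------------------------------------
  selected <- stage("select", select_sequencing_samples(
    fit$phased, fit$freqs, top_hap,
    n_total = cfg$selection$n_total,
    common_freq_threshold = cfg$selection$common_freq_threshold,
    n_reference = cfg$selection$n_reference))
  stage("select", utils::write.table(selected, file.path(out_dir, "selected.tsv"),
                                     sep = "\t", quote = FALSE, row.names = FALSE))
  note("select: %d samples (%d case / %d control)", nrow(selected),
       sum(selected$cohort == "case"), sum(selected$cohort == "control"))

  # -- read QC --------------------------------------------------------
  rsim <- stage("readqc", simulate_reads(
    n_reads = cfg$reads$n_reads, read_len = cfg$reads$read_len,
    adapter = cfg$reads$adapter, frac_adapter = cfg$reads$frac_adapter,
    frac_lowq = cfg$reads$frac_lowq, frac_highN = cfg$reads$frac_highN,
    seed = derive_seed(cfg$seed, "reads")))
  qc <- stage("readqc", {
    write_fastq(rsim$reads, file.path(out_dir, "reads.fastq"))
    filter_reads(rsim$reads, adapter = cfg$reads$adapter)
  })
  stage("readqc", write_fastq(qc$clean, file.path(out_dir, "clean.fastq")))
  note("readqc: %d/%d reads kept", qc$report$n_clean, qc$report$n_raw)

  # -- variants: simulate, write, re-read -----------------------------
  vt <- stage("variants", simulate_lof_variants(scfg, selected, truth))
  vt <- stage("variants", {
    write_variant_table(vt, file.path(out_dir, "variants.vcf"),
                        file.path(out_dir, "annotation.tsv"))
    write_cohort_table(vt$samples, file.path(out_dir, "cohorts.tsv"))
    read_variant_table(file.path(out_dir, "variants.vcf"),
                       file.path(out_dir, "annotation.tsv"),
                       file.path(out_dir, "cohorts.tsv"))
  })
  lof <- stage("lof", classify_lof(vt, cfg$lof_categories))
  note("lof: %d LOF sites in %d genes", nrow(lof$sites),
       length(unique(lof$sites$gene)))

  # -- co-segregation scan against the top haplotype ------------------
  target_dosage <- dosage[selected$sample_id, top_hap]
  coseg <- stage("coseg", coseg_scan(lof, target_dosage, target_hap = top_hap))
  stage("coseg", utils::write.table(coseg, file.path(out_dir, "coseg.tsv"),
                                    sep = "\t", quote = FALSE, row.names = FALSE))
  note("coseg: %d co-segregating site(s) with %s", nrow(coseg), top_hap)

  # -- burden ---------------------------------------------------------
  burden <- stage("burden", gene_burden_scan(lof))
  stage("burden", utils::write.table(burden, file.path(out_dir, "burden.tsv"),
                                     sep = "\t", quote = FALSE, row.names = FALSE))
  note("burden: %d genes, %d tested", nrow(burden), sum(burden$tested))

  summary <- list(
    seed = cfg$seed,
    n_case = cfg$n_case, n_control = cfg$n_control,
    phasing = list(n_haplotypes = nrow(fit$freqs),
                   log_likelihood = fit$log_likelihood,
                   n_iter = fit$n_iter, converged = fit$converged,
                   n_dropped = fit$n_dropped),
    haplotype_freqs = fit$freqs,
    haplotype_assoc = scan,
    top_haplotype = top_hap,
    selected_samples = selected,
    read_qc = list(n_raw = qc$report$n_raw, n_clean = qc$report$n_clean,
                   raw_bases = qc$report$raw_bases,
                   clean_bases = qc$report$clean_bases,
                   gc_content = qc$report$gc_content,
                   removed_by = as.list(qc$report$removed_by)),
    coseg_hits = coseg,
    gene_burden = burden)
  json <- jsonlite::toJSON(summary, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  writeLines(json, file.path(out_dir, "summary.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}
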