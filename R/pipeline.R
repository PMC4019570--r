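# Pipeline driver: simulate (optional) -> duplicate filter -> gap repair ->
# call -> evaluate, with ablation switches for the two preprocessing stages
# (the four-way comparison is how the preprocessing is validated).

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed integer master seed (propagated to the simulator unless the
#'   simulation config sets its own).
#' @param input named list of file paths: `reads` (SAM/BAM), `ref` (FASTA),
#'   `bed` (target regions), `truth_vcf`, `wgs_control`,
#'   `genotyping_control`, `known_sites` — any may be `NULL`. When `reads`
#'   is `NULL` a simulation supplies reads, reference, target and truth.
#' @param simulate a [sim_config()] (used when `input$reads` is `NULL`).
#' @param rdast_enabled,aos_enabled ablation switches.
#' @param rdast,aos,caller stage configurations.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("ionsnp_run_"), seed = 1L,
                            input = list(), simulate = sim_config(seed = seed),
                            rdast_enabled = TRUE, aos_enabled = TRUE,
                            rdast = rdast_config(), aos = aos_config(),
                            caller = caller_config()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), input = input,
                 simulate = simulate, rdast_enabled = isTRUE(rdast_enabled),
                 aos_enabled = isTRUE(aos_enabled), rdast = rdast, aos = aos,
                 caller = caller),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stage order is fixed: duplicate filter, then gap repair, then calling —
#' each stage reading the previous stage's output. All artifacts
#' (`dedup.sam`, `aos.sam`, `calls.vcf`, `report.tsv`, per-stage stats TSVs)
#' and a JSON copy of the configuration are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param caller_hook optional function `(reads, ref, caller_cfg, regions)`
#'   returning a variant `data.table`; substitute a real variant caller for
#'   the built-in one here.
#' @return `list(calls=, report=, stats=, paths=)`.
#' @export
run_pipeline <- function(config = pipeline_config(), caller_hook = NULL) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.json"))
  inp <- config$input
  truth <- NULL
  if (is.null(inp$reads)) {
    sim <- simulate_run(config$simulate, out_dir = file.path(out_dir, "sim"))
    reads <- sim$reads; ref <- sim$ref; regions <- sim$target
    truth <- sim$truth
  } else {
    reads <- read_alignments(inp$reads)
    ref <- read_reference(inp$ref)
    regions <- if (!is.null(inp$bed)) read_regions(inp$bed) else NULL
    if (!is.null(inp$truth_vcf)) truth <- read_variants(inp$truth_vcf)
  }
  stats <- list(reads_in = nrow(reads))

  if (config$rdast_enabled) {
    rd <- run_rdast(reads, config$rdast)
    reads <- rd$reads
    stats$rdast <- rd$stats
    fwrite(as.data.table(rd$stats), file.path(out_dir, "rdast_stats.tsv"),
           sep = "\t")
  }
  write_alignments(reads, file.path(out_dir, "dedup.sam"),
                   sq = ref_lengths(ref))

  if (config$aos_enabled) {
    ao <- run_aos(reads, ref, config$aos, regions)
    reads <- ao$reads
    stats$aos <- ao$stats
    fwrite(as.data.table(ao$stats), file.path(out_dir, "aos_stats.tsv"),
           sep = "\t")
  }
  write_alignments(reads, file.path(out_dir, "aos.sam"),
                   sq = ref_lengths(ref))

  caller <- if (is.null(caller_hook)) call_snps_fast else caller_hook
  calls <- caller(reads, ref, config$caller, regions)
  write_variants(calls, file.path(out_dir, "calls.vcf"),
                 contigs = ref_lengths(ref))

  wgs <- if (!is.null(inp$wgs_control)) read_variants(inp$wgs_control)
         else truth
  geno <- if (!is.null(inp$genotyping_control))
            read_variants(inp$genotyping_control) else truth
  known <- if (!is.null(inp$known_sites)) read_variants(inp$known_sites)
           else truth
  report <- NULL
  if (!is.null(wgs) || !is.null(geno)) {
    report <- eval_report(calls, wgs_control = wgs,
                          genotyping_control = geno, known_sites = known,
                          regions = regions)
    write_eval_report(report, file.path(out_dir, "report.tsv"))
  }
  list(calls = calls, report = report, stats = stats,
       paths = list(out_dir = out_dir,
                    dedup = file.path(out_dir, "dedup.sam"),
                    aos = file.path(out_dir, "aos.sam"),
                    calls = file.path(out_dir, "calls.vcf"),
                    report = file.path(out_dir, "report.tsv")))
}

#' Serialize / restore a pipeline configuration (JSON)
#'
#' The JSON copy written next to every run's outputs is the provenance
#' record; `read_pipeline_config()` restores a runnable configuration.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `path` (write) / a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$simulate <- unclass(x$simulate)
  x$rdast <- unclass(x$rdast)
  x$aos <- unclass(x$aos)
  x$caller <- unclass(x$caller)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    out_dir = x$out_dir, seed = x$seed,
    input = if (length(x$input)) x$input else list(),
    simulate = do.call(sim_config, x$simulate),
    rdast_enabled = x$rdast_enabled, aos_enabled = x$aos_enabled,
    rdast = do.call(rdast_config, x$rdast),
    aos = do.call(aos_config, x$aos),
    caller = do.call(caller_config, x$caller)
  )
}

#' Four-way preprocessing ablation
#'
#' Runs the pipeline with both preprocessing stages, each alone, and
#' neither, on the same simulated scenario, and reports
#' sensitivity/specificity against the planted truth for each arm — the
#' comparison that shows the duplicate filter buys specificity and the gap
#' repair buys sensitivity.
#'
#' @param sim result of [simulate_run()].
#' @param rdast_cfg,aos_cfg,caller_cfg stage configurations.
#' @return `data.table(arm, rdast, aos, total_snps, sensitivity,
#'   specificity)`.
#' @export
ablation_table <- function(sim, rdast_cfg = rdast_config(),
                           aos_cfg = aos_config(),
                           caller_cfg = caller_config()) {
  arms <- data.table(
    arm = c("full", "no_rdast", "no_aos", "neither"),
    rdast = c(TRUE, FALSE, TRUE, FALSE),
    aos = c(TRUE, TRUE, FALSE, FALSE)
  )
  res <- vector("list", nrow(arms))
  dedup <- run_rdast(sim$reads, rdast_cfg)$reads
  for (k in seq_len(nrow(arms))) {
    reads <- if (arms$rdast[k]) dedup else sim$reads
    if (arms$aos[k]) reads <- run_aos(reads, sim$ref, aos_cfg)$reads
    calls <- call_snps_fast(reads, sim$ref, caller_cfg, sim$target)
    ss <- sensitivity_specificity(calls, sim$truth, sim$target)
    res[[k]] <- data.table(arm = arms$arm[k], rdast = arms$rdast[k],
                           aos = arms$aos[k], total_snps = nrow(calls),
                           sensitivity = ss$sensitivity,
                           specificity = ss$specificity)
    rm(reads); gc(verbose = FALSE)   # large libraries; keep the peak low
  }
  rbindlist(res)
}
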