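# End-to-end pipeline driver: simulate (or reuse) a study bundle, then run
# summarise -> profile -> DMR -> promoter DMGs -> integration -> enrichment,
# writing every stage output plus a provenance manifest under one directory.

#' Default pipeline run configuration
#'
#' Every pipeline threshold in one flat list: DMR rule (`min_cpg = 5`,
#' `min_fold = 2`, `p_max = 0.05`), window geometry (1000/500 bp),
#' per-group site coverage floor 4, promoter span 2000 bp, DEG thresholds
#' (`|log2FC| > 1`, `FDR <= 0.001`), enrichment `q <= 0.05`, PPI cutoff
#' 0.400. Serialized verbatim into every output directory.
#'
#' @param seed Master seed for the simulation stage.
#' @param ... Overrides of any default.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    context = "CG",
    window_width = 1000L, window_step = 500L,
    min_cpg = 5L, min_fold = 2.0, p_max = 0.05,
    min_coverage = 4L,
    promoter_bp = 2000L, downstream_bp = 2000L,
    deg_min_abs_log2fc = 1.0, deg_max_fdr = 0.001,
    enrich_q_max = 0.05, ppi_min_score = 0.400,
    bins_per_feature = 20L,
    density_window_bp = 200L)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "sim"))
  if (length(unknown)) stop_input("unknown run_config field(s): %s",
                                  paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on a synthetic bundle
#'
#' Simulates the study bundle under `sim` (a [sim_config()]; its seed is
#' taken from `config$seed` unless supplied), writes it under
#' `out_dir/data`, reads the files back through the package readers, and
#' executes every stage: per-sample methylome summaries and lambda
#' conversion rate; level histograms, density-methylation matrix and
#' metagene profile of sample g1_r1; CG-context window scan and DMR
#' calling; promoter DMG extraction; DEG filtering, DMG-DEG overlap,
#' concordance, candidate selection, gene-set enrichment and PPI
#' filtering. All outputs land under `out_dir`; a `manifest.json` with
#' input/output checksums and the full configuration closes the run.
#' Outputs are deterministic given (`config`, `sim`).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param sim Optional [sim_config()] override.
#' @param simulate If `FALSE`, reuse an existing `out_dir/data` bundle
#'   instead of regenerating it.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_all <- function(config = run_config(), out_dir, sim = NULL, simulate = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  sim <- sim %||% sim_config(seed = config$seed)
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %6.1fs %s", stage, proc.time()[["elapsed"]] - t0, msg))
  }

  if (simulate) {
    log_stage("simulate", "generating synthetic bundle")
    simulate_bundle(sim, data_dir)
  } else {
    log_stage("simulate", "reusing existing bundle")
  }

  # -- read everything back through the package readers
  need <- c("genome.fa", "genes.gtf", "lambda.tsv", "expression.tsv",
            "sets.gmt", "curated.txt", "ppi_edges.tsv",
            sprintf("g%d_r%d.tsv", rep(1:2, each = sim$n_replicates),
                    seq_len(sim$n_replicates)))
  missing <- need[!file.exists(file.path(data_dir, need))]
  if (length(missing)) {
    stop_input("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  genome <- load_genome(file.path(data_dir, "genome.fa"))
  chrom_sizes <- stats::setNames(nchar(genome), names(genome))
  annotation <- read_annotation(file.path(data_dir, "genes.gtf"), "gtf",
                                chrom_sizes)
  isl_path <- file.path(data_dir, "islands.bed")
  if (file.exists(isl_path)) {
    isl <- data.table::fread(isl_path, header = FALSE,
                             col.names = c("chrom", "start", "end"))
    annotation$cpg_islands <- isl
  }
  sample_names <- sprintf("g%d_r%d", rep(1:2, each = sim$n_replicates),
                          seq_len(sim$n_replicates))
  calls <- lapply(stats::setNames(sample_names, sample_names), function(nm)
    read_cytosine_table(file.path(data_dir, paste0(nm, ".tsv")), "cgmap",
                        chrom_sizes))
  lambda <- read_cytosine_table(file.path(data_dir, "lambda.tsv"), "cgmap")
  expression <- data.table::fread(file.path(data_dir, "expression.tsv"))
  gene_sets <- read_gmt(file.path(data_dir, "sets.gmt"))
  curated <- readLines(file.path(data_dir, "curated.txt"))
  ppi <- data.table::fread(file.path(data_dir, "ppi_edges.tsv"))

  # -- stage: summarize
  log_stage("summarize", sprintf("%d samples + lambda", length(calls)))
  summaries <- lapply(sample_names, function(nm) {
    s <- summarize_methylome(calls[[nm]], min_coverage = config$min_coverage,
                             sample_id = nm)
    list(sample_id = nm, counts = as.list(s$counts), shares = as.list(s$shares),
         mean_levels = as.list(s$mean_levels), n_mc = s$n_mc)
  })
  conv <- conversion_rate(lambda)
  write_report_tables(list(samples = summaries, conversion_rate_pct = conv),
                      file.path(out_dir, "summary"))

  # -- stage: profiles (representative sample g1_r1)
  log_stage("profile", "histogram / density matrix / metagene for g1_r1")
  hist_all <- data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(cx)
    suppressWarnings(level_histogram(calls[["g1_r1"]], cx,
                                     min_coverage = config$min_coverage))))
  data.table::fwrite(hist_all, file.path(out_dir, "level_histogram.tsv"), sep = "\t")
  dmat <- density_meth_matrix(genome, calls[["g1_r1"]],
                              window_bp = config$density_window_bp,
                              min_coverage = config$min_coverage)
  data.table::fwrite(dmat$medians, file.path(out_dir, "density_medians.tsv"),
                     sep = "\t")
  utils::write.table(dmat$matrix, file.path(out_dir, "density_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  mg <- metagene_profile(calls[["g1_r1"]], annotation,
                         bins_per_feature = config$bins_per_feature,
                         min_coverage = config$min_coverage,
                         upstream_bp = config$promoter_bp,
                         downstream_bp = config$downstream_bp)
  data.table::fwrite(mg, file.path(out_dir, "metagene.tsv"), sep = "\t")

  # -- stage: DMR
  log_stage("dmr", sprintf("%s context scan %d/%d bp", config$context,
                           config$window_width, config$window_step))
  g1 <- calls[grep("^g1_", sample_names, value = TRUE)]
  g2 <- calls[grep("^g2_", sample_names, value = TRUE)]
  mw <- scan_windows(g1, g2, context = config$context,
                     width = config$window_width, step = config$window_step,
                     min_cpg = config$min_cpg,
                     min_coverage = config$min_coverage)
  dmrs <- call_dmrs(mw, p_max = config$p_max, min_fold = config$min_fold,
                    min_cpg = config$min_cpg)
  write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
  data.table::fwrite(dmrs, file.path(out_dir, "dmrs.tsv"), sep = "\t")
  assignments <- annotate_dmrs(dmrs, annotation,
                               upstream_bp = config$promoter_bp,
                               downstream_bp = config$downstream_bp)
  dmgs <- promoter_dmgs(assignments)
  writeLines(dmgs, file.path(out_dir, "dmgs.txt"))
  log_stage("dmr", sprintf("%d windows -> %d DMRs -> %d promoter DMGs",
                           nrow(mw$windows), nrow(dmrs), length(dmgs)))

  # -- stage: integration
  log_stage("integrate", "DEG filter / overlap / concordance / candidates")
  degs <- filter_degs(expression, config$deg_min_abs_log2fc, config$deg_max_fdr)
  ov <- overlap_sets(dmgs, degs)
  prom_dir <- assignments[feature == "promoter" & !is.na(gene_id),
                          .(direction = direction[1L]), by = gene_id]
  conc <- merge(prom_dir, expression[, .(gene_id, log2_fc)], by = "gene_id")
  conc <- conc[gene_id %in% ov$intersection]
  conc[, concord := concordance(sub("_in_a$", "_in_g1", direction), log2_fc)]
  data.table::fwrite(conc, file.path(out_dir, "concordance.tsv"), sep = "\t")
  candidates <- select_candidates(ov$intersection, gene_sets, curated)
  data.table::fwrite(candidates, file.path(out_dir, "candidates.tsv"), sep = "\t")
  enr <- enrich(ov$intersection, unique(annotation$genes$gene_id), gene_sets,
                q_max = config$enrich_q_max)
  data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t")
  ppi_net <- filter_ppi_edges(ppi, config$ppi_min_score)
  data.table::fwrite(ppi_net$nodes, file.path(out_dir, "ppi_nodes.tsv"), sep = "\t")

  # -- manifest
  outputs <- c("summary.json", "level_histogram.tsv", "density_medians.tsv",
               "density_matrix.tsv", "metagene.tsv", "dmrs.bed", "dmrs.tsv",
               "dmgs.txt", "concordance.tsv", "candidates.tsv",
               "enrichment.tsv", "ppi_nodes.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("crispmeth")),
    config = unclass(config),
    sim_config = unclass(sim),
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(data_dir, need))), need)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)),
    venn = as.list(ov$counts),
    n_dmrs = nrow(dmrs), n_promoter_dmgs = length(dmgs),
    n_degs = length(degs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", sprintf("outputs in %s", out_dir))
  invisible(list(summaries = summaries, conversion_rate = conv, windows = mw,
                 dmrs = dmrs, assignments = assignments, dmgs = dmgs,
                 degs = degs, overlap = ov, concordance = conc,
                 candidates = candidates, enrichment = enr, ppi = ppi_net,
                 manifest = manifest))
}
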