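# Shared fixture builders. Everything is generated in code at test time;
# heavier simulated objects are cached per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_cfg <- function(...) {
  args <- list(seed = 11L, n_chroms = 1L, chrom_length = 150000L,
               n_genes = 12L, n_planted_dmrs = 5L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# one shared tiny simulation, built lazily and cached for the whole run
.fixture_env <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- tiny_cfg()
    gen <- simulate_genome(cfg)
    meth <- simulate_methylomes(gen$genome, gen$annotation, cfg)
    .fixture_env$sim <- list(cfg = cfg, genome = gen$genome,
                             annotation = gen$annotation,
                             samples = meth$samples, truth = meth$truth)
  }
  .fixture_env$sim
}

# random valid call table for IO / summary tests
random_calls <- function(n, seed = 1L, chroms = c("chr1", "chr2"),
                         max_pos = 100000L) {
  withr::with_seed(seed, {
    total <- rpois(n, 15) + 1L
    data.table::data.table(
      chrom = sample(chroms, n, replace = TRUE),
      pos = sample.int(max_pos, n, replace = TRUE) - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
      meth = NA_integer_, total = total)[
        , meth := rbinom(.N, total, 0.4)][]
  })
}

# toy 3-exon plus-strand gene GTF written to a temp file
write_toy_gtf <- function(path, strand = "+") {
  lines <- c(
    sprintf("chr1\ttoy\texon\t1001\t1200\t.\t%s\t.\tgene_id \"gA\"; transcript_id \"gA.t1\";", strand),
    sprintf("chr1\ttoy\texon\t1501\t1700\t.\t%s\t.\tgene_id \"gA\"; transcript_id \"gA.t1\";", strand),
    sprintf("chr1\ttoy\texon\t2001\t2300\t.\t%s\t.\tgene_id \"gA\"; transcript_id \"gA.t1\";", strand))
  writeLines(lines, path)
  path
}
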