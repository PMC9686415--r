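# Seeded generator of a toy genome, annotation, per-sample methylomes with
# planted promoter DMRs, an unmethylated lambda spike-in, and an expression
# table with planted DEGs anti-correlated with promoter methylation. This is
# the statistical stand-in for the study's six-sample (2 groups x 3
# replicates) WGBS + RNA-seq design; all randomness flows from one seed.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: two groups of three
#' replicates; CG-dominated methylation (baseline mean CG level 0.80 with
#' hypermethylated CpG islands, CHG 0.02, CHH 0.03, so > 90% of methylated
#' cytosines fall in CG context); beta-binomial replicate noise; Poisson
#' coverage; CG-context DMRs of effect size 0.5 planted in gene promoters;
#' an unmethylated lambda spike-in whose apparent methylation is the
#' bisulfite conversion failure rate.
#'
#' @param seed Integer master seed; identical seeds give identical outputs.
#' @param n_chroms,chrom_length Genome shape (default 2 x 1 Mb).
#' @param n_genes Genes placed non-overlapping (default 120).
#' @param n_replicates Replicates per group (default 3).
#' @param baseline_cg,baseline_chg,baseline_chh Mean true methylation level
#'   per context (defaults 0.80 / 0.02 / 0.03).
#' @param island_hyper_fraction Fraction of island CpGs drawn
#'   hypermethylated (default 0.6).
#' @param island_hyper_level True level of hypermethylated island CpGs
#'   (default 0.95).
#' @param n_islands_per_mb CpG-island patches per Mb of genome (default 15).
#' @param dispersion Beta-binomial overdispersion rho (default 0.02).
#' @param mean_coverage Poisson mean per-site coverage (default 20).
#' @param n_planted_dmrs Promoter DMRs planted in group contrast (default 50).
#' @param dmr_delta Methylation-level effect size Delta (default 0.5).
#' @param dmr_sign `-1` (default): group 2's planted promoter mean is
#'   shifted down by Delta (group 1 hyper); `+1` shifts it up, clipped to
#'   \[0, 1\] with a warning.
#' @param lambda_length Lambda spike-in length in bp (default 48502).
#' @param conversion_failure Bisulfite conversion failure rate
#'   (default 0.0095, i.e. a 99.05% conversion rate).
#' @param p_anticorrelated Probability that a planted promoter DMR gene
#'   gets an expression change of opposite sign (default 0.8).
#' @param gc_content Background GC fraction of the toy genome (default
#'   0.45; the toy genome has no CpG depletion, so this keeps the
#'   CG/CHG/CHH site ratio in a range where methylated cytosines are
#'   CG-dominated as in real fish methylomes).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1000000L,
                       n_genes = 120L, n_replicates = 3L,
                       baseline_cg = 0.80, baseline_chg = 0.02,
                       baseline_chh = 0.03, island_hyper_fraction = 0.6,
                       island_hyper_level = 0.95, n_islands_per_mb = 15L,
                       dispersion = 0.02, mean_coverage = 20,
                       n_planted_dmrs = 50L, dmr_delta = 0.5, dmr_sign = -1L,
                       lambda_length = 48502L, conversion_failure = 0.0095,
                       p_anticorrelated = 0.8, gc_content = 0.45) {
  cfg <- as.list(environment())
  fracs <- c(baseline_cg, baseline_chg, baseline_chh, island_hyper_fraction,
             island_hyper_level, conversion_failure, p_anticorrelated,
             gc_content, dispersion)
  if (any(fracs < 0 | fracs > 1)) stop_input("all fractions must lie in [0, 1]")
  if (dmr_delta < 0 || dmr_delta > 1) stop_input("dmr_delta must lie in [0, 1]")
  if (!dmr_sign %in% c(-1L, 1L)) stop_input("dmr_sign must be -1 or +1")
  if (n_replicates < 1L || n_chroms < 1L) stop_input("need >= 1 chromosome and replicate")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_chroms, "x",
      format(x$chrom_length, big.mark = ","), "bp |", x$n_genes, "genes | 2 x",
      x$n_replicates, "replicates |", x$n_planted_dmrs,
      "planted promoter DMRs (delta", x$dmr_delta, ")\n")
  invisible(x)
}

#' Simulate a toy genome with CpG islands and gene models
#'
#' Background sequence is i.i.d. with the configured GC content; CpG-island
#' patches (0.5-1.5 kb) are drawn GC-rich (GC 0.65), which elevates their
#' CpG dinucleotide frequency well above background. Genes with 2-6 exons
#' are placed non-overlapping with 2 kb clearance for flanks.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named character vector of chromosome sequences)
#'   and `annotation` (an [annotation_set()] carrying genes and islands).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "genome", {
    gc <- config$gc_content
    p_bg <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    p_isl <- c(A = 0.175, C = 0.325, G = 0.325, T = 0.175)
    chroms <- paste0("chr", seq_len(config$n_chroms))
    L <- config$chrom_length
    genome <- character(config$n_chroms)
    islands <- list()
    for (i in seq_along(chroms)) {
      s <- sample(names(p_bg), L, replace = TRUE, prob = p_bg)
      n_isl <- max(0L, round(config$n_islands_per_mb * L / 1e6))
      if (n_isl > 0L) {
        isl_len <- sample(500:1500, n_isl, replace = TRUE)
        isl_start <- sort(sample.int(L - max(isl_len) - 1L, n_isl))
        # drop overlapping patches
        keep <- rep(TRUE, n_isl)
        last_end <- -1L
        for (j in seq_len(n_isl)) {
          if (isl_start[j] <= last_end) keep[j] <- FALSE
          else last_end <- isl_start[j] + isl_len[j]
        }
        isl_start <- isl_start[keep]; isl_len <- isl_len[keep]
        for (j in seq_along(isl_start)) {
          idx <- seq.int(isl_start[j] + 1L, isl_start[j] + isl_len[j])
          s[idx] <- sample(names(p_isl), isl_len[j], replace = TRUE, prob = p_isl)
        }
        islands[[i]] <- data.table::data.table(
          chrom = chroms[i], start = isl_start, end = isl_start + isl_len)
      }
      genome[i] <- paste(s, collapse = "")
    }
    names(genome) <- chroms
    islands <- data.table::rbindlist(islands)
    genes <- place_genes(config, chroms, L)
    ann <- annotation_set(genes, stats::setNames(rep(L, length(chroms)), chroms),
                          cpg_islands = if (nrow(islands)) islands else NULL)
    list(genome = genome, annotation = ann)
  })
}

# Place n_genes non-overlapping gene models across chromosomes, each with
# 2-6 exons and 2 kb flank clearance. Errors if they cannot fit.
place_genes <- function(config, chroms, L) {
  n <- config$n_genes
  if (n == 0L) {
    return(data.table::data.table(gene_id = character(), transcript_id = character(),
                                  chrom = character(), strand = character(),
                                  start = integer(), end = integer()))
  }
  per_chrom <- diff(round(seq(0, n, length.out = length(chroms) + 1L)))
  exons_all <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    # budget: flank + gene footprint per slot
    slot <- L %/% ng
    if (slot < 9000L) {
      stop_input("genes cannot fit: increase chrom_length or reduce n_genes")
    }
    for (g in seq_len(ng)) {
      gi <- gi + 1L
      n_ex <- sample(2:6, 1L)
      ex_len <- sample(100:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(200:800, n_ex - 1L, replace = TRUE) else integer()
      glen <- sum(ex_len) + sum(in_len)
      lo <- (g - 1L) * slot + 2500L
      hi <- g * slot - 2500L - glen
      gstart <- if (hi > lo) sample(lo:hi, 1L) else lo
      starts <- gstart + cumsum(c(0L, head(ex_len, -1L) + in_len))
      exons_all[[gi]] <- data.table::data.table(
        gene_id = sprintf("gene%04d", gi),
        transcript_id = sprintf("gene%04d.t1", gi),
        chrom = chroms[ci],
        strand = sample(c("+", "-"), 1L),
        start = starts, end = starts + ex_len)
    }
  }
  data.table::rbindlist(exons_all)
}

#' Simulate per-sample methylomes with planted promoter DMRs
#'
#' Every cytosine of the simulated genome (both strands) is classified by
#' its sequence context. CG sites take the baseline CG mean (shared by the
#' two strands of a CpG unit), with CpG units inside declared islands
#' hypermethylated at the configured fraction. Non-CpG methylation is
#' sparse, as in real fish methylomes: a random fraction of CHG/CHH sites
#' equal to the context baseline is fully methylated and the rest are
#' unmethylated, so the pooled CHG/CHH level recovers the baseline while
#' methylated cytosines stay CG-dominated. `n_planted_dmrs` gene promoters
#' get a group-2 CG level shifted by the signed effect size (clipped to
#' \[0, 1\] with a warning when it overflows). Per sample, each site draws
#' coverage ~ Poisson(mean), a replicate level ~ Beta around the site mean
#' with the configured overdispersion, and a methylated count ~ Binomial.
#' Sites with zero coverage are dropped, as in real call files.
#'
#' @param genome,annotation From [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List: `samples` (named list of call tables, `g1_r1` ...
#'   `g2_rN`), `truth` (planted DMR ledger: interval, gene, per-group true
#'   means, direction; plus config echo).
#' @export
simulate_methylomes <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  sites <- enumerate_cytosines(genome)
  # --- site means per group
  sites <- sites[!is.na(context)]
  # CpG unit id shared by the two strands of one CpG
  sites[, unit_pos := ifelse(context == "CG",
                             ifelse(strand == "+", pos, pos - 1L), pos)]
  with_stage_seed(config$seed, "site_means", {
    # CG: baseline mean everywhere; CHG/CHH: sparse fully-methylated sites
    # at density = baseline level (pooled level == baseline)
    sites[, mu1 := 0]
    sites[context == "CG", mu1 := config$baseline_cg]
    sites[context == "CHG", mu1 := as.numeric(runif(.N) < config$baseline_chg)]
    sites[context == "CHH", mu1 := as.numeric(runif(.N) < config$baseline_chh)]
    isl <- annotation$cpg_islands
    if (!is.null(isl) && nrow(isl)) {
      units <- unique(sites[context == "CG", .(chrom, unit_pos)])
      hits <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(units$chrom,
                               IRanges::IRanges(units$unit_pos + 1L, units$unit_pos + 2L)),
        to_granges(isl))
      in_isl <- unique(S4Vectors::queryHits(hits))
      if (length(in_isl)) {
        hyper <- in_isl[runif(length(in_isl)) < config$island_hyper_fraction]
        units[, island_hyper := FALSE]
        units[hyper, island_hyper := TRUE]
        sites <- merge(sites, units, by = c("chrom", "unit_pos"), all.x = TRUE)
        sites[island_hyper %in% TRUE, mu1 := config$island_hyper_level]
        sites[, island_hyper := NULL]
      }
    }
    sites[, mu2 := mu1]
    # --- plant promoter DMRs
    truth_dmrs <- data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      gene_id = character(), mean_g1 = numeric(), mean_g2 = numeric(),
      direction = character())
    if (config$n_planted_dmrs > 0L) {
      proms <- gene_features(annotation)[feature == "promoter"]
      if (nrow(proms) < config$n_planted_dmrs) {
        stop_input("not enough genes (%d promoters) for %d planted DMRs",
                   nrow(proms), config$n_planted_dmrs)
      }
      sel <- proms[sort(sample.int(nrow(proms), config$n_planted_dmrs))]
      shift <- config$dmr_sign * config$dmr_delta
      planted <- list()
      for (j in seq_len(nrow(sel))) {
        in_prom <- sites$chrom == sel$chrom[j] & sites$context == "CG" &
          sites$unit_pos >= sel$start[j] & sites$unit_pos < sel$end[j]
        raw2 <- sites$mu1[in_prom] + shift
        if (any(raw2 < 0 | raw2 > 1)) {
          warning(sprintf("planted effect clipped to [0,1] in promoter of %s",
                          sel$gene_id[j]))
        }
        sites$mu2[in_prom] <- pmin(1, pmax(0, raw2))
        planted[[j]] <- data.table::data.table(
          chrom = sel$chrom[j], start = sel$start[j], end = sel$end[j],
          gene_id = sel$gene_id[j],
          mean_g1 = mean(sites$mu1[in_prom]),
          mean_g2 = mean(sites$mu2[in_prom]),
          direction = if (shift < 0) "hyper_in_g1" else "hypo_in_g1")
      }
      truth_dmrs <- data.table::rbindlist(planted)
    }
    data.table::setorder(sites, chrom, pos, strand)
    # --- draw replicate counts
    samples <- list()
    for (grp in 1:2) {
      mu <- if (grp == 1L) sites$mu1 else sites$mu2
      for (rep_i in seq_len(config$n_replicates)) {
        samples[[sprintf("g%d_r%d", grp, rep_i)]] <-
          draw_sample_counts(sites, mu, config)
      }
    }
    truth <- list(dmrs = truth_dmrs,
                  lambda_failure = config$conversion_failure,
                  config = unclass(config))
    list(samples = samples, truth = truth)
  })
}

# One replicate: Poisson coverage, beta-distributed replicate level around
# the site mean (rho = dispersion), binomial methylated count.
draw_sample_counts <- function(sites, mu, config) {
  n <- nrow(sites)
  covr <- rpois(n, config$mean_coverage)
  rho <- config$dispersion
  if (rho > 0) {
    nu <- (1 - rho) / rho
    lev <- numeric(n)
    interior <- mu > 0 & mu < 1
    lev[interior] <- rbeta(sum(interior), mu[interior] * nu,
                           (1 - mu[interior]) * nu)
    lev[!interior] <- mu[!interior]
  } else {
    lev <- mu
  }
  meth <- rbinom(n, covr, lev)
  out <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    context = sites$context, meth = meth, total = covr)
  out[total > 0L]
}

# Enumerate all cytosines on both strands with sequence-derived context.
enumerate_cytosines <- function(genome) {
  genome <- load_genome(genome)
  res <- lapply(names(genome), function(cx) {
    s <- strsplit(genome[[cx]], "", fixed = TRUE)[[1L]]
    ppos <- which(s == "C") - 1L
    mpos <- which(s == "G") - 1L
    dt <- data.table::data.table(
      chrom = cx,
      pos = c(ppos, mpos),
      strand = rep(c("+", "-"), c(length(ppos), length(mpos))))
    dt[, context := classify_context(s, pos, strand)]
    dt
  })
  out <- data.table::rbindlist(res)
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Simulate the unmethylated lambda spike-in
#'
#' The lambda control is truly unmethylated, so every methylated read is a
#' conversion failure: `meth ~ Binomial(coverage, conversion_failure)` at
#' every lambda cytosine.
#'
#' @param config A [sim_config()].
#' @return Cytosine call table on chromosome `"lambda"`.
#' @export
simulate_lambda <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "lambda", {
    L <- config$lambda_length
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seqc <- paste(s, collapse = "")
    sites <- enumerate_cytosines(stats::setNames(seqc, "lambda"))
    n <- nrow(sites)
    covr <- rpois(n, config$mean_coverage)
    meth <- rbinom(n, covr, config$conversion_failure)
    out <- data.table::data.table(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      context = sites$context, meth = meth, total = covr)
    out[total > 0L]
  })
}

#' Simulate an expression table with planted DEGs
#'
#' Genes with a planted promoter DMR receive a strong expression change
#' (|log2FC| in \[1.5, 4\], FDR well below 0.001) whose sign is opposite
#' the methylation change with probability `p_anticorrelated` (and equal
#' otherwise). All other genes draw a null log2FC ~ Normal(0, 0.3) with an
#' FDR above the DEG threshold.
#'
#' @param annotation An [annotation_set()].
#' @param truth Truth ledger from [simulate_methylomes()].
#' @param config The same [sim_config()].
#' @return List: `expression` (`data.table`: gene_id, log2_fc, fdr) and
#'   `deg_truth` (planted DEG table with true signs and anticorrelation
#'   flags).
#' @export
simulate_expression <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "expression", {
    genes <- unique(annotation$genes$gene_id)
    expr <- data.table::data.table(
      gene_id = genes,
      log2_fc = rnorm(length(genes), 0, 0.3),
      fdr = runif(length(genes), 0.002, 1))
    planted <- truth$dmrs
    deg_truth <- data.table::data.table(
      gene_id = character(), meth_direction = character(),
      log2_fc = numeric(), anticorrelated = logical())
    if (!is.null(planted) && nrow(planted)) {
      anti <- runif(nrow(planted)) < config$p_anticorrelated
      # hyper_in_g1 promoter + anticorrelated -> expression down in g1
      meth_up_g1 <- planted$direction == "hyper_in_g1"
      sign_fc <- ifelse(xor(meth_up_g1, anti), +1, -1)
      mag <- runif(nrow(planted), 1.5, 4)
      fc <- sign_fc * mag
      idx <- match(planted$gene_id, expr$gene_id)
      expr[idx, log2_fc := fc]
      expr[idx, fdr := runif(.N, 1e-8, 5e-4)]
      deg_truth <- data.table::data.table(
        gene_id = planted$gene_id, meth_direction = planted$direction,
        log2_fc = fc, anticorrelated = anti)
    }
    list(expression = expr[], deg_truth = deg_truth)
  })
}

#' Simulate and write the full synthetic study bundle
#'
#' Runs all four generators and writes: `genome.fa`, `genes.gtf`,
#' `islands.bed`, six cgmap call files (`g1_r1.tsv` ...), `lambda.tsv`,
#' `expression.tsv`, `sets.gmt` (toy gene sets including a muscle-like set
#' enriched for planted genes), `curated.txt`, `ppi_edges.tsv`, and
#' `truth.json`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  meth <- simulate_methylomes(gen$genome, gen$annotation, config)
  lambda <- simulate_lambda(config)
  expr <- simulate_expression(gen$annotation, meth$truth, config)

  writeLines(unlist(lapply(names(gen$genome), function(cx)
    c(paste0(">", cx), chunk_fasta(gen$genome[[cx]])))),
    file.path(out_dir, "genome.fa"))
  write_gtf(gen$annotation, file.path(out_dir, "genes.gtf"))
  isl <- gen$annotation$cpg_islands
  if (!is.null(isl) && nrow(isl)) {
    data.table::fwrite(isl, file.path(out_dir, "islands.bed"), sep = "\t",
                       col.names = FALSE)
  }
  for (nm in names(meth$samples)) {
    write_cytosine_table(meth$samples[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  write_cytosine_table(lambda, file.path(out_dir, "lambda.tsv"))
  data.table::fwrite(expr$expression, file.path(out_dir, "expression.tsv"),
                     sep = "\t")
  write_toy_genesets(gen$annotation, meth$truth, config, out_dir)
  truth_out <- list(
    dmrs = meth$truth$dmrs, deg_truth = expr$deg_truth,
    lambda_failure = config$conversion_failure, seed = config$seed)
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = gen$genome, annotation = gen$annotation,
                 samples = meth$samples, truth = meth$truth, lambda = lambda,
                 expression = expr$expression, deg_truth = expr$deg_truth))
}

chunk_fasta <- function(s, width = 70L) {
  n <- nchar(s)
  substring(s, seq(1L, n, width), pmin(seq(1L, n, width) + width - 1L, n))
}

# Minimal GTF writer (1-based closed) for the simulated annotation.
write_gtf <- function(annotation, path) {
  ex <- annotation$genes
  lines <- ex[, sprintf(
    paste0("%s\tcrispmeth\texon\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; transcript_id \"%s\";"),
    chrom, start + 1L, end, strand, gene_id, transcript_id)]
  writeLines(lines, path)
  invisible(path)
}

# Toy gene sets / curated list / PPI edges for the integration stage: one
# "muscle_structure" set enriched for planted genes, random background sets,
# a curated list covering part of the planted genes, and a random PPI edge
# table over the planted genes with STRING-style 0-1000 scores.
write_toy_genesets <- function(annotation, truth, config, out_dir) {
  with_stage_seed(config$seed, "genesets", {
    genes <- unique(annotation$genes$gene_id)
    planted <- truth$dmrs$gene_id
    muscle <- unique(c(
      if (length(planted)) sample(planted, ceiling(length(planted) / 2)),
      sample(genes, max(3L, length(genes) %/% 20L))))
    sets <- list(muscle_structure = muscle)
    for (k in 1:9) {
      sets[[sprintf("random_set_%02d", k)]] <-
        sample(genes, max(3L, length(genes) %/% 10L))
    }
    gmt <- vapply(names(sets), function(nm)
      paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
    writeLines(gmt, file.path(out_dir, "sets.gmt"))
    curated <- if (length(planted)) {
      sort(sample(planted, ceiling(length(planted) * 0.6)))
    } else character()
    writeLines(curated, file.path(out_dir, "curated.txt"))
    nodes <- if (length(planted) >= 2L) planted else genes[seq_len(min(10L, length(genes)))]
    n_edges <- min(200L, length(nodes) * 3L)
    edges <- data.table::data.table(
      from = sample(nodes, n_edges, replace = TRUE),
      to = sample(nodes, n_edges, replace = TRUE),
      score = sample(150:999, n_edges, replace = TRUE))
    edges <- unique(edges[from != to])
    data.table::fwrite(edges, file.path(out_dir, "ppi_edges.tsv"), sep = "\t")
  })
  invisible(out_dir)
}
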