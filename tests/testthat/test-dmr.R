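# The DMR core: Fisher exact test, replicate pooling, window scanning,
# region merging, feature annotation.

test_that("fisher_two_sided matches exact hand-derived values", {
  # (5,0 / 0,5): only the two extreme tables, each 1/C(10,5)
  expect_equal(fisher_two_sided(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_two_sided(3, 3, 3, 3), 1)
  expect_equal(fisher_two_sided(0, 0, 0, 0), 1)
  expect_error(fisher_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("fisher_two_sided is symmetric under row and column swaps", {
  withr::with_seed(101, {
    for (i in 1:200) {
      t <- rpois(4, 8)
      p <- fisher_two_sided(t[1], t[2], t[3], t[4])
      expect_equal(p, fisher_two_sided(t[3], t[4], t[1], t[2]), tolerance = 1e-12)
      expect_equal(p, fisher_two_sided(t[2], t[1], t[4], t[3]), tolerance = 1e-12)
    }
  })
})

test_that("fisher_two_sided agrees with stats::fisher.test on random tables", {
  withr::with_seed(102, {
    tabs <- matrix(rpois(4 * 300, 12), ncol = 4)
  })
  mine <- fisher_two_sided(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  ref <- apply(tabs, 1, function(t)
    stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value)
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("pool_counts pools replicates then sites with a coverage floor", {
  mk <- function(meth, total) data.table::data.table(
    chrom = "chr1", pos = 100L, strand = "+", context = "CG",
    meth = meth, total = total)
  res <- pool_counts(list(mk(3L, 4L), mk(1L, 6L)), list(mk(2L, 5L), mk(2L, 5L)),
                     list("chr1", 0L, 1000L))
  expect_equal(res$meth_a, 4L); expect_equal(res$total_a, 10L)
  expect_equal(res$level_a, 0.4)
  expect_equal(res$n_cpg_covered, 1L)
  # empty interval -> zeros
  res0 <- pool_counts(mk(3L, 4L), mk(2L, 5L), list("chr1", 5000L, 6000L))
  expect_equal(res0$n_cpg_covered, 0L)
  expect_equal(res0$meth_a + res0$total_a, 0L)
})

test_that("CG strand merging collapses symmetric CpG counts to the forward C", {
  rec <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 11L, 50L), strand = c("+", "-", "+"),
    context = c("CG", "CG", "CG"), meth = c(3L, 2L, 1L), total = c(5L, 4L, 8L))
  m <- merge_cg_strands(rec)
  expect_equal(nrow(m), 2L)
  expect_equal(m[pos == 10L, meth], 5L)
  expect_equal(m[pos == 10L, total], 9L)
  expect_equal(m[pos == 50L, total], 8L)
})

test_that("pooled totals equal a per-site enumeration oracle on random intervals", {
  sim <- tiny_sim()
  g1 <- sim$samples[1:3]; g2 <- sim$samples[4:6]
  withr::with_seed(103, {
    for (i in 1:20) {
      s <- sample.int(140000L, 1L); e <- s + sample(1000:8000, 1L)
      res <- pool_counts(g1, g2, list("chr1", s, e))
      # oracle: loop over replicates and raw records, strand-merging CpGs
      acc <- new.env()
      acc$a_m <- 0L; acc$a_t <- 0L; acc$b_m <- 0L; acc$b_t <- 0L
      unit_tab <- list()
      for (grp in c("a", "b")) {
        reps <- if (grp == "a") g1 else g2
        for (r in reps) {
          cg <- r[context == "CG"]
          for (j in seq_len(nrow(cg))) {
            u <- if (cg$strand[j] == "+") cg$pos[j] else cg$pos[j] - 1L
            key <- as.character(u)
            cur <- unit_tab[[key]] %||% c(a_m = 0L, a_t = 0L, b_m = 0L, b_t = 0L)
            cur[paste0(grp, "_m")] <- cur[paste0(grp, "_m")] + cg$meth[j]
            cur[paste0(grp, "_t")] <- cur[paste0(grp, "_t")] + cg$total[j]
            unit_tab[[key]] <- cur
          }
        }
      }
      n_cpg <- 0L
      for (key in names(unit_tab)) {
        u <- as.integer(key)
        cur <- unit_tab[[key]]
        if (u >= s && u < e && cur["a_t"] >= 4 && cur["b_t"] >= 4) {
          n_cpg <- n_cpg + 1L
          acc$a_m <- acc$a_m + cur[["a_m"]]; acc$a_t <- acc$a_t + cur[["a_t"]]
          acc$b_m <- acc$b_m + cur[["b_m"]]; acc$b_t <- acc$b_t + cur[["b_t"]]
        }
      }
      expect_equal(res$n_cpg_covered, n_cpg)
      expect_equal(res$meth_a, acc$a_m); expect_equal(res$total_a, acc$a_t)
      expect_equal(res$meth_b, acc$b_m); expect_equal(res$total_b, acc$b_t)
    }
  })
})

test_that("identical groups yield null windows; sparse windows are skipped", {
  sim <- tiny_sim()
  s1 <- sim$samples$g1_r1
  mw <- scan_windows(s1, s1, min_coverage = 2L)
  expect_gt(nrow(mw$windows), 50)
  expect_true(all(mw$windows$fold == 1))
  expect_true(all(mw$windows$p_value > 1 - 1e-9))
  expect_equal(nrow(call_dmrs(mw)), 0L)
  expect_true(all(mw$windows$n_cpg >= 5L))
  # min_cpg excludes windows with fewer covered units
  few <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 40L, 80L, 120L), strand = "+",
    context = "CG", meth = 3L, total = 6L)
  mw4 <- scan_windows(few, few, min_cpg = 5L)
  expect_equal(nrow(mw4$windows), 0L)
  mw4b <- scan_windows(few, few, min_cpg = 4L)
  expect_gt(nrow(mw4b$windows), 0L)
})

test_that("a strong 0.9-vs-0.1 window at depth 50 is significant", {
  # 5 CpGs, 10 reads each: group totals 50/50, meth 45 vs 5
  mk <- function(meth) data.table::data.table(
    chrom = "chr1", pos = seq(100L, 500L, 100L), strand = "+", context = "CG",
    meth = meth, total = 10L)
  mw <- scan_windows(mk(9L), mk(1L))
  w <- mw$windows[1]
  expect_equal(w$fold, 9, tolerance = 1e-6)
  expect_equal(w$p_value, fisher_two_sided(45, 5, 5, 45), tolerance = 1e-12)
  expect_lt(w$p_value, 0.05)
  dmrs <- call_dmrs(mw)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$direction, "hyper_in_a")
})

test_that("overlapping same-direction significant windows merge into one DMR", {
  sim <- tiny_sim()
  mw <- scan_windows(sim$samples[1:3], sim$samples[4:6])
  dmrs <- call_dmrs(mw)
  expect_gt(nrow(dmrs), 0)
  # merged regions are disjoint per direction and span >= window width
  expect_true(all(dmrs$end - dmrs$start >= mw$params$width))
  for (dir in unique(dmrs$direction)) {
    d <- dmrs[direction == dir][order(start)]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # every constituent-window criterion holds for the merged statistics source
  expect_true(all(dmrs$n_cpg >= 5))
})

test_that("calling on already-merged regions is idempotent", {
  sim <- tiny_sim()
  mw <- scan_windows(sim$samples[1:3], sim$samples[4:6])
  dmrs <- call_dmrs(mw)
  again <- call_dmrs(dmrs[, .(chrom, start, end, n_cpg, fold, p_value,
                              direction, level_a, level_b)],
                     sites = mw$sites)
  expect_equal(again$start, dmrs$start)
  expect_equal(again$end, dmrs$end)
  expect_equal(again$p_value, dmrs$p_value)
})

test_that("planted DMRs are recovered and recall grows with delta and coverage", {
  recover <- function(delta, coverage, seed = 19L) {
    cfg <- tiny_cfg(seed = seed, chrom_length = 300000L, n_genes = 25L,
                    n_planted_dmrs = 10L, dmr_delta = delta,
                    mean_coverage = coverage)
    gen <- simulate_genome(cfg)
    meth <- simulate_methylomes(gen$genome, gen$annotation, cfg)
    dmrs <- call_dmrs(scan_windows(meth$samples[1:3], meth$samples[4:6]))
    truth <- meth$truth$dmrs
    if (!nrow(dmrs)) return(c(recall = 0, precision = NA))
    hit <- function(t_s, t_e) any(dmrs$chrom == "chr1" & dmrs$start < t_e &
                                    dmrs$end > t_s &
                                    dmrs$direction == "hyper_in_a")
    rec <- mean(mapply(hit, truth$start, truth$end))
    tp <- sum(mapply(function(s, e) any(truth$start < e & truth$end > s),
                     dmrs$start, dmrs$end))
    c(recall = rec, precision = tp / nrow(dmrs))
  }
  r_delta <- vapply(c(0.15, 0.3, 0.5), function(d) recover(d, 20)["recall"],
                    numeric(1))
  expect_true(all(diff(r_delta) >= 0))
  expect_gte(r_delta[3], 0.9)
  r_cov <- vapply(c(3, 8, 20), function(cv) recover(0.3, cv)["recall"],
                  numeric(1))
  expect_true(all(diff(r_cov) >= 0))
})

test_that("null p-values are uniform-or-conservative under a binomial model", {
  # dispersion 0 so the Fisher sampling model holds exactly
  cfg <- tiny_cfg(seed = 23L, chrom_length = 400000L, n_genes = 10L,
                  n_planted_dmrs = 0L, dispersion = 0)
  gen <- simulate_genome(cfg)
  meth <- simulate_methylomes(gen$genome, gen$annotation, cfg)
  mw <- scan_windows(meth$samples[1:3], meth$samples[4:6])
  frac <- mean(mw$windows$p_value <= 0.05)
  n <- nrow(mw$windows)
  expect_gt(n, 500)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("DMR-gene assignment matches a brute-force all-pairs oracle", {
  sim <- tiny_sim()
  feats <- gene_features(sim$annotation)
  withr::with_seed(104, {
    n <- 100L
    starts <- sample.int(145000L, n)
    dmrs <- data.table::data.table(
      chrom = "chr1", start = starts, end = starts + sample(200:3000, n, TRUE),
      direction = sample(c("hyper_in_a", "hypo_in_a"), n, TRUE))
  })
  asg <- annotate_dmrs(dmrs, sim$annotation)
  # oracle: quadratic loop over (dmr, feature-piece) half-open intersections
  cls <- function(f) switch(f, promoter = "promoter",
                            first_exon = "exon", internal_exons = "exon",
                            last_exon = "exon", first_intron = "intron",
                            internal_introns = "intron", downstream = "downstream",
                            NA_character_)
  want <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(feats))) {
      ov <- min(dmrs$end[i], feats$end[j]) - max(dmrs$start[i], feats$start[j])
      fc <- cls(feats$feature[j])
      if (ov > 0 && feats$feature[j] != "upstream" && !is.na(fc)) {
        want[[length(want) + 1L]] <- data.table::data.table(
          gene_id = feats$gene_id[j], feature = fc, dmr_id = i)
      }
    }
  }
  want <- unique(data.table::rbindlist(want))
  got <- asg[!is.na(gene_id), .(gene_id, feature, dmr_id)]
  data.table::setorder(want, gene_id, feature, dmr_id)
  data.table::setorder(got, gene_id, feature, dmr_id)
  expect_equal(got, want)
})

test_that("zero-length promoter contact is not an overlap (half-open)", {
  genes <- data.table::data.table(gene_id = "g1", transcript_id = "g1.t",
                                  chrom = "chr1", strand = "+",
                                  start = 5000L, end = 5600L)
  ann <- annotation_set(genes, c(chr1 = 20000L))
  # promoter is [3000, 5000); a DMR ending exactly at 3000 only touches
  touch <- data.table::data.table(chrom = "chr1", start = 2000L, end = 3000L,
                                  direction = "hyper_in_a")
  inside <- data.table::data.table(chrom = "chr1", start = 3500L, end = 3600L,
                                   direction = "hyper_in_a")
  expect_equal(length(promoter_dmgs(annotate_dmrs(touch, ann))), 0L)
  expect_equal(promoter_dmgs(annotate_dmrs(inside, ann)), "g1")
  # unknown chromosome is reported unannotated
  far <- data.table::data.table(chrom = "chrZ", start = 10L, end = 20L,
                                direction = "hypo_in_a")
  asg <- annotate_dmrs(far, ann)
  expect_true(all(is.na(asg$gene_id)))
})
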