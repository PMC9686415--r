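# Landscape profiles: histograms, density-methylation matrices, metagene
# profiles, CpG island calling.

test_that("level histogram bins by floor(level*10) with 1.0 in the top bin", {
  mk <- function(levels) data.table::data.table(
    chrom = "chr1", pos = seq_along(levels) - 1L, strand = "+", context = "CG",
    meth = as.integer(round(levels * 20)), total = 20L)
  h <- level_histogram(mk(rep(1, 5)), "CG")
  expect_equal(h$fraction[10], 1)
  h2 <- level_histogram(mk(c(0.05, 0.95)), "CG")
  expect_equal(h2$fraction[c(1, 10)], c(0.5, 0.5))
  expect_equal(sum(h2$fraction), 1)
  expect_warning(h0 <- level_histogram(mk(rep(1, 5)), "CHH"), "all-zero")
  expect_true(isTRUE(attr(h0, "empty")))
})

test_that("histogram matches a per-site enumeration oracle on 1000 sites", {
  calls <- random_calls(1000, seed = 14, chroms = "chr1")
  calls <- unique(calls, by = c("chrom", "pos", "strand"))
  h <- level_histogram(calls, "CG", min_coverage = 4L)
  # oracle: loop over sites, increment bins
  bins <- rep(0L, 10)
  sub <- calls[context == "CG" & total >= 4 & meth >= 1]
  for (i in seq_len(nrow(sub))) {
    lev <- sub$meth[i] / sub$total[i]
    b <- min(floor(lev * 10), 9) + 1
    bins[b] <- bins[b] + 1L
  }
  expect_equal(h$count, bins)
  expect_equal(h$fraction, bins / sum(bins))
})

test_that("density matrix assigns windows by sequence CpG count and mean level", {
  # chr: 3 windows of 200bp; window 1 has 3 CpGs fully methylated,
  # window 2 is CpG-free, window 3 has 2 CpGs at mixed levels
  s <- paste(rep("A", 600), collapse = "")
  substr(s, 11, 12) <- "CG"; substr(s, 51, 52) <- "CG"; substr(s, 101, 102) <- "CG"
  substr(s, 451, 452) <- "CG"; substr(s, 501, 502) <- "CG"
  calls <- data.table::data.table(
    chrom = "chrT",
    pos = c(10L, 50L, 100L, 450L, 500L),
    strand = "+", context = "CG",
    meth = c(10L, 10L, 10L, 2L, 4L), total = 10L)
  dm <- density_meth_matrix(c(chrT = s), calls, window_bp = 200L)
  w <- dm$windows
  expect_equal(nrow(w), 2L)             # CpG-free window excluded
  expect_equal(w[start == 0, density], 3L)
  expect_equal(w[start == 0, level], 1)
  expect_equal(w[start == 400, density], 2L)
  expect_equal(w[start == 400, level], 0.3)
  expect_equal(sum(dm$matrix), nrow(w)) # count conservation
  expect_equal(dm$medians[density == 3, median_level], 1)
})

test_that("per-density medians match a sort-based oracle on random windows", {
  sim <- tiny_sim()
  dm <- density_meth_matrix(sim$genome, sim$samples$g1_r1, window_bp = 200L)
  expect_gt(nrow(dm$windows), 500)
  med_oracle <- function(x) { # median by explicit sorting
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  for (d in dm$medians$density) {
    expect_equal(dm$medians[density == d, median_level],
                 med_oracle(dm$windows[density == d, level]),
                 info = paste("density", d))
  }
  expect_equal(sum(dm$matrix), nrow(dm$windows))
})

test_that("interval mask restricts the matrix to overlapping windows", {
  sim <- tiny_sim()
  isl <- sim$annotation$cpg_islands
  dm_all <- density_meth_matrix(sim$genome, sim$samples$g1_r1)
  dm_isl <- density_meth_matrix(sim$genome, sim$samples$g1_r1, mask = isl)
  expect_lt(nrow(dm_isl$windows), nrow(dm_all$windows))
  # island windows are CpG-dense on average
  expect_gt(mean(dm_isl$windows$density), mean(dm_all$windows$density))
})

test_that("uniform methylation gives a flat metagene profile", {
  sim <- tiny_sim()
  s1 <- data.table::copy(sim$samples$g1_r1)
  s1[, `:=`(meth = 4L, total = 5L)]
  prof <- metagene_profile(s1, sim$annotation, bins_per_feature = 10L)
  filled <- prof[n_sites > 0]
  expect_true(all(abs(filled$mean_level - 0.8) < 1e-12))
  expect_true(all(abs(filled$smoothed - 0.8) < 1e-12))
})

test_that("metagene bin means match a hand-worked single-gene example", {
  # one + strand gene, 2 exons: [1000,1200) intron [1200,1400) exon [1400,1600)
  genes <- data.table::data.table(
    gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1", strand = "+",
    start = c(1000L, 1400L), end = c(1200L, 1600L))
  ann <- annotation_set(genes, c(chr1 = 10000L))
  # sites: first_exon offsets 5 and 25 (bins 0 and 1 of 10 20bp-bins),
  # first_intron offset 30 (bin 1), upstream offset 1990 (last bin)
  calls <- data.table::data.table(
    chrom = "chr1", pos = c(1005L, 1025L, 1230L, 990L), strand = "+",
    context = "CG", meth = c(8L, 4L, 2L, 10L), total = 10L)
  prof <- metagene_profile(calls, ann, bins_per_feature = 10L)
  cg <- prof[context == "CG"]
  expect_equal(cg[feature == "first_exon" & bin == 0, mean_level], 0.8)
  expect_equal(cg[feature == "first_exon" & bin == 1, mean_level], 0.4)
  expect_equal(cg[feature == "first_intron" & bin == 1, mean_level], 0.2)
  expect_equal(cg[feature == "upstream" & bin == 9, mean_level], 1.0)
  expect_equal(cg[feature == "first_exon" & bin == 5, n_sites], 0L)
})

test_that("minus-strand gene profile equals the mirror-image construction", {
  n <- 4000L
  withr::with_seed(77, {
    s_fwd <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  })
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
  s_rev <- revcomp(s_fwd)
  genes_fwd <- data.table::data.table(
    gene_id = "g", transcript_id = "g.t", chrom = "c", strand = "+",
    start = c(1500L, 2000L, 2600L), end = c(1800L, 2300L, 3000L))
  # mirrored coordinates on the reverse-complemented chromosome
  genes_rev <- data.table::copy(genes_fwd)[, `:=`(
    start = n - rev(genes_fwd$end), end = n - rev(genes_fwd$start),
    strand = "-")]
  ann_f <- annotation_set(genes_fwd, c(c = n))
  ann_r <- annotation_set(genes_rev, c(c = n))
  sites_f <- crispmeth:::enumerate_cytosines(c(c = s_fwd))
  sites_r <- crispmeth:::enumerate_cytosines(c(c = s_rev))
  withr::with_seed(78, lev <- runif(nrow(sites_f)))
  calls_f <- sites_f[, .(chrom, pos, strand, context,
                         meth = as.integer(round(lev * 10)), total = 10L)]
  # mirror the same per-site levels: position p maps to n-1-p, strand flips
  calls_r <- data.table::copy(calls_f)[, `:=`(pos = n - 1L - pos,
                                              strand = ifelse(strand == "+", "-", "+"))]
  calls_r[, context := classify_context(s_rev, pos, strand)]
  data.table::setorder(calls_r, pos)
  pf <- metagene_profile(calls_f, ann_f, bins_per_feature = 8L)
  pr <- metagene_profile(calls_r, ann_r, bins_per_feature = 8L)
  expect_equal(pf$mean_level, pr$mean_level, tolerance = 1e-12)
  expect_equal(pf$n_sites, pr$n_sites)
})

test_that("metagene profile is invariant to gene input order", {
  sim <- tiny_sim()
  ann <- sim$annotation
  shuf <- annotation_set(ann$genes[rev(seq_len(nrow(ann$genes)))],
                         ann$chrom_sizes, ann$cpg_islands)
  p1 <- metagene_profile(sim$samples$g1_r1, ann, bins_per_feature = 8L)
  p2 <- metagene_profile(sim$samples$g1_r1, shuf, bins_per_feature = 8L)
  expect_equal(p1, p2)
})

test_that("CG metagene dominates CHG/CHH at every covered bin under defaults", {
  sim <- tiny_sim()
  prof <- metagene_profile(sim$samples$g1_r1, sim$annotation,
                           bins_per_feature = 10L)
  wide <- data.table::dcast(prof, feature + bin ~ context,
                            value.var = "smoothed")
  filled <- wide[!is.na(CG) & !is.na(CHG) & !is.na(CHH)]
  expect_gt(nrow(filled), 30)
  expect_true(all(filled$CG > filled$CHG))
  expect_true(all(filled$CG > filled$CHH))
})

test_that("moving average of a constant is the constant; edges shrink", {
  expect_equal(moving_average(rep(3.5, 10)), rep(3.5, 10))
  x <- c(1, 2, 3, 4, 5)
  ma <- moving_average(x, 5L)
  expect_equal(ma[1], mean(x[1:3]))  # shrunk left edge
  expect_equal(ma[3], 3)
  expect_equal(ma[5], mean(x[3:5]))
})

test_that("Gardiner-Garden-Frommer island calling finds GC/CpG-rich patches", {
  withr::with_seed(55, {
    bg <- sample(c("A", "C", "G", "T"), 6000, TRUE, prob = c(0.35, 0.15, 0.15, 0.35))
    isl <- rep(c("C", "G"), 300) # 600 bp of pure CpG
    s <- paste(c(bg[1:3000], isl, bg[3001:6000]), collapse = "")
  })
  found <- find_cpg_islands(c(chr1 = s))
  expect_equal(nrow(found), 1L)
  expect_lt(abs(found$start - 3000), 250)
  expect_lt(abs(found$end - 3600), 250)
  # no islands in plain AT-rich sequence
  none <- find_cpg_islands(c(chr1 = paste(rep(c("A", "T"), 1000), collapse = "")))
  expect_equal(nrow(none), 0L)
})
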