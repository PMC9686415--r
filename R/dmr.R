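# Windowed two-group differential methylation: replicate pooling, two-sided
# Fisher exact testing, sliding-window scanning, DMR merging, and
# gene-feature annotation. The calling rule is: a window is significant when
# it contains at least `min_cpg` covered CpG sites, shows at least a
# `min_fold` change in pooled methylation level between groups, and has a
# two-sided Fisher exact p <= `p_max`.

#' Two-sided Fisher exact test for 2x2 count tables
#'
#' The two-sided p is the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (ties included up to a relative tolerance of 1e-7, the
#' usual convention). Vectorised over tables. An all-zero table has p = 1
#' by convention.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b Non-negative integer vectors: the
#'   2x2 table rows (group A meth/unmeth, group B meth/unmeth).
#' @return Numeric vector of p values in \[0, 1\].
#' @examples
#' fisher_two_sided(5, 0, 0, 5)  # 2/252
#' fisher_two_sided(3, 3, 3, 3)  # 1
#' @export
fisher_two_sided <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  a <- as.numeric(meth_a); b <- as.numeric(unmeth_a)
  c_ <- as.numeric(meth_b); d <- as.numeric(unmeth_b)
  n <- max(length(a), length(b), length(c_), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c_ <- rep_len(c_, n); d <- rep_len(d, n)
  if (any(c(a, b, c_, d) < 0)) stop_input("table entries must be non-negative")
  if (any(c(a, b, c_, d) != floor(c(a, b, c_, d)))) {
    stop_input("table entries must be integers")
  }
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c_[i] + d[i]; k <- a[i] + c_[i]
    if (r1 + r2 == 0) return(1)
    lo <- max(0, k - r2); hi <- min(k, r1)
    probs <- dhyper(lo:hi, r1, r2, k)
    p_obs <- probs[a[i] - lo + 1L]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Merge symmetric CpG counts onto the forward strand
#'
#' CpG methylation is strand-symmetric: the minus-strand cytosine of a CpG
#' sits one base 3' of the forward-strand C. For CG-context records this
#' sums the two strands into one CpG unit anchored at the forward C
#' position. Non-CG records pass through unchanged.
#'
#' @param records Cytosine call table.
#' @return Call table with CG records collapsed to forward-strand units.
#' @export
merge_cg_strands <- function(records) {
  records <- data.table::as.data.table(records)
  validate_calls(records)
  cg <- records[context == "CG"]
  rest <- records[is.na(context) | context != "CG"]
  if (nrow(cg)) {
    cg[, unit_pos := ifelse(strand == "+", pos, pos - 1L)]
    cg <- cg[, .(strand = "+", context = "CG",
                 meth = sum(meth), total = sum(total)),
             by = .(chrom, pos = unit_pos)]
  }
  out <- data.table::rbindlist(list(cg, rest), use.names = TRUE, fill = TRUE)
  data.table::setorder(out, chrom, pos)
  data.table::setcolorder(out, c("chrom", "pos", "strand", "context", "meth", "total"))
  out[]
}

# Pool replicate call tables of both groups into one per-site table.
# Returns chrom, pos, meth_a, total_a, meth_b, total_b for sites of the
# requested context passing the coverage floor in BOTH pooled groups.
# CG sites are strand-merged into CpG units first.
pool_sites <- function(records_a, records_b, context = "CG", min_coverage = 4L) {
  ctx <- context
  pool_group <- function(lst) {
    if (data.table::is.data.table(lst) || is.data.frame(lst)) lst <- list(lst)
    if (!length(lst)) stop_input("each group needs at least one replicate")
    dt <- data.table::rbindlist(lapply(lst, data.table::as.data.table))
    validate_calls(dt)
    dt <- dt[!is.na(context) & context == ctx]
    if (ctx == "CG") dt <- merge_cg_strands(dt)
    dt[, .(meth = sum(meth), total = sum(total)), by = .(chrom, pos)]
  }
  ga <- pool_group(records_a)
  gb <- pool_group(records_b)
  sites <- merge(ga, gb, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  sites <- sites[total_a >= min_coverage & total_b >= min_coverage]
  data.table::setorder(sites, chrom, pos)
  sites[]
}

#' Pool per-group read counts over a genomic interval
#'
#' Replicates within each group are summed ("all-replicate" pooling), then
#' counts are summed over every context site inside the half-open interval
#' that meets the coverage floor in both pooled groups. For the CG context
#' the covered-CpG count is over strand-merged CpG units.
#'
#' @param records_a,records_b Call table or list of replicate call tables.
#' @param interval List or vector `(chrom, start, end)`, 0-based half-open.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage Per-site pooled coverage floor applied per group.
#' @return List: `meth_a`, `total_a`, `meth_b`, `total_b`,
#'   `n_cpg_covered`, `level_a`, `level_b`.
#' @export
pool_counts <- function(records_a, records_b, interval, context = "CG",
                        min_coverage = 4L) {
  sites <- pool_sites(records_a, records_b, context, min_coverage)
  iv_chrom <- as.character(interval[[1L]])
  iv_start <- as.integer(interval[[2L]]); iv_end <- as.integer(interval[[3L]])
  sub <- sites[chrom == iv_chrom & pos >= iv_start & pos < iv_end]
  list(meth_a = sum(sub$meth_a), total_a = sum(sub$total_a),
       meth_b = sum(sub$meth_b), total_b = sum(sub$total_b),
       n_cpg_covered = nrow(sub),
       level_a = if (sum(sub$total_a) > 0) sum(sub$meth_a) / sum(sub$total_a) else NA_real_,
       level_b = if (sum(sub$total_b) > 0) sum(sub$meth_b) / sum(sub$total_b) else NA_real_)
}

#' Scan sliding windows and test each for differential methylation
#'
#' Tiles every chromosome with sliding windows (default 1000 bp wide,
#' 500 bp step), pools replicate counts per window and group, and computes
#' pooled levels, fold change (`max(level) / max(min(level), eps)`), the
#' two-sided Fisher exact p of the pooled 2x2 table, and a
#' Benjamini-Hochberg q across all emitted windows. Windows with fewer than
#' `min_cpg` covered CpG sites are skipped.
#'
#' @param records_a,records_b Call table or list of replicate tables per group.
#' @param context Cytosine context to test.
#' @param width,step Window geometry in bp.
#' @param min_cpg Minimum covered CpG sites for a window to be emitted.
#' @param min_coverage Per-site pooled coverage floor per group.
#' @param fold_eps Pseudocount on the fold-change denominator.
#' @return Object of class `meth_windows`: list with `windows` (data.table:
#'   chrom, start, end, n_cpg, counts, levels, fold, p_value, q_value,
#'   direction), `sites` (the pooled per-site table), and `params`.
#' @export
scan_windows <- function(records_a, records_b, context = "CG", width = 1000L,
                         step = 500L, min_cpg = 5L, min_coverage = 4L,
                         fold_eps = 1e-6) {
  if (width <= 0L || step <= 0L) stop_input("width and step must be positive")
  if (step > width) warning("step > width leaves gaps between windows")
  sites <- pool_sites(records_a, records_b, context, min_coverage)
  offsets <- unique(seq(0L, width - 1L, by = step) %% width)
  wins <- data.table::rbindlist(lapply(offsets, function(off) {
    s <- sites[pos >= off]
    if (!nrow(s)) return(NULL)
    s[, win_start := ((pos - off) %/% width) * width + off]
    s[, .(n_cpg = .N, meth_a = sum(meth_a), total_a = sum(total_a),
          meth_b = sum(meth_b), total_b = sum(total_b)),
      by = .(chrom, start = win_start)]
  }))
  if (!nrow(wins)) {
    return(structure(list(windows = empty_windows(), sites = sites,
                          params = list(context = context, width = width,
                                        step = step, min_cpg = min_cpg,
                                        min_coverage = min_coverage,
                                        fold_eps = fold_eps)),
                     class = "meth_windows"))
  }
  wins <- wins[n_cpg >= min_cpg]
  wins[, end := start + width]
  wins[, level_a := meth_a / total_a]
  wins[, level_b := meth_b / total_b]
  wins[, fold := pmax(level_a, level_b) / pmax(pmin(level_a, level_b), fold_eps)]
  wins[, p_value := fisher_two_sided(meth_a, total_a - meth_a,
                                     meth_b, total_b - meth_b)]
  wins[, q_value := p.adjust(p_value, method = "BH")]
  wins[, direction := ifelse(level_a >= level_b, "hyper_in_a", "hypo_in_a")]
  data.table::setorder(wins, chrom, start)
  data.table::setcolorder(wins, c("chrom", "start", "end", "n_cpg"))
  structure(list(windows = wins[], sites = sites,
                 params = list(context = context, width = width, step = step,
                               min_cpg = min_cpg, min_coverage = min_coverage,
                               fold_eps = fold_eps)),
            class = "meth_windows")
}

empty_windows <- function() {
  data.table::data.table(
    chrom = character(), start = integer(), end = integer(), n_cpg = integer(),
    meth_a = integer(), total_a = integer(), meth_b = integer(),
    total_b = integer(), level_a = numeric(), level_b = numeric(),
    fold = numeric(), p_value = numeric(), q_value = numeric(),
    direction = character())
}

#' @export
print.meth_windows <- function(x, ...) {
  cat("meth_windows:", nrow(x$windows), "windows (", x$params$context,
      "context,", x$params$width, "/", x$params$step, "bp ) over",
      nrow(x$sites), "covered sites\n")
  invisible(x)
}

#' Call differentially methylated regions from scanned windows
#'
#' Windows passing all three criteria — at least `min_cpg` covered CpGs,
#' fold change of at least `min_fold`, Fisher p at most `p_max` — are
#' retained; overlapping or book-ended significant windows with the same
#' direction are merged, and the merged region's pooled counts, level,
#' fold and p are recomputed over the merged span from the per-site table.
#'
#' @param windows A `meth_windows` object from [scan_windows()] (or a
#'   window data.table plus a `sites` table).
#' @param p_max,min_fold,min_cpg The calling thresholds.
#' @param sites Pooled per-site table; defaults to the one carried by
#'   `windows`.
#' @return `data.table` of DMRs: interval, `n_windows`, `n_cpg`, pooled
#'   counts and levels, `fold`, `p_value`, `direction`, `context`.
#' @export
call_dmrs <- function(windows, p_max = 0.05, min_fold = 2.0, min_cpg = 5L,
                      sites = NULL) {
  if (inherits(windows, "meth_windows")) {
    sites <- sites %||% windows$sites
    context <- windows$params$context
    fold_eps <- windows$params$fold_eps
    wt <- windows$windows
  } else {
    if (is.null(sites)) stop_input("`sites` table required for merged-region statistics")
    context <- attr(windows, "context") %||% "CG"
    fold_eps <- 1e-6
    wt <- data.table::as.data.table(windows)
  }
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    n_windows = integer(), n_cpg = integer(), meth_a = integer(),
    total_a = integer(), meth_b = integer(), total_b = integer(),
    level_a = numeric(), level_b = numeric(), fold = numeric(),
    p_value = numeric(), direction = character(), context = character())
  if (!nrow(wt)) return(empty)
  sig <- wt[n_cpg >= min_cpg & fold >= min_fold & p_value <= p_max]
  if (!nrow(sig)) return(empty)
  data.table::setorder(sig, chrom, direction, start)
  # chained-overlap merge: a new region starts when a window begins past the
  # running max end of its (chrom, direction) run
  sig[, grp := {
    ce <- cummax(end)
    cumsum(c(1L, start[-1L] > ce[-.N]))
  }, by = .(chrom, direction)]
  merged <- sig[, .(start = min(start), end = max(end), n_windows = .N),
                by = .(chrom, direction, grp)][, grp := NULL]
  # recompute statistics over the merged spans
  stats_dt <- merged[, {
    sub <- sites[chrom == .BY$chrom & pos >= start & pos < end]
    list(n_cpg = nrow(sub),
         meth_a = sum(sub$meth_a), total_a = sum(sub$total_a),
         meth_b = sum(sub$meth_b), total_b = sum(sub$total_b))
  }, by = .(chrom, direction, start, end, n_windows)]
  stats_dt[, level_a := meth_a / pmax(total_a, 1L)]
  stats_dt[, level_b := meth_b / pmax(total_b, 1L)]
  stats_dt[, fold := pmax(level_a, level_b) / pmax(pmin(level_a, level_b), fold_eps)]
  stats_dt[, p_value := fisher_two_sided(meth_a, total_a - meth_a,
                                         meth_b, total_b - meth_b)]
  stats_dt[, context := context]
  data.table::setorder(stats_dt, chrom, start)
  data.table::setcolorder(stats_dt, c("chrom", "start", "end", "n_windows",
                                      "n_cpg", "meth_a", "total_a", "meth_b",
                                      "total_b", "level_a", "level_b", "fold",
                                      "p_value", "direction", "context"))
  stats_dt[]
}

#' Annotate DMRs with overlapping gene features
#'
#' Each DMR is intersected (half-open, >= 1 bp overlap) with the promoter,
#' exon, intron and downstream features of every gene. A zero-length
#' touching contact is not an overlap. DMRs on chromosomes absent from the
#' annotation are reported unannotated (feature `NA`).
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param annotation An [annotation_set()].
#' @param upstream_bp,downstream_bp Flank widths for [gene_features()].
#' @return `data.table`: `gene_id`, `feature` (promoter / exon / intron /
#'   downstream), `dmr_id` (row of `dmrs`), `chrom`, `start`, `end`,
#'   `direction`.
#' @export
annotate_dmrs <- function(dmrs, annotation, upstream_bp = 2000L,
                          downstream_bp = 2000L) {
  dmrs <- data.table::as.data.table(dmrs)
  empty <- data.table::data.table(
    gene_id = character(), feature = character(), dmr_id = integer(),
    chrom = character(), start = integer(), end = integer(),
    direction = character())
  if (!nrow(dmrs)) return(empty)
  feats <- gene_features(annotation, upstream_bp, downstream_bp)
  # collapse the seven metagene features into the four annotation classes
  feats[, feature := data.table::fcase(
    feature == "promoter", "promoter",
    feature %in% c("first_exon", "internal_exons", "last_exon"), "exon",
    feature %in% c("first_intron", "internal_introns"), "intron",
    feature == "downstream", "downstream",
    default = NA_character_)]
  feats <- feats[!is.na(feature)]
  gr_d <- to_granges(dmrs)
  gr_f <- to_granges(feats)
  # chromosomes absent from the annotation are reported unannotated below,
  # so the disjoint-seqlevels warning carries no information here
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_d, gr_f, minoverlap = 1L))
  if (!length(hits)) {
    unann <- dmrs[!chrom %in% unique(annotation$genes$chrom)]
    if (nrow(unann)) {
      return(data.table::data.table(
        gene_id = NA_character_, feature = NA_character_,
        dmr_id = which(!dmrs$chrom %in% unique(annotation$genes$chrom)),
        chrom = unann$chrom, start = unann$start, end = unann$end,
        direction = unann$direction))
    }
    return(empty)
  }
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.table::data.table(
    gene_id = feats$gene_id[si], feature = feats$feature[si],
    dmr_id = qi, chrom = dmrs$chrom[qi], start = dmrs$start[qi],
    end = dmrs$end[qi], direction = dmrs$direction[qi])
  out <- unique(out)
  # DMRs on chromosomes the annotation does not know
  missing_chr <- which(!dmrs$chrom %in% unique(annotation$genes$chrom))
  if (length(missing_chr)) {
    out <- data.table::rbindlist(list(out, data.table::data.table(
      gene_id = NA_character_, feature = NA_character_, dmr_id = missing_chr,
      chrom = dmrs$chrom[missing_chr], start = dmrs$start[missing_chr],
      end = dmrs$end[missing_chr], direction = dmrs$direction[missing_chr])))
  }
  data.table::setorder(out, gene_id, dmr_id)
  out[]
}

#' Promoter differentially methylated genes
#'
#' A gene is a promoter DMG iff at least one DMR overlaps its promoter
#' (2 kb upstream of the TSS by default). Each gene is counted once.
#'
#' @param assignments Output of [annotate_dmrs()].
#' @return Character vector of unique gene ids.
#' @export
promoter_dmgs <- function(assignments) {
  assignments <- data.table::as.data.table(assignments)
  if (!nrow(assignments)) return(character())
  sort(unique(assignments[feature == "promoter" & !is.na(gene_id), gene_id]))
}
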