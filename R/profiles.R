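# Methylome landscape statistics: methylation-level histograms, CpG-density
# by methylation-level matrices with per-density median traces, and
# seven-feature metagene profiles.

#' Methylation-level histogram of methylated cytosines
#'
#' Each methylated cytosine (>= 1 methylated read) of the requested context
#' meeting the coverage floor is assigned to one of ten bins of width 10%
#' by `floor(level * 10)`; a level of exactly 1.0 goes to the top bin.
#' Fractions are normalised by the total mC count of the context.
#'
#' @param records Cytosine call table.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage Coverage floor for a site to enter the histogram.
#' @return `data.table` with `bin` (0-9), `bin_label`, `count`, `fraction`.
#'   If the context has no methylated sites all counts are zero and the
#'   result carries attribute `empty = TRUE`.
#' @export
level_histogram <- function(records, context = "CG", min_coverage = 4L) {
  ctx <- context
  records <- data.table::as.data.table(records)
  validate_calls(records)
  rec <- records[!is.na(records$context) & records$context == ctx &
                   total >= min_coverage & meth >= 1L]
  out <- data.table::data.table(
    bin = 0:9,
    bin_label = paste0(seq(0, 90, 10), "-", seq(10, 100, 10), "%"),
    count = 0L)
  if (nrow(rec)) {
    lev <- rec$meth / rec$total
    b <- pmin(floor(lev * 10), 9)
    tab <- tabulate(b + 1L, nbins = 10L)
    out[, count := tab]
  }
  empty_flag <- sum(out$count) == 0L
  out[, fraction := if (empty_flag) 0 else count / sum(count)]
  out[, context := ctx]
  if (empty_flag) {
    warning(sprintf("no methylated %s sites: all-zero histogram", ctx))
    data.table::setattr(out, "empty", TRUE)
  }
  out[]
}

#' CpG-density by methylation-level matrix
#'
#' The genome is tiled with non-overlapping windows (default 200 bp). Per
#' window the CpG dinucleotide count is taken from the sequence and the
#' methylation level is the unweighted mean level of covered CG-context
#' cytosines inside it. Windows with no covered CpG are excluded. Cells
#' count windows per (level bin, CpG count); a per-density median level
#' trace is computed.
#'
#' @param genome Named list/`DNAStringSet` of chromosome sequences, or a
#'   FASTA path.
#' @param records Cytosine call table.
#' @param window_bp Tile width (default 200).
#' @param mask Optional interval table (`chrom`, `start`, `end`): only
#'   windows overlapping the mask by >= 1 bp are counted (genomic-feature
#'   restriction).
#' @param min_coverage Coverage floor for a site to contribute.
#' @param level_bins Number of methylation-level bins (default 10).
#' @return List of class `density_meth_matrix`: `matrix` (level bins x CpG
#'   densities), `medians` (per density), `windows` (per-window table),
#'   `density_marginal`, `level_marginal`.
#' @export
density_meth_matrix <- function(genome, records, window_bp = 200L, mask = NULL,
                                min_coverage = 4L, level_bins = 10L) {
  if (window_bp <= 0L) stop_input("window_bp must be positive")
  genome <- load_genome(genome)
  records <- data.table::as.data.table(records)
  validate_calls(records)
  cg <- records[!is.na(context) & context == "CG" & total >= min_coverage]
  win_list <- lapply(names(genome), function(cx) {
    s <- genome[[cx]]
    L <- nchar(s)
    n_win <- L %/% window_bp # complete tiles only
    if (n_win == 0L) return(NULL)
    # CpG dinucleotide starts
    cpg_pos <- gregexpr("CG", s, fixed = TRUE)[[1L]]
    cpg_pos <- cpg_pos[cpg_pos > 0L] - 1L # 0-based
    dens <- tabulate(cpg_pos %/% window_bp + 1L, nbins = n_win)
    sub <- cg[chrom == cx & pos < n_win * window_bp]
    msum <- rep(0, n_win); mn <- rep(0L, n_win)
    if (nrow(sub)) {
      wi <- sub$pos %/% window_bp + 1L
      lev <- sub$meth / sub$total
      msum <- unname(vapply(split(lev, factor(wi, levels = seq_len(n_win))),
                            sum, numeric(1)))
      mn <- tabulate(wi, nbins = n_win)
    }
    data.table::data.table(chrom = cx,
                           start = (seq_len(n_win) - 1L) * window_bp,
                           end = seq_len(n_win) * window_bp,
                           density = dens, n_covered = mn,
                           level = ifelse(mn > 0L, msum / pmax(mn, 1L), NA_real_))
  })
  wins <- data.table::rbindlist(win_list)
  wins <- wins[!is.na(level)]
  if (!is.null(mask)) {
    mask <- data.table::as.data.table(mask)
    hits <- GenomicRanges::findOverlaps(to_granges(wins), to_granges(mask),
                                        minoverlap = 1L)
    wins <- wins[sort(unique(S4Vectors::queryHits(hits)))]
  }
  if (!nrow(wins)) stop_input("no windows with covered CpGs")
  wins[, bin := pmin(floor(level * level_bins), level_bins - 1L)]
  dens_vals <- sort(unique(wins$density))
  mat <- matrix(0L, nrow = level_bins, ncol = length(dens_vals),
                dimnames = list(level_bin = seq_len(level_bins) - 1L,
                                density = dens_vals))
  tab <- wins[, .N, by = .(bin, density)]
  mat[cbind(tab$bin + 1L, match(tab$density, dens_vals))] <- tab$N
  med <- wins[, .(median_level = stats::median(level)), by = density]
  data.table::setorder(med, density)
  structure(list(matrix = mat, medians = med, windows = wins[],
                 density_marginal = wins[, .N, by = density][order(density)],
                 level_marginal = wins[, .N, by = bin][order(bin)],
                 window_bp = window_bp),
            class = "density_meth_matrix")
}

#' @export
print.density_meth_matrix <- function(x, ...) {
  cat("density_meth_matrix:", sum(x$matrix), "windows of", x$window_bp,
      "bp;", ncol(x$matrix), "density columns\n")
  invisible(x)
}

# Accept a DNAStringSet, named character vector/list, or FASTA path.
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*$", "", names(genome)))
  } else if (is.list(genome)) {
    genome <- vapply(genome, as.character, character(1))
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop_input("genome sequences must be named by chromosome")
  }
  toupper(genome)
}

#' Centered moving average with shrinking edge windows
#'
#' `k`-bin centered moving average; near the series edges the window
#' shrinks symmetrically to the available bins, so the average of a
#' constant series is that constant everywhere.
#'
#' @param x Numeric vector (NAs are dropped within each window).
#' @param k Window size in bins (default 5).
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(x, k = 5L) {
  half <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Metagene methylation profile over seven gene features
#'
#' Each gene's features (`upstream`, `first_exon`, `first_intron`,
#' `internal_exons`, `internal_introns`, `last_exon`, `downstream`) are
#' length-normalised into `bins_per_feature` equal bins (integer partition,
#' remainder to the 5'-most bins; features shorter than the bin count map
#' sites proportionally). Covered site levels are averaged per bin across
#' genes and contexts, and a 5-bin centered moving average is attached.
#' Genes lacking a feature (e.g. single-exon genes) contribute only to the
#' features they have.
#'
#' @param records Cytosine call table.
#' @param annotation An [annotation_set()].
#' @param bins_per_feature Bins per feature (default 20).
#' @param min_coverage Coverage floor per site.
#' @param contexts Contexts to profile.
#' @param upstream_bp,downstream_bp Flank widths.
#' @return `data.table`: `context`, `feature`, `bin`, `n_sites`,
#'   `mean_level`, `smoothed`; features ordered 5' to 3'.
#' @export
metagene_profile <- function(records, annotation, bins_per_feature = 20L,
                             min_coverage = 4L,
                             contexts = c("CG", "CHG", "CHH"),
                             upstream_bp = 2000L, downstream_bp = 2000L) {
  if (bins_per_feature < 5L) {
    warning("fewer than 5 bins per feature degrades the 5-bin moving average")
  }
  records <- data.table::as.data.table(records)
  validate_calls(records)
  rec <- records[!is.na(context) & context %in% contexts & total >= min_coverage]
  rec[, level := meth / total]
  feats <- gene_features(annotation, upstream_bp, downstream_bp)
  feats <- feats[feature != "promoter"]
  feature_order <- c("upstream", "first_exon", "first_intron", "internal_exons",
                     "internal_introns", "last_exon", "downstream")
  B <- as.integer(bins_per_feature)
  # transcription-ordered cumulative offset of each feature piece
  data.table::setorder(feats, gene_id, feature, piece_rank)
  feats[, width_bp := end - start]
  feats[, offset0 := cumsum(c(0L, width_bp[-.N])), by = .(gene_id, feature)]
  # map sites onto feature pieces
  gr_s <- GenomicRanges::GRanges(rec$chrom,
                                 IRanges::IRanges(rec$pos + 1L, rec$pos + 1L))
  gr_f <- to_granges(feats)
  hits <- GenomicRanges::findOverlaps(gr_s, gr_f)
  if (!length(hits)) stop_input("no covered sites fall inside gene features")
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dt <- data.table::data.table(
    context = rec$context[qi], level = rec$level[qi],
    gene_id = feats$gene_id[si], feature = feats$feature[si],
    pos = rec$pos[qi], fstart = feats$start[si], fend = feats$end[si],
    fstrand = feats$strand[si], offset0 = feats$offset0[si])
  # transcription-orientation offset within the concatenated feature
  dt[, offset := ifelse(fstrand == "+", pos - fstart, fend - 1L - pos) + offset0]
  flen <- feats[, .(len = sum(width_bp)), by = .(gene_id, feature)]
  dt <- merge(dt, flen, by = c("gene_id", "feature"))
  dt[, bin := bin_offset(offset, len, B)]
  prof <- dt[, .(n_sites = .N, mean_level = mean(level)),
             by = .(context, feature, bin)]
  # complete grid so every feature has all bins
  grid <- data.table::CJ(context = contexts, feature = feature_order,
                         bin = seq_len(B) - 1L)
  prof <- merge(grid, prof, by = c("context", "feature", "bin"), all.x = TRUE)
  prof[is.na(n_sites), n_sites := 0L]
  prof[, feature := factor(feature, levels = feature_order)]
  data.table::setorder(prof, context, feature, bin)
  prof[, smoothed := moving_average(mean_level, 5L), by = .(context, feature)]
  prof[]
}

# Assign a 0-based offset within a feature of length `len` to one of B bins:
# equal integer partition with the remainder spread over the leading (5')
# bins; features shorter than B map proportionally.
bin_offset <- function(offset, len, B) {
  out <- integer(length(offset))
  for (L in unique(len)) {
    i <- which(len == L)
    if (L >= B) {
      q <- L %/% B; r <- L %% B
      sizes <- rep(q, B) + c(rep(1L, r), rep(0L, B - r))
      edges <- cumsum(sizes)
      out[i] <- findInterval(offset[i], c(0L, edges), rightmost.closed = FALSE,
                             left.open = FALSE) - 1L
    } else {
      out[i] <- pmin(B - 1L, floor(offset[i] * B / L))
    }
  }
  pmin(pmax(out, 0L), B - 1L)
}

#' Call CpG islands by the Gardiner-Garden and Frommer criteria
#'
#' Sliding 200 bp windows (1 bp step) qualifying on all three criteria —
#' length >= 200 bp, GC fraction >= `min_gc`, observed/expected CpG ratio
#' >= `min_oe` (obs/exp = n_CpG * window / (n_C * n_G)) — are merged into
#' islands.
#'
#' @param genome Genome (see [density_meth_matrix()]).
#' @param window_bp Window width (default 200).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_oe Minimum observed/expected CpG ratio (default 0.6).
#' @return `data.table` of islands: `chrom`, `start`, `end` (half-open).
#' @export
find_cpg_islands <- function(genome, window_bp = 200L, min_gc = 0.5,
                             min_oe = 0.6) {
  genome <- load_genome(genome)
  res <- lapply(names(genome), function(cx) {
    s <- strsplit(genome[[cx]], "", fixed = TRUE)[[1L]]
    L <- length(s)
    if (L < window_bp) return(NULL)
    isC <- as.integer(s == "C"); isG <- as.integer(s == "G")
    isCG <- as.integer(s == "C" & c(s[-1L], "") == "G")
    cC <- cumsum(isC); cG <- cumsum(isG); cCG <- cumsum(isCG)
    n_win <- L - window_bp + 1L
    idx0 <- seq_len(n_win) - 1L # 0-based window starts
    wC <- cC[idx0 + window_bp] - c(0L, cC)[idx0 + 1L]
    wG <- cG[idx0 + window_bp] - c(0L, cG)[idx0 + 1L]
    # CpG starts within [start, start+window-1); last position cannot start a CpG inside
    wCG <- cCG[idx0 + window_bp - 1L] - c(0L, cCG)[idx0 + 1L]
    gc <- (wC + wG) / window_bp
    oe <- ifelse(wC * wG > 0, wCG * window_bp / (wC * wG), 0)
    ok <- which(gc >= min_gc & oe >= min_oe)
    if (!length(ok)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(start = ok, width = window_bp))
    data.table::data.table(chrom = cx, start = IRanges::start(ir) - 1L,
                           end = IRanges::end(ir))
  })
  out <- data.table::rbindlist(res)
  if (!nrow(out)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  data.table::setorder(out, chrom, start)
  out[]
}
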