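# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats dhyper phyper p.adjust rbeta rbinom rnorm rpois runif
#' @importFrom utils head tail
NULL

# Quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "strand", "context", "meth", "total",
  "level", "start", "end", "gene_id", "feature", "win_start", "n_cpg",
  "meth_a", "total_a", "meth_b", "total_b", "level_a", "level_b",
  "fold", "p_value", "q_value", "direction", "bin", "piece_rank",
  "density", "score", "from", "to", "log2_fc", "fdr", "unit_pos",
  "transcript_id", "type", "exon_rank", "offset0", "island", "mean_level",
  "smoothed", "n_windows", "name", "width_bp", "tx_len", "grp", ".BY", ".GRP",
  "neg_log10_p", "V1", "V2", "V4", "V6", "V10", "V11", "V12",
  "offset", "fstart", "fend", "fstrand", "len", "n_covered", "count",
  "fraction", "bin_label", "median_level", "n_sites", "nuc", "dinuc",
  "mu1", "mu2", "island_hyper", "meth_direction", "anticorrelated",
  "in_overlap", "in_pathway", "in_curated", "selected", "pathways",
  "concord", "k", "K", "set_name", "degree", "significant", "N"
))

# Scope the global RNG: run `code` under a seed derived from (seed, stage)
# and restore the previous RNG state afterwards. All generator stages go
# through this so a single config seed determines every output.
with_stage_seed <- function(seed, stage, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # Fold the stage label into the seed; keep the result inside 32-bit range.
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  sub_seed <- (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
  sub_seed <- sub_seed %% 2147483629L
  withr::with_seed(sub_seed, code)
}

# Round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

assert_cols <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop_input("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
}

# Validate a cytosine call table (internal convention: 0-based pos).
validate_calls <- function(dt, what = "cytosine table") {
  assert_cols(dt, c("chrom", "pos", "strand", "context", "meth", "total"), what)
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(dt$meth < 0L) || any(dt$total < 0L)) {
    stop_input("%s: negative read counts", what)
  }
  bad <- which(dt$meth > dt$total)
  if (length(bad)) {
    stop_input("%s: meth_count > total_count at row %d (%s:%d)", what,
               bad[1L], dt$chrom[bad[1L]], dt$pos[bad[1L]])
  }
  if (!all(dt$strand %in% c("+", "-"))) stop_input("%s: strand must be + or -", what)
  if (!all(dt$context %in% c("CG", "CHG", "CHH", NA_character_))) {
    stop_input("%s: context must be CG, CHG, CHH or NA", what)
  }
  invisible(dt)
}

# 0-based half-open intervals -> IRanges/GRanges (1-based closed) and back.
to_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
}
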