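# Site-level and genome-level methylation statistics: levels, context
# classification, bisulfite conversion rate, and alignment/context summary
# arithmetic.

#' Per-site methylation level
#'
#' The methylation level of a cytosine is the number of reads supporting
#' methylation divided by the total reads covering the site,
#' \eqn{R_m = N_m / (N_m + N_{nm})}. Vectorised.
#'
#' @param meth_count Non-negative integer vector of methylated read counts.
#' @param total_count Positive integer vector of total read counts.
#' @return Numeric vector of fractions in \[0, 1\]; `NA` where
#'   `total_count` is zero (such sites are excluded upstream).
#' @examples
#' methylation_level(3, 4)   # 0.75
#' methylation_level(0, 15)  # 0
#' @export
methylation_level <- function(meth_count, total_count) {
  if (any(meth_count < 0 | total_count < 0, na.rm = TRUE)) {
    stop_input("read counts must be non-negative")
  }
  if (any(meth_count > total_count, na.rm = TRUE)) {
    stop_input("meth_count cannot exceed total_count")
  }
  ifelse(total_count > 0, meth_count / total_count, NA_real_)
}

#' Classify cytosine sequence context (CG / CHG / CHH)
#'
#' Context is determined by the two bases immediately 3' of the cytosine on
#' its own strand (H = A, C or T). On the minus strand the rule is applied
#' to the reverse complement. Sites within 2 bp of a contig end with too
#' little sequence to decide, or with ambiguous (non-ACGT) following bases,
#' are classified `NA`.
#'
#' @param sequence Chromosome sequence: a single character string, a
#'   character vector of single bases, or a [Biostrings::DNAString].
#' @param pos Integer vector of 0-based positions on the forward strand.
#' @param strand Character vector of "+" / "-" (recycled).
#' @return Character vector in `c("CG", "CHG", "CHH", NA)`.
#' @examples
#' classify_context("ACGT", 1, "+")  # "CG"
#' classify_context("ACTG", 1, "+")  # "CHG"
#' classify_context("ACTT", 1, "+")  # "CHH"
#' @export
classify_context <- function(sequence, pos, strand) {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  if (length(sequence) == 1L && nchar(sequence[1L]) != 1L) {
    s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  } else {
    s <- toupper(sequence)
  }
  n <- length(s)
  pos <- as.integer(pos)
  if (length(strand) == 1L) strand <- rep(strand, length(pos))
  if (any(pos < 0L) || any(pos >= n)) stop_input("pos out of chromosome bounds")
  plus <- strand == "+"
  base <- s[pos + 1L]
  if (any(plus & base != "C") || any(!plus & base != "G")) {
    i <- which((plus & base != "C") | (!plus & base != "G"))[1L]
    stop_input("base at position %d is not a cytosine on strand %s",
               pos[i], strand[i])
  }
  step <- ifelse(plus, 1L, -1L)
  i1 <- pos + 1L + step
  i2 <- pos + 1L + 2L * step
  get_base <- function(idx) {
    ok <- idx >= 1L & idx <= n
    out <- rep(NA_character_, length(idx))
    out[ok] <- s[idx[ok]]
    out
  }
  b1 <- get_base(i1)
  b2 <- get_base(i2)
  # sense-strand identity of the following bases
  g1 <- ifelse(plus, b1 == "G", b1 == "C")
  h1 <- ifelse(plus, b1 %in% c("A", "C", "T"), b1 %in% c("A", "G", "T"))
  g2 <- ifelse(plus, b2 == "G", b2 == "C")
  h2 <- ifelse(plus, b2 %in% c("A", "C", "T"), b2 %in% c("A", "G", "T"))
  ctx <- rep(NA_character_, length(pos))
  known1 <- !is.na(b1)
  ctx[known1 & g1] <- "CG"
  need2 <- known1 & !g1 & h1
  ctx[need2 & !is.na(b2) & g2] <- "CHG"
  ctx[need2 & !is.na(b2) & h2] <- "CHH"
  ctx
}

#' Context shares of methylated cytosines
#'
#' Percentage share of each sequence context among all methylated
#' cytosines: `100 * context_count / total_mC`, rounded to 2 decimals.
#'
#' @param mcg,mchg,mchh Counts of methylated cytosines per context.
#' @return Named numeric vector (`CG`, `CHG`, `CHH`) of percentages.
#' @examples
#' context_shares(26421894, 237327, 906008)  # 95.85 0.86 3.29
#' @export
context_shares <- function(mcg, mchg, mchh) {
  counts <- c(CG = mcg, CHG = mchg, CHH = mchh)
  if (any(counts < 0)) stop_input("context counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop_input("no methylated cytosines: shares undefined")
  round(100 * counts / tot, 2)
}

#' Summarise a methylome: per-context mC counts, shares and mean levels
#'
#' A cytosine counts as methylated either by the simple evidence rule
#' (`meth >= min_meth_evidence`, default 1 read) or, with
#' `rule = "binom"`, by a one-sided binomial test of its counts against
#' the bisulfite conversion failure rate at Benjamini-Hochberg q < 0.05.
#' Mean levels are computed over sites meeting the coverage floor.
#'
#' @param records Cytosine call table (see [read_cytosine_table()]).
#' @param min_meth_evidence Minimum methylated reads to call a site mC.
#' @param min_coverage Coverage floor for reporting a site level.
#' @param rule `"count"` (default) or `"binom"`.
#' @param conversion_failure Assumed conversion failure rate for
#'   `rule = "binom"`.
#' @param sample_id Optional label carried into the summary.
#' @return A list of class `methylome_summary`: `counts`, `shares`
#'   (percentages), `mean_levels`, `n_sites`, `sample_id`.
#' @export
summarize_methylome <- function(records, min_meth_evidence = 1L,
                                min_coverage = 4L, rule = c("count", "binom"),
                                conversion_failure = 0.01, sample_id = NA_character_) {
  rule <- match.arg(rule)
  records <- data.table::as.data.table(records)
  validate_calls(records)
  rec <- records[!is.na(context) & total > 0L]
  if (rule == "count") {
    is_mc <- rec$meth >= min_meth_evidence
  } else {
    pv <- stats::pbinom(rec$meth - 1L, rec$total, conversion_failure,
                        lower.tail = FALSE)
    is_mc <- stats::p.adjust(pv, method = "BH") < 0.05 & rec$meth >= 1L
  }
  mc <- rec[is_mc]
  counts <- c(CG = nrow(mc[context == "CG"]),
              CHG = nrow(mc[context == "CHG"]),
              CHH = nrow(mc[context == "CHH"]))
  shares <- if (sum(counts) > 0) context_shares(counts[["CG"]], counts[["CHG"]],
                                                counts[["CHH"]]) else
    c(CG = NA_real_, CHG = NA_real_, CHH = NA_real_)
  cov_ok <- rec[total >= min_coverage]
  mean_levels <- vapply(c("CG", "CHG", "CHH"), function(cx) {
    sub <- cov_ok[context == cx]
    if (nrow(sub) == 0L) NA_real_ else mean(sub$meth / sub$total)
  }, numeric(1))
  structure(list(counts = counts, shares = shares, mean_levels = mean_levels,
                 n_sites = nrow(rec), n_mc = sum(counts),
                 sample_id = sample_id),
            class = "methylome_summary")
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("Methylome summary", if (!is.na(x$sample_id)) paste0("(", x$sample_id, ")"),
      "\n  mC counts:  ", paste(names(x$counts), format(x$counts, big.mark = ","),
                                collapse = "  "),
      "\n  shares (%): ", paste(names(x$shares), x$shares, collapse = "  "),
      "\n  mean level: ", paste(names(x$mean_levels),
                                round(x$mean_levels, 4), collapse = "  "), "\n")
  invisible(x)
}

#' Bisulfite conversion rate from an unmethylated lambda spike-in
#'
#' Conversion rate (%) = 100 * (1 - methylation rate of the lambda DNA),
#' where the lambda methylation rate is the pooled
#' `sum(meth) / sum(total)` over all covered lambda cytosines. Because the
#' spike-in is truly unmethylated, any apparent methylation measures
#' conversion failure.
#'
#' @param lambda_records Cytosine call table for the lambda control.
#' @return Conversion rate as a percentage.
#' @export
conversion_rate <- function(lambda_records) {
  lambda_records <- data.table::as.data.table(lambda_records)
  validate_calls(lambda_records, "lambda table")
  tot <- sum(as.numeric(lambda_records$total))
  if (tot == 0) stop_input("lambda spike-in has zero coverage")
  100 * (1 - sum(as.numeric(lambda_records$meth)) / tot)
}

#' Alignment rate summary
#'
#' Mapping and unique-mapping percentages from read counts, rounded to two
#' decimals as conventionally tabulated.
#'
#' @param clean_reads,mapped_reads,uniquely_mapped_reads Read counts
#'   (vectors are summarised row-wise).
#' @param sample_id Optional labels.
#' @return A data.frame of class `alignment_summary` with the counts and
#'   `mapping_rate` / `unique_rate` percentages.
#' @examples
#' alignment_rates(350174586, 325098027, 309905822)  # 92.84 / 88.50
#' @export
alignment_rates <- function(clean_reads, mapped_reads, uniquely_mapped_reads,
                            sample_id = NULL) {
  if (any(uniquely_mapped_reads > mapped_reads) || any(mapped_reads > clean_reads)) {
    stop_input("count ordering violated: need unique <= mapped <= clean")
  }
  if (any(clean_reads <= 0)) stop_input("clean_reads must be positive")
  out <- data.frame(
    sample_id = sample_id %||% paste0("S", seq_along(clean_reads)),
    clean_reads = clean_reads,
    mapped_reads = mapped_reads,
    uniquely_mapped_reads = uniquely_mapped_reads,
    mapping_rate = round(100 * mapped_reads / clean_reads, 2),
    unique_rate = round(100 * uniquely_mapped_reads / clean_reads, 2)
  )
  class(out) <- c("alignment_summary", "data.frame")
  out
}
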