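# Readers and writers for on-disk formats. A single internal coordinate
# convention is used everywhere: 0-based half-open intervals and 0-based
# site positions; conversion to/from 1-based external dialects happens only
# here, at the I/O boundary.

#' Read a per-cytosine methylation call table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`cgmap`}{8 tab-separated columns as emitted by BSMAP-style
#'     methylation callers: chrom, nucleotide (C on + / G on -), 1-based
#'     position, context (CG/CHG/CHH), dinucleotide, methylation level,
#'     methylated reads, total reads.}
#'   \item{`bedgraph_pair`}{7 tab-separated columns: chrom, 0-based start,
#'     end, strand, context, methylation fraction, coverage. The methylated
#'     read count is reconstructed as `round(fraction * coverage)`,
#'     half away from zero.}
#' }
#'
#' @param path Path to a (possibly headerless) TSV file.
#' @param dialect `"cgmap"` or `"bedgraph_pair"`.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   validate positions.
#' @return A `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `meth`, `total`, sorted by (chrom, pos).
#' @export
read_cytosine_table <- function(path, dialect = c("cgmap", "bedgraph_pair"),
                                chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), strand = character(),
    context = character(), meth = integer(), total = integer())
  if (file.size(path) == 0L) return(empty)
  raw <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = "character", na.strings = NULL),
    error = function(e) stop_input("cannot parse %s: %s", path, conditionMessage(e)))
  if (nrow(raw) == 0L) return(empty)
  ncol_need <- if (dialect == "cgmap") 8L else 7L
  bad <- which(apply(raw[, seq_len(min(ncol(raw), ncol_need)), with = FALSE],
                     1L, function(r) any(is.na(r) | r == "")))
  if (ncol(raw) < ncol_need || length(bad)) {
    line <- if (length(bad)) bad[1L] else 1L
    stop_input("malformed %s line %d in %s: expected %d fields",
               dialect, line, path, ncol_need)
  }
  num_or_die <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop_input("malformed %s line %d in %s: non-numeric %s",
                             dialect, which(is.na(v))[1L], path, col)
    v
  }
  if (dialect == "cgmap") {
    nuc <- raw[[2L]]
    if (!all(nuc %in% c("C", "G"))) {
      stop_input("malformed cgmap line %d in %s: nucleotide must be C or G",
                 which(!nuc %in% c("C", "G"))[1L], path)
    }
    dt <- data.table::data.table(
      chrom = raw[[1L]],
      pos = as.integer(num_or_die(raw[[3L]], "position")) - 1L,
      strand = ifelse(nuc == "C", "+", "-"),
      context = raw[[4L]],
      meth = as.integer(num_or_die(raw[[7L]], "meth count")),
      total = as.integer(num_or_die(raw[[8L]], "total count")))
  } else {
    frac <- num_or_die(raw[[6L]], "fraction")
    covr <- num_or_die(raw[[7L]], "coverage")
    if (any(frac < 0 | frac > 1)) {
      stop_input("malformed bedgraph_pair line %d in %s: fraction outside [0,1]",
                 which(frac < 0 | frac > 1)[1L], path)
    }
    dt <- data.table::data.table(
      chrom = raw[[1L]],
      pos = as.integer(num_or_die(raw[[2L]], "start")),
      strand = raw[[4L]],
      context = raw[[5L]],
      meth = as.integer(round_half_up(frac * covr)),
      total = as.integer(covr))
  }
  dt[context == "NA" | context == ".", context := NA_character_]
  if (any(dt$pos < 0L)) {
    stop_input("malformed %s line %d in %s: non-positive position",
               dialect, which(dt$pos < 0L)[1L], path)
  }
  validate_calls(dt, sprintf("%s (%s)", path, dialect))
  if (!is.null(chrom_sizes)) {
    for (cx in unique(dt$chrom)) {
      if (!cx %in% names(chrom_sizes)) stop_input("unknown chromosome %s in %s", cx, path)
      if (any(dt[chrom == cx, pos] >= chrom_sizes[[cx]])) {
        stop_input("position beyond end of %s in %s", cx, path)
      }
    }
  }
  data.table::setorder(dt, chrom, pos, strand)
  dt[]
}

#' Write a cytosine call table in the cgmap dialect
#'
#' Inverse of [read_cytosine_table()] for `dialect = "cgmap"`:
#' positions are emitted 1-based.
#'
#' @param records Internal call table.
#' @param path Output path.
#' @export
write_cytosine_table <- function(records, path) {
  records <- data.table::as.data.table(records)
  validate_calls(records)
  out <- data.table::data.table(
    chrom = records$chrom,
    nuc = ifelse(records$strand == "+", "C", "G"),
    pos = records$pos + 1L,
    context = ifelse(is.na(records$context), "NA", records$context),
    dinuc = ifelse(is.na(records$context), "NA", substr(records$context, 1L, 2L)),
    level = ifelse(records$total > 0, sprintf("%.6g", records$meth / records$total), "0"),
    meth = records$meth,
    total = records$total)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene annotation

#' Construct an annotation set
#'
#' @param genes Exon table: `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param cpg_islands Optional interval table (`chrom`, `start`, `end`).
#' @param repeats Optional interval table.
#' @return List of class `annotation_set`.
#' @export
annotation_set <- function(genes, chrom_sizes, cpg_islands = NULL, repeats = NULL) {
  genes <- data.table::as.data.table(genes)
  assert_cols(genes, c("gene_id", "chrom", "strand", "start", "end"), "gene table")
  if (!"transcript_id" %in% names(genes)) genes[, transcript_id := gene_id]
  if (nrow(genes)) {
    if (any(genes$start < 0L) || any(genes$end > chrom_sizes[genes$chrom])) {
      stop_input("gene intervals outside chromosome bounds")
    }
  }
  data.table::setorder(genes, chrom, start)
  norm_iv <- function(x) {
    if (is.null(x)) return(NULL)
    x <- data.table::as.data.table(x)
    assert_cols(x, c("chrom", "start", "end"), "interval table")
    data.table::setorder(x, chrom, start)
    x[]
  }
  structure(list(genes = genes[], chrom_sizes = chrom_sizes,
                 cpg_islands = norm_iv(cpg_islands), repeats = norm_iv(repeats)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(unique(x$genes$gene_id)), "genes on",
      length(x$chrom_sizes), "chromosome(s);",
      if (is.null(x$cpg_islands)) "no" else nrow(x$cpg_islands),
      "CpG islands\n")
  invisible(x)
}

#' Read a gene annotation (GTF or BED12)
#'
#' One representative transcript is kept per gene: the transcript with the
#' longest total exonic span, ties broken by lexicographically smallest
#' transcript id. GTF 1-based closed coordinates are converted to the
#' internal 0-based half-open convention. Exonless transcripts are skipped
#' with a warning.
#'
#' @param path GTF/GFF or BED12 file.
#' @param format `"gtf"` or `"bed12"`.
#' @param chrom_sizes Named vector of chromosome lengths. Required;
#'   annotations on unknown chromosomes are an error.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, format = c("gtf", "bed12"), chrom_sizes) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) stop_input("no exon features in %s", path)
    exons <- data.table::data.table(
      gene_id = ex$gene_id,
      transcript_id = ex$transcript_id %||% ex$gene_id,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      start = GenomicRanges::start(ex) - 1L,
      end = GenomicRanges::end(ex))
    # transcripts declared but exonless
    tx_all <- unique(gr$transcript_id[gr$type %in% c("transcript", "mRNA")])
    dropped <- setdiff(tx_all[!is.na(tx_all)], unique(exons$transcript_id))
    if (length(dropped)) {
      warning(sprintf("skipping %d exonless transcript(s): %s",
                      length(dropped), paste(head(dropped, 3L), collapse = ", ")))
    }
  } else {
    raw <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(raw) < 12L) stop_input("%s is not BED12 (found %d columns)", path, ncol(raw))
    exons <- raw[, {
      sizes <- as.integer(strsplit(sub(",$", "", V11), ",")[[1L]])
      offs <- as.integer(strsplit(sub(",$", "", V12), ",")[[1L]])
      if (length(sizes) != V10) stop_input("BED12 block count mismatch for %s", V4)
      list(gene_id = V4, transcript_id = V4, chrom = V1, strand = V6,
           start = V2 + offs, end = V2 + offs + sizes)
    }, by = seq_len(nrow(raw))][, seq_len := NULL][]
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop_input("unstranded transcript(s) in %s", path)
  }
  unknown <- setdiff(unique(exons$chrom), names(chrom_sizes))
  if (length(unknown)) stop_input("unknown chromosome %s in %s", unknown[1L], path)
  # representative transcript per gene: longest exonic span, ties -> smallest id
  span <- exons[, .(tx_len = sum(end - start)), by = .(gene_id, transcript_id)]
  data.table::setorder(span, gene_id, -tx_len, transcript_id)
  keep <- span[, .SD[1L], by = gene_id]
  exons <- exons[keep, on = c("gene_id", "transcript_id")]
  data.table::setorder(exons, chrom, start)
  annotation_set(exons, chrom_sizes)
}

#' Decompose genes into metagene features
#'
#' Each representative transcript is decomposed, in transcription order,
#' into the seven canonical features: `upstream`, `first_exon`,
#' `first_intron`, `internal_exons`, `internal_introns`, `last_exon`,
#' `downstream`, plus a `promoter` (the `upstream_bp` immediately 5' of the
#' TSS). Single-exon genes have only `first_exon` (plus flanks); two-exon
#' genes lack internal features. Flanks are clipped at chromosome bounds.
#'
#' @param annotation An [annotation_set()].
#' @param upstream_bp,downstream_bp Flank widths (default 2000 bp each).
#' @return `data.table`: `gene_id`, `chrom`, `strand`, `feature`, `start`,
#'   `end` (0-based half-open), `piece_rank` (transcription order of pieces
#'   within a feature).
#' @export
gene_features <- function(annotation, upstream_bp = 2000L, downstream_bp = 2000L) {
  stopifnot(inherits(annotation, "annotation_set"))
  exons <- data.table::copy(annotation$genes)
  sizes <- annotation$chrom_sizes
  res <- exons[, {
    es <- start; ee <- end
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    ne <- length(es)
    fwd <- strand[1L] == "+"
    # transcription-ordered exon indices
    idx <- if (fwd) seq_len(ne) else rev(seq_len(ne))
    tss <- if (fwd) es[1L] else ee[ne]
    tes <- if (fwd) ee[ne] else es[1L]
    clen <- sizes[[chrom[1L]]]
    feats <- list()
    add <- function(feats, name, s, e, rank = seq_along(s)) {
      keep <- e > s
      if (any(keep)) feats[[name]] <- list(feature = name, start = s[keep],
                                           end = e[keep],
                                           piece_rank = rank[keep])
      feats
    }
    if (fwd) {
      feats <- add(feats, "upstream", max(0L, tss - upstream_bp), tss)
      feats <- add(feats, "downstream", tes, min(clen, tes + downstream_bp))
      feats <- add(feats, "promoter", max(0L, tss - upstream_bp), tss)
    } else {
      feats <- add(feats, "upstream", tss, min(clen, tss + upstream_bp))
      feats <- add(feats, "downstream", max(0L, tes - downstream_bp), tes)
      feats <- add(feats, "promoter", tss, min(clen, tss + upstream_bp))
    }
    fe <- idx[1L]
    feats <- add(feats, "first_exon", es[fe], ee[fe])
    if (ne >= 2L) {
      le <- idx[ne]
      feats <- add(feats, "last_exon", es[le], ee[le])
      # introns in genomic order, then ranked in transcription order
      is_ <- ee[-ne]; ie_ <- es[-1L]
      ni <- ne - 1L
      irank <- if (fwd) seq_len(ni) else rev(seq_len(ni))
      fi <- which(irank == 1L)
      feats <- add(feats, "first_intron", is_[fi], ie_[fi])
      if (ni >= 2L) {
        keep <- which(irank != 1L)
        feats <- add(feats, "internal_introns", is_[keep], ie_[keep], irank[keep] - 1L)
      }
      if (ne >= 3L) {
        keep <- setdiff(seq_len(ne), c(fe, le))
        erank <- idx # transcription rank of genomic exon i is match(i, idx)
        feats <- add(feats, "internal_exons", es[keep], ee[keep],
                     match(keep, idx) - 1L)
      }
    }
    data.table::rbindlist(lapply(feats, data.table::as.data.table))
  }, by = .(gene_id, chrom, strand)]
  data.table::setorder(res, chrom, start)
  res[]
}

# ---------------------------------------------------------------------------
# DMR tables

#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name, -log10(p) score, strand ("."), then
#' fold change, group levels, CpG count, direction and context. 0-based
#' half-open, with a commented header line. [read_dmr_bed()] round-trips
#' the file.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dmrs <- data.table::as.data.table(dmrs)
  header <- paste("#chrom", "start", "end", "name", "neg_log10_p", "strand",
                  "fold", "level_a", "level_b", "n_cpg", "direction", "context",
                  sep = "\t")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_input("cannot write %s: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dmrs)) {
    out <- data.table::data.table(
      chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
      name = sprintf("DMR_%05d", seq_len(nrow(dmrs))),
      score = sprintf("%.6g", -log10(pmax(dmrs$p_value, 1e-300))),
      strand = ".",
      fold = sprintf("%.6g", dmrs$fold),
      level_a = sprintf("%.6g", dmrs$level_a),
      level_b = sprintf("%.6g", dmrs$level_b),
      n_cpg = dmrs$n_cpg, direction = dmrs$direction, context = dmrs$context)
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a DMR BED6+ file written by [write_dmr_bed()]
#' @param path BED file path.
#' @return `data.table` of DMRs.
#' @export
read_dmr_bed <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  cols <- c("chrom", "start", "end", "name", "neg_log10_p", "strand", "fold",
            "level_a", "level_b", "n_cpg", "direction", "context")
  if (!length(lines)) {
    out <- data.table::as.data.table(
      stats::setNames(rep(list(character()), length(cols)), cols))
    return(out)
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          col.names = cols)
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            p_value = 10^(-as.numeric(neg_log10_p)),
            fold = as.numeric(fold), level_a = as.numeric(level_a),
            level_b = as.numeric(level_b), n_cpg = as.integer(n_cpg))]
  dt[]
}

#' Write summary tables as TSV and JSON
#'
#' @param summary A named list (or data.frame) of results.
#' @param path Output path without extension; `<path>.tsv` is written for
#'   tabular input and `<path>.json` always.
#' @export
write_report_tables <- function(summary, path) {
  if (is.data.frame(summary)) {
    data.table::fwrite(summary, paste0(path, ".tsv"), sep = "\t")
    jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop_input("malformed GMT line: %s", substr(l, 1, 40))
    unique(f[-c(1L, 2L)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
  sets
}
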