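# Methylation-expression integration: DEG filtering, DMG/DEG overlap,
# concordance classification, candidate-gene selection, hypergeometric
# gene-set enrichment, STRING-style PPI edge filtering, and the
# muscle-fiber diameter helper.

#' Filter differentially expressed genes
#'
#' Keeps genes with `|log2_fc| > min_abs_log2fc` (strict) and
#' `fdr <= max_fdr` (inclusive) — the conventional strict-fold /
#' inclusive-FDR reading of the thresholds.
#'
#' @param expression_table `data.frame` with `gene_id`, `log2_fc`, `fdr`.
#' @param min_abs_log2fc Fold-change threshold (default 1).
#' @param max_fdr FDR threshold (default 0.001).
#' @return Character vector of DEG ids.
#' @export
filter_degs <- function(expression_table, min_abs_log2fc = 1.0, max_fdr = 0.001) {
  dt <- data.table::as.data.table(expression_table)
  assert_cols(dt, c("gene_id", "log2_fc", "fdr"), "expression table")
  if (any(dt$fdr < 0 | dt$fdr > 1, na.rm = TRUE)) stop_input("fdr outside [0, 1]")
  if (anyDuplicated(dt$gene_id)) stop_input("duplicate gene_id in expression table")
  dt[abs(log2_fc) > min_abs_log2fc & fdr <= max_fdr, gene_id]
}

#' Set algebra of DMGs and DEGs (Venn counts)
#'
#' @param dmgs,degs Character vectors of gene ids.
#' @return List: `intersection`, `dmg_only`, `deg_only`, and `counts`
#'   (named integer vector `both` / `dmg_only` / `deg_only`).
#' @export
overlap_sets <- function(dmgs, degs) {
  dmgs <- unique(as.character(dmgs)); degs <- unique(as.character(degs))
  both <- sort(intersect(dmgs, degs))
  list(intersection = both,
       dmg_only = sort(setdiff(dmgs, degs)),
       deg_only = sort(setdiff(degs, dmgs)),
       counts = c(both = length(both),
                  dmg_only = length(setdiff(dmgs, degs)),
                  deg_only = length(setdiff(degs, dmgs))))
}

#' Methylation-expression concordance of a promoter DMG
#'
#' Promoter hypermethylation is expected to repress expression: a gene
#' whose promoter is hypomethylated in group 1 and up-regulated (positive
#' log2 fold-change, group 1 vs group 2), or hypermethylated and
#' down-regulated, is `canonical`; any other combination (including a zero
#' fold-change) is `non_canonical`. Vectorised.
#'
#' @param promoter_dmr_direction `"hyper_in_g1"` / `"hypo_in_g1"` (the
#'   `hyper_in_a` / `hypo_in_a` labels of [call_dmrs()] are accepted).
#' @param log2_fc Expression log2 fold-change, group 1 vs group 2.
#' @return Character vector: `"canonical"` or `"non_canonical"`.
#' @export
concordance <- function(promoter_dmr_direction, log2_fc) {
  dir <- sub("_in_(a|g1)$", "", promoter_dmr_direction)
  if (!all(dir %in% c("hyper", "hypo"))) {
    stop_input("direction must be hyper_in_g1/hypo_in_g1 (or *_in_a)")
  }
  if (length(dir) != length(log2_fc)) {
    n <- max(length(dir), length(log2_fc))
    dir <- rep_len(dir, n); log2_fc <- rep_len(log2_fc, n)
  }
  ifelse((dir == "hypo" & log2_fc > 0) | (dir == "hyper" & log2_fc < 0),
         "canonical", "non_canonical")
}

#' Select candidate genes by the four-criteria rule
#'
#' A candidate must (1) lie in the DMG-DEG overlap, (2) belong to at least
#' one supplied pathway set, and (3/4) appear in the user-supplied curated
#' literature list. All flags are recorded per gene so partial matches can
#' be inspected.
#'
#' @param overlap_genes Character vector (criterion 1 universe).
#' @param pathway_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param curated_list Character vector of curated gene ids.
#' @return `data.table`: `gene_id`, `in_overlap`, `in_pathway`,
#'   `in_curated`, `pathways` (comma-collapsed), `selected`.
#' @export
select_candidates <- function(overlap_genes, pathway_sets, curated_list) {
  overlap_genes <- unique(as.character(overlap_genes))
  if (!length(curated_list)) {
    warning("empty curated list: criteria 3/4 are unsatisfiable")
  }
  member_of <- function(g) {
    nm <- names(pathway_sets)[vapply(pathway_sets, function(s) g %in% s, logical(1))]
    paste(nm, collapse = ",")
  }
  dt <- data.table::data.table(gene_id = overlap_genes)
  dt[, in_overlap := TRUE]
  dt[, pathways := vapply(gene_id, member_of, character(1))]
  dt[, in_pathway := nzchar(pathways)]
  dt[, in_curated := gene_id %in% curated_list]
  dt[, selected := in_overlap & in_pathway & in_curated]
  data.table::setorder(dt, -selected, gene_id)
  dt[]
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric p per set (probability of observing
#' at least the seen overlap between the query and the set within the
#' universe), Benjamini-Hochberg corrected across the tested sets
#' (Bonferroni by option). Sets are intersected with the universe first.
#'
#' @param query_genes Character vector; must be a subset of `universe`.
#' @param universe Character vector of all considered genes.
#' @param gene_sets Named list of character vectors.
#' @param q_max Significance threshold on the corrected p (default 0.05).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return `data.table` sorted by `q_value`: `set_name`, `k` (overlap),
#'   `K` (set size in universe), `n` (query size), `N` (universe size),
#'   `p_value`, `q_value`, `significant`.
#' @export
enrich <- function(query_genes, universe, gene_sets, q_max = 0.05,
                   method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_input("empty universe")
  query_genes <- unique(as.character(query_genes))
  if (!all(query_genes %in% universe)) {
    stop_input("query genes must be a subset of the universe")
  }
  N <- length(universe); n <- length(query_genes)
  res <- data.table::rbindlist(lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query_genes, set))
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.table::data.table(set_name = nm, k = k, K = K, n = n, N = N,
                           p_value = p)
  }))
  if (!nrow(res)) return(res)
  res[, q_value := p.adjust(p_value, method = method)]
  res[, significant := q_value <= q_max]
  data.table::setorder(res, q_value, set_name)
  res[]
}

#' Filter a PPI edge table at a confidence cutoff
#'
#' STRING-style combined scores are rescaled from the 0-1000 integer range
#' into \[0, 1\] when any score exceeds 1; edges with rescaled score >=
#' `min_score` (default 0.400, medium confidence) are kept. Self-loops are
#' dropped (count reported). Connected components and node degrees are
#' computed on the filtered network.
#'
#' @param edge_table `data.frame` with columns `from`, `to`, `score`.
#' @param min_score Confidence cutoff (default 0.400).
#' @return List of class `ppi_network`: `edges`, `nodes` (`node`, `degree`,
#'   `component`), `n_components`, `n_self_loops_dropped`.
#' @export
filter_ppi_edges <- function(edge_table, min_score = 0.400) {
  dt <- data.table::as.data.table(edge_table)
  assert_cols(dt, c("from", "to", "score"), "PPI edge table")
  if (!is.numeric(dt$score)) stop_input("PPI scores must be numeric")
  if (any(dt$score > 1)) dt[, score := score / 1000]
  if (any(dt$score < 0 | dt$score > 1)) stop_input("PPI scores outside [0, 1000]")
  n_self <- sum(dt$from == dt$to)
  if (n_self) message(sprintf("dropped %d self-loop(s)", n_self))
  dt <- dt[from != to & score >= min_score]
  if (nrow(dt)) {
    g <- igraph::graph_from_data_frame(dt[, .(from, to)], directed = FALSE)
    comp <- igraph::components(g)
    nodes <- data.table::data.table(
      node = igraph::V(g)$name,
      degree = as.integer(igraph::degree(g)),
      component = as.integer(comp$membership))
    n_comp <- comp$no
  } else {
    nodes <- data.table::data.table(node = character(), degree = integer(),
                                    component = integer())
    n_comp <- 0L
  }
  structure(list(edges = dt[], nodes = nodes, n_components = n_comp,
                 n_self_loops_dropped = n_self),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", nrow(x$edges), "edges,", nrow(x$nodes), "nodes,",
      x$n_components, "component(s)\n")
  invisible(x)
}

#' Muscle fiber diameter from cross-sectional area
#'
#' Fibers are modelled as cylinders, so the cross-section is a circle of
#' area \eqn{s = \pi r^2} and the diameter is \eqn{d = 2\sqrt{s/\pi}}.
#'
#' @param area Cross-sectional area in square micrometres (> 0).
#' @return Diameter in micrometres.
#' @examples
#' fiber_diameter_from_area(pi)  # 2
#' @export
fiber_diameter_from_area <- function(area) {
  if (any(area <= 0)) stop_input("fiber area must be positive")
  2 * sqrt(area / pi)
}
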