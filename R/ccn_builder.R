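#' Intersect a cell's differential network with the ceRNA reference
#'
#' Keeps exactly the RCN edges whose canonical gene pair is present in the
#' ceRNA reference; all edge statistics are preserved and the network stage
#' becomes `"CCN"`. When the reference carries shared-miRNA evidence, a
#' `shared_mirnas` column is attached. An empty CCN is valid.
#'
#' @param rcn A `CellNetwork` with `stage = "RCN"`.
#' @param ref A `CeRNAReference`.
#' @return A `CellNetwork` with `stage = "CCN"`.
#' @export
intersect_cerna <- function(rcn, ref) {
  stopifnot(inherits(rcn, "CellNetwork"), inherits(ref, "CeRNAReference"))
  if (rcn$stage != "RCN")
    ccn_abort("invalid_stage", "intersect_cerna expects an RCN, got %s", rcn$stage)
  key <- paste(rcn$edges$gene_a, rcn$edges$gene_b, sep = "\x1f")
  refkey <- cerna_keys(ref)
  keep <- key %in% refkey
  edges <- rcn$edges[keep, , drop = FALSE]
  if ("shared_mirnas" %in% names(ref))
    edges$shared_mirnas <- ref$shared_mirnas[match(key[keep], refkey)]
  rownames(edges) <- NULL
  out <- new_cell_network(rcn$cell_id, "CCN", edges, rcn$alpha_edge,
                          rcn$alpha_diff, rcn$direction_rule,
                          rcn$edge_universe, rcn$n_degenerate,
                          log = c(rcn$log, list(n_ccn = sum(keep))))
  out
}

#' Build a cell-specific ceRNA network for every query cell
#'
#' Builds the reference panel once, then for each non-reference cell builds
#' the differential co-expression network ([build_cell_rcn()]) and
#' intersects it with the ceRNA reference ([intersect_cerna()]).
#'
#' @param x An `ExpressionMatrix` with designated reference cells.
#' @param ref A `CeRNAReference`.
#' @param alpha_edge,alpha_diff,direction_rule,edge_universe,sided
#'   Passed to [build_cell_rcn()].
#' @param alpha_ref Significance level for reference-network edges.
#' @param keep_rcn If TRUE, each element's `"rcn"` attribute holds the
#'   pre-intersection network.
#' @return Named list (one `CellNetwork` per query cell, in metadata
#'   order) with attribute `"log"`: a data frame of per-cell candidate /
#'   retained / CCN edge counts.
#' @export
build_all_ccns <- function(x, ref, alpha_edge = 0.05, alpha_diff = 0.05,
                           direction_rule = "delta_positive",
                           edge_universe = "perturbed", sided = "two",
                           alpha_ref = 0.05, keep_rcn = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  panel <- build_reference_panel(x, alpha = alpha_ref)
  query <- x$cell_meta$cell_id[!x$cell_meta$is_reference]
  if (!length(query))
    ccn_abort("too_few_cells", "no non-reference (query) cells present")
  ccns <- vector("list", length(query))
  names(ccns) <- query
  log <- data.frame(cell_id = query, n_candidates = 0L, n_rcn = 0L,
                    n_ccn = 0L, n_degenerate = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(query)) {
    rcn <- build_cell_rcn(panel, x, query[i], alpha_edge = alpha_edge,
                          alpha_diff = alpha_diff,
                          direction_rule = direction_rule,
                          edge_universe = edge_universe, sided = sided)
    ccn <- intersect_cerna(rcn, ref)
    if (keep_rcn) attr(ccn, "rcn") <- rcn
    ccns[[i]] <- ccn
    log$n_candidates[i] <- rcn$log$n_candidates
    log$n_rcn[i] <- nrow(rcn$edges)
    log$n_ccn[i] <- nrow(ccn$edges)
    log$n_degenerate[i] <- rcn$n_degenerate
  }
  attr(ccns, "log") <- log
  ccns
}

network_genes <- function(net) {
  unique(c(net$edges$gene_a, net$edges$gene_b))
}

#' Per-group summary of cell-specific ceRNA networks
#'
#' For each group: the mean edge count and the mean number of distinct
#' lncRNA nodes per cell (a node counts as lncRNA when the annotation says
#' so; unannotated genes count as non-lncRNA). Groups with no cells among
#' `ccns` are excluded with a warning.
#'
#' @param ccns Named list of `CellNetwork`s (names = cell ids).
#' @param ann A `GeneAnnotation` (or NULL: no lncRNAs).
#' @param groups Named character vector mapping cell id -> group label.
#' @return List with `summary` (data frame: group, mean_edges,
#'   mean_lncrnas) and `per_cell` (data frame: cell_id, group, n_edges,
#'   n_lncrnas). Group order follows first appearance in `groups`.
#' @export
summarize_ccns <- function(ccns, ann, groups) {
  cells <- names(ccns)
  if (any(!cells %in% names(groups)))
    ccn_abort("metadata_mismatch", "every cell needs a group label")
  per_cell <- data.frame(
    cell_id = cells,
    group = unname(groups[cells]),
    n_edges = vapply(ccns, function(n) nrow(n$edges), integer(1)),
    n_lncrnas = vapply(ccns, function(n) {
      g <- network_genes(n)
      sum(biotype_of(g, ann) == "lncRNA")
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_cell) <- NULL
  empty <- setdiff(unique(unname(groups)), per_cell$group)
  if (length(empty))
    ccn_warn("empty_group", "group(s) with no cells excluded: %s",
             paste(empty, collapse = ", "))
  grp <- unique(per_cell$group)
  summary <- data.frame(
    group = grp,
    mean_edges = vapply(grp, function(g) mean(per_cell$n_edges[per_cell$group == g]), numeric(1)),
    mean_lncrnas = vapply(grp, function(g) mean(per_cell$n_lncrnas[per_cell$group == g]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(summary = summary, per_cell = per_cell)
}
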