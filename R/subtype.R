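#' Upper-tail hypergeometric probability
#'
#' Probability of observing `n` or more successes when drawing `m` genes
#' from a background of `M` genes of which `N_set` belong to the set:
#' `P = sum_{x >= n} C(N_set, x) C(M - N_set, m - x) / C(M, m)`.
#' The tail includes `x = n`, so `n = 0` gives P = 1.
#'
#' @param M Background size.
#' @param N_set Genes of the set within the background.
#' @param m Genes drawn (e.g. CCN genes within the background).
#' @param n Overlap count.
#' @return Upper-tail probability in \[0, 1\]. Vectorised.
#' @export
hypergeom_tail <- function(M, N_set, m, n) {
  bad <- N_set < 0 | N_set > M | m < 0 | m > M | n < 0 | n > pmin(N_set, m)
  if (any(bad))
    ccn_abort("invalid_parameter",
              "need 0 <= N_set <= M, 0 <= m <= M, 0 <= n <= min(N_set, m)")
  stats::phyper(n - 1, N_set, M - N_set, m, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a cell network's genes
#'
#' The cell's gene set is the union of its edge endpoints, restricted to
#' the background; each gene set is likewise restricted before counting the
#' overlap. Empty networks or disjoint sets give p = 1.
#'
#' @param ccn A `CellNetwork`.
#' @param gs A `GeneSetCollection`.
#' @param background Nonempty character vector of background gene symbols.
#' @return Data frame with columns `set_name`, `M`, `N_set`, `m`, `n`, `p`,
#'   one row per set, in collection order.
#' @export
enrich_cell <- function(ccn, gs, background) {
  background <- unique(as.character(background))
  if (!length(background)) ccn_abort("empty_background", "background is empty")
  nodes <- intersect(network_genes(ccn), background)
  M <- length(background)
  m <- length(nodes)
  res <- lapply(names(gs$sets), function(nm) {
    set_bg <- intersect(gs$sets[[nm]], background)
    n <- length(intersect(nodes, set_bg))
    data.frame(set_name = nm, M = M, N_set = length(set_bg), m = m, n = n,
               p = hypergeom_tail(M, length(set_bg), m, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify cells into response subtypes by hallmark enrichment
#'
#' Each cell's network genes are tested against the early- and
#' late-response gene sets with the upper-tail hypergeometric test. A cell
#' is labelled `early_response` iff `p_early < alpha`; otherwise
#' `late_response` iff `p_late < alpha`; otherwise `other`. Both p-values
#' are always reported.
#'
#' @param ccns Named list of `CellNetwork`s.
#' @param gs_early,gs_late Character vectors of gene symbols (the two
#'   hallmark sets).
#' @param background Background gene symbols.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `cell_id`, `p_early`, `p_late`, `label`,
#'   `alpha` (class `SubtypeCalls`).
#' @export
classify_cells <- function(ccns, gs_early, gs_late, background, alpha = 0.05) {
  gs <- gene_set_collection(list(early = gs_early, late = gs_late))
  rows <- lapply(names(ccns), function(cid) {
    e <- enrich_cell(ccns[[cid]], gs, background)
    p_early <- e$p[e$set_name == "early"]
    p_late <- e$p[e$set_name == "late"]
    label <- if (p_early < alpha) "early_response"
             else if (p_late < alpha) "late_response" else "other"
    data.frame(cell_id = cid, p_early = p_early, p_late = p_late,
               label = label, alpha = alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("SubtypeCalls", "data.frame")
  out
}

#' Subtype-exclusive edge biomarkers
#'
#' For each subtype label, collects edges that appear in at least one cell
#' of that subtype and in no cell of any other subtype, ranks them by
#' (number of carrying cells, then mean |delta|, then lexicographic pair),
#' and keeps the top `top_k` per subtype. The result carries a
#' delta-correlation matrix over all cells, 0 where an edge is absent from
#' a cell's network.
#'
#' @param ccns Named list of `CellNetwork`s.
#' @param calls A `SubtypeCalls` data frame (from [classify_cells()]).
#' @param top_k Edges kept per subtype (default 20).
#' @param per_subtype If FALSE, `top_k` is a total across subtypes (ranked
#'   by the same rule, subtypes interleaved by rank).
#' @return Object of class `EdgeMarkerMatrix`: list with `edges` (data
#'   frame: gene_a, gene_b, subtype, n_cells, mean_abs_delta), `delta`
#'   (edge x cell matrix), `cells`.
#' @export
select_edge_markers <- function(ccns, calls, top_k = 20, per_subtype = TRUE) {
  stopifnot(is.data.frame(calls))
  labels <- unique(calls$label)
  if (length(labels) < 2L)
    ccn_abort("invalid_parameter", "need >= 2 subtype labels among calls")
  cells <- calls$cell_id
  edge_keys <- lapply(ccns[cells], function(n)
    paste(n$edges$gene_a, n$edges$gene_b, sep = "\x1f"))

  # per-edge: which cells carry it
  all_keys <- sort(unique(unlist(edge_keys)))
  carriers <- lapply(stats::setNames(all_keys, all_keys), function(k)
    cells[vapply(edge_keys, function(e) k %in% e, logical(1))])
  label_of <- stats::setNames(calls$label, calls$cell_id)

  rows <- list()
  for (k in all_keys) {
    lab <- unique(unname(label_of[carriers[[k]]]))
    if (length(lab) != 1L) next  # not exclusive to one subtype
    cc <- carriers[[k]]
    deltas <- vapply(cc, function(cid) {
      e <- ccns[[cid]]$edges
      e$delta[paste(e$gene_a, e$gene_b, sep = "\x1f") == k]
    }, numeric(1))
    ab <- strsplit(k, "\x1f", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ab[1], gene_b = ab[2], subtype = lab,
      n_cells = length(cc), mean_abs_delta = mean(abs(deltas)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    ccn_warn("no_exclusive_edges", "no subtype-exclusive edges found")
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        subtype = character(), n_cells = integer(),
                        mean_abs_delta = numeric(), stringsAsFactors = FALSE)
    delta <- matrix(0, 0, length(cells), dimnames = list(NULL, cells))
    return(structure(list(edges = edges, delta = delta, cells = cells),
                     class = "EdgeMarkerMatrix"))
  }
  edges <- do.call(rbind, rows)
  ord <- order(-edges$n_cells, -edges$mean_abs_delta,
               edges$gene_a, edges$gene_b)
  edges <- edges[ord, , drop = FALSE]
  if (per_subtype) {
    keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$subtype),
                          function(i) i[seq_len(min(top_k, length(i)))]))
    edges <- edges[sort(keep), , drop = FALSE]
  } else {
    edges <- edges[seq_len(min(top_k, nrow(edges))), , drop = FALSE]
  }
  rownames(edges) <- NULL

  delta <- matrix(0, nrow(edges), length(cells),
                  dimnames = list(paste(edges$gene_a, edges$gene_b, sep = "|"),
                                  cells))
  for (i in seq_len(nrow(edges))) {
    k <- paste(edges$gene_a[i], edges$gene_b[i], sep = "\x1f")
    for (cid in carriers[[k]]) {
      e <- ccns[[cid]]$edges
      delta[i, cid] <- e$delta[paste(e$gene_a, e$gene_b, sep = "\x1f") == k]
    }
  }
  structure(list(edges = edges, delta = delta, cells = cells),
            class = "EdgeMarkerMatrix")
}

#' @export
print.EdgeMarkerMatrix <- function(x, ...) {
  cat(sprintf("<EdgeMarkerMatrix> %d marker edges x %d cells\n",
              nrow(x$edges), length(x$cells)))
  invisible(x)
}
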