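as_igraph <- function(net) {
  stopifnot(inherits(net, "CellNetwork"))
  if (!nrow(net$edges))
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE)
}

#' Node degree in a cell network
#'
#' Number of distinct neighbors; genes absent from the network have
#' degree 0.
#'
#' @param net A `CellNetwork`.
#' @param genes Optional character vector; default: all network nodes.
#' @return Named integer vector of degrees.
#' @export
network_degree <- function(net, genes = NULL) {
  g <- as_igraph(net)
  d <- if (igraph::vcount(g)) igraph::degree(g) else stats::setNames(integer(0), character(0))
  if (is.null(genes)) return(stats::setNames(as.integer(d), names(d)))
  out <- stats::setNames(rep(0L, length(genes)), genes)
  hit <- genes %in% names(d)
  out[hit] <- as.integer(d[genes[hit]])
  out
}

#' Betweenness centrality in a cell network
#'
#' `B_i = sum_{s != i != t} delta_st(i) / d_st`, where `d_st` counts the
#' shortest s-t paths and `delta_st(i)` those passing through i. Uses the
#' unordered-pair convention (each pair \{s, t\} counted once), the natural
#' choice for these undirected networks; tools using the directed
#' convention report doubled values. Pairs with no connecting path
#' contribute 0.
#'
#' @param net A `CellNetwork`.
#' @return Named numeric vector over network nodes.
#' @export
network_betweenness <- function(net) {
  g <- as_igraph(net)
  if (!igraph::vcount(g)) return(stats::setNames(numeric(0), character(0)))
  b <- igraph::betweenness(g, directed = FALSE)
  stats::setNames(as.numeric(b), names(b))
}

#' Closeness centrality in a cell network
#'
#' `C(i) = (n - 1) / sum_{s != i} d_si` computed within i's connected
#' component, with `n` the component size. Isolated nodes (degree 0 after
#' edge filtering never occur here, but single-component-of-one nodes in
#' subgraphs can) get closeness 0 by convention.
#'
#' @param net A `CellNetwork`.
#' @return Named numeric vector over network nodes.
#' @export
network_closeness <- function(net) {
  g <- as_igraph(net)
  nv <- igraph::vcount(g)
  if (!nv) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(g)
  out <- vapply(seq_len(nv), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) return(0)
    length(di) / sum(di)
  }, numeric(1))
  stats::setNames(out, igraph::V(g)$name)
}

#' Full topology table over a set of cell networks
#'
#' @param ccns Named list of `CellNetwork`s.
#' @return Data frame with columns `cell_id`, `gene`, `degree`,
#'   `betweenness`, `closeness`.
#' @export
topology_table <- function(ccns) {
  rows <- lapply(names(ccns), function(cid) {
    net <- ccns[[cid]]
    deg <- network_degree(net)
    if (!length(deg))
      return(data.frame(cell_id = character(), gene = character(),
                        degree = integer(), betweenness = numeric(),
                        closeness = numeric(), stringsAsFactors = FALSE))
    btw <- network_betweenness(net)
    cls <- network_closeness(net)
    g <- names(deg)
    data.frame(cell_id = cid, gene = g, degree = as.integer(deg[g]),
               betweenness = as.numeric(btw[g]),
               closeness = as.numeric(cls[g]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank hub lncRNAs by average degree within a subtype
#'
#' For each lncRNA (per the annotation), averages its degree across the
#' cells of the requested subtype. With `presence_rule = "present_only"`
#' (default) the average is over cells where the gene has degree >= 1;
#' `"all_cells"` includes zeros for absent cells. Sorted by descending
#' average degree, ties broken lexicographically by symbol.
#'
#' @param ccns Named list of `CellNetwork`s.
#' @param calls A `SubtypeCalls` data frame.
#' @param subtype Label to restrict to (default `"early_response"`).
#' @param ann A `GeneAnnotation` declaring lncRNA biotypes.
#' @param presence_rule `"present_only"` or `"all_cells"`.
#' @return Data frame with columns `gene`, `biotype`, `average_degree`,
#'   `n_cells_present`, plus attribute `"presence_rule"`.
#' @export
rank_hub_lncrnas <- function(ccns, calls, subtype = "early_response", ann,
                             presence_rule = c("present_only", "all_cells")) {
  presence_rule <- match.arg(presence_rule)
  if (is.null(ann)) ccn_abort("invalid_parameter", "lncRNA annotation required")
  cells <- calls$cell_id[calls$label == subtype]
  if (!length(cells))
    ccn_abort("invalid_parameter", "no cell carries subtype label '%s'", subtype)
  cells <- sort(cells)  # invariant to cell-map iteration order
  lnc <- ann$symbol[ann$biotype == "lncRNA"]
  degs <- vapply(cells, function(cid) network_degree(ccns[[cid]], lnc),
                 stats::setNames(numeric(length(lnc)), lnc))
  degs <- matrix(degs, nrow = length(lnc), dimnames = list(lnc, cells))
  present <- degs >= 1
  n_present <- rowSums(present)
  avg <- if (presence_rule == "present_only") {
    ifelse(n_present > 0, rowSums(degs) / pmax(n_present, 1L), NA_real_)
  } else {
    rowMeans(degs)
  }
  keep <- n_present > 0
  out <- data.frame(gene = lnc[keep], biotype = "lncRNA",
                    average_degree = as.numeric(avg[keep]),
                    n_cells_present = as.integer(n_present[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$average_degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "presence_rule") <- presence_rule
  out
}

#' Ego subnetwork of a gene
#'
#' The induced subnetwork on a gene and its direct neighbors, returned
#' only when the gene's degree meets `min_degree` (e.g. the hub-lncRNA
#' displays use degree >= 20); otherwise an empty network. Node marker
#' tags from the annotation are attached as the `"nodes"` attribute for
#' display.
#'
#' @param net A `CellNetwork`.
#' @param gene Center gene symbol.
#' @param min_degree Minimum degree of `gene` for a nonempty result.
#' @param ann Optional `GeneAnnotation` supplying biotypes and marker tags.
#' @return A `CellNetwork` (possibly with zero edges).
#' @export
ego_network <- function(net, gene, min_degree = 0, ann = NULL) {
  deg <- unname(network_degree(net, gene))
  empty <- net$edges[0, , drop = FALSE]
  if (deg < min_degree || deg == 0L) {
    return(new_cell_network(net$cell_id, net$stage, empty, net$alpha_edge,
                            net$alpha_diff, net$direction_rule,
                            net$edge_universe))
  }
  nbrs <- unique(c(net$edges$gene_b[net$edges$gene_a == gene],
                   net$edges$gene_a[net$edges$gene_b == gene]))
  nodeset <- c(gene, nbrs)
  keep <- net$edges$gene_a %in% nodeset & net$edges$gene_b %in% nodeset
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  out <- new_cell_network(net$cell_id, net$stage, edges, net$alpha_edge,
                          net$alpha_diff, net$direction_rule,
                          net$edge_universe)
  if (!is.null(ann)) {
    nd <- data.frame(gene = nodeset,
                     biotype = biotype_of(nodeset, ann),
                     tags = ann$tags[match(nodeset, ann$symbol)],
                     stringsAsFactors = FALSE)
    nd$tags[is.na(nd$tags)] <- ""
    attr(out, "nodes") <- nd
  }
  out
}
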