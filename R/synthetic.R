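#' Define a synthetic study scenario
#'
#' The default scenario mirrors the study design the package targets:
#' 20 reference cells (baseline, "0h") plus 64 query cells split over
#' three stimulation groups ("3h", "6h", "12h"), a modest gene panel,
#' block-correlated baseline expression, per-cell planted differential
#' edges, a synthetic ceRNA reference covering all planted pairs plus
#' random pairs, and an early/late-response gene-set pair with a
#' membership bias for planted-early cells.
#'
#' Latent expression is Gaussian (blocks are exchangeable-correlation on
#' the latent scale) and mapped to FPKM-like values by exponentiation, so
#' values are skewed, nonnegative, and rank-preserving in the latent
#' scale. A planted edge displaces one query cell by `displacement`
#' standard deviations on both genes of a pair, which creates a positive
#' change in correlation when that cell joins the reference panel.
#'
#' @param n_genes Number of genes (default 150).
#' @param n_ref_cells Reference cells (default 20).
#' @param n_query_cells Query cells (default 64).
#' @param groups Group labels cycled over query cells (default
#'   `c("3h", "6h", "12h")`, split as evenly as possible).
#' @param corr_blocks List of `list(genes = indices, rho = value in [0,1))`;
#'   default: three 8-gene blocks at rho 0.6 outside the hallmark sets.
#' @param n_early_cells Query cells planted as early-response (default 41,
#'   the remainder are "other").
#' @param n_planted_edges_per_cell Planted pairs per query cell (default 8).
#' @param displacement Planted displacement in latent SD units (default 6).
#' @param subtype_bias Probability that a planted pair endpoint of an early
#'   cell is drawn from the early gene set (default 0.8).
#' @param early_set_size,late_set_size Sizes of the two hallmark-like sets
#'   (defaults 40 and 30; the sets are disjoint).
#' @param cerna_coverage Fraction of all gene pairs included in the
#'   synthetic ceRNA reference in addition to planted pairs (default 0.05).
#' @param lncrna_fraction Fraction of genes annotated as lncRNA
#'   (default 0.2).
#' @param seed Integer seed; the scenario is fully determined by it.
#' @return Object of class `SyntheticScenario` (a list of the above).
#' @export
synthetic_scenario <- function(n_genes = 150, n_ref_cells = 20,
                               n_query_cells = 64,
                               groups = c("3h", "6h", "12h"),
                               corr_blocks = NULL,
                               n_early_cells = 41,
                               n_planted_edges_per_cell = 8,
                               displacement = 6,
                               subtype_bias = 0.8,
                               early_set_size = 40, late_set_size = 30,
                               cerna_coverage = 0.05,
                               lncrna_fraction = 0.2,
                               seed = 1) {
  if (is.null(corr_blocks)) {
    base <- early_set_size + late_set_size
    corr_blocks <- list()
    if (n_genes >= base + 24) {
      for (b in 0:2)
        corr_blocks[[b + 1]] <- list(genes = base + b * 8 + 1:8, rho = 0.6)
    }
  }
  for (blk in corr_blocks) {
    if (any(blk$genes < 1 | blk$genes > n_genes) || blk$rho < 0 || blk$rho >= 1)
      ccn_abort("invalid_parameter", "invalid correlation block")
  }
  if (subtype_bias < 0 || subtype_bias > 1)
    ccn_abort("invalid_parameter", "subtype_bias must be in [0, 1]")
  if (n_early_cells > n_query_cells)
    ccn_abort("invalid_parameter", "n_early_cells exceeds n_query_cells")
  structure(list(n_genes = n_genes, n_ref_cells = n_ref_cells,
                 n_query_cells = n_query_cells, groups = groups,
                 corr_blocks = corr_blocks, n_early_cells = n_early_cells,
                 n_planted_edges_per_cell = n_planted_edges_per_cell,
                 displacement = displacement, subtype_bias = subtype_bias,
                 early_set_size = early_set_size,
                 late_set_size = late_set_size,
                 cerna_coverage = cerna_coverage,
                 lncrna_fraction = lncrna_fraction, seed = seed),
            class = "SyntheticScenario")
}

.gene_names <- function(s) {
  n_lnc <- round(s$n_genes * s$lncrna_fraction)
  # interleave lncRNAs throughout the panel so hallmark sets contain both
  idx_lnc <- if (n_lnc > 0) round(seq(1, s$n_genes, length.out = n_lnc)) else integer(0)
  nm <- sprintf("MRNA%03d", seq_len(s$n_genes))
  nm[idx_lnc] <- sprintf("LNC%03d", idx_lnc)
  list(names = nm, lnc_idx = idx_lnc)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws reference and query cells from the scenario's block-correlated
#' latent Gaussian, applies the planted per-cell displacements, maps to
#' FPKM-like values, and assembles the ceRNA reference, hallmark-like gene
#' sets, annotations, and ground-truth tables. Fully determined by the
#' scenario seed; the caller's RNG state is untouched.
#'
#' @param s A `SyntheticScenario`.
#' @return List with elements `expr` (`ExpressionMatrix`), `cerna`
#'   (`CeRNAReference`), `gene_sets` (`GeneSetCollection`), `annotation`
#'   (`GeneAnnotation`), `truth` (list: `planted_edges` data frame,
#'   `subtype` data frame, `early_set`, `late_set`), `scenario`.
#' @export
generate_synthetic <- function(s) {
  stopifnot(inherits(s, "SyntheticScenario"))
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(s$seed)

  G <- s$n_genes
  n_cells <- s$n_ref_cells + s$n_query_cells
  gn <- .gene_names(s)
  genes <- gn$names

  # latent Gaussian with exchangeable-correlation blocks
  Z <- matrix(stats::rnorm(G * n_cells), G, n_cells)
  for (blk in s$corr_blocks) {
    shared <- stats::rnorm(n_cells)
    Z[blk$genes, ] <- sqrt(blk$rho) * matrix(shared, length(blk$genes),
                                             n_cells, byrow = TRUE) +
      sqrt(1 - blk$rho) * Z[blk$genes, , drop = FALSE]
  }

  cell_names <- c(sprintf("REF%02d", seq_len(s$n_ref_cells)),
                  sprintf("CELL%03d", seq_len(s$n_query_cells)))
  grp <- c(rep("0h", s$n_ref_cells),
           rep_len(s$groups, s$n_query_cells))

  # gene sets (disjoint): early then late block of the panel
  early_set <- genes[seq_len(s$early_set_size)]
  late_set <- genes[s$early_set_size + seq_len(s$late_set_size)]

  # planted subtype labels and planted edges
  query_names <- cell_names[-seq_len(s$n_ref_cells)]
  early_cells <- sort(sample(query_names, s$n_early_cells))
  truth_subtype <- data.frame(cell_id = query_names,
                              truth = ifelse(query_names %in% early_cells,
                                             "early", "other"),
                              stringsAsFactors = FALSE)
  early_idx <- seq_len(s$early_set_size)
  planted <- list()
  for (ci in seq_along(query_names)) {
    cid <- query_names[ci]
    is_early <- cid %in% early_cells
    for (e in seq_len(s$n_planted_edges_per_cell)) {
      pick <- function() {
        if (is_early && stats::runif(1) < s$subtype_bias)
          sample(early_idx, 1)
        else sample.int(G, 1)
      }
      a <- pick(); b <- pick()
      while (b == a) b <- pick()
      col <- s$n_ref_cells + ci
      Z[a, col] <- Z[a, col] + s$displacement
      Z[b, col] <- Z[b, col] + s$displacement
      planted[[length(planted) + 1L]] <- data.frame(
        cell_id = cid, gene_a = min(genes[a], genes[b]),
        gene_b = max(genes[a], genes[b]),
        displacement = s$displacement, stringsAsFactors = FALSE)
    }
  }
  planted_edges <- unique(do.call(rbind, planted))
  rownames(planted_edges) <- NULL

  # FPKM-like mapping: lognormal, median exp(1.2) ~ 3.3
  V <- exp(0.6 * Z + 1.2)
  dimnames(V) <- list(genes, cell_names)
  meta <- data.frame(cell_id = cell_names, group = grp,
                     is_reference = seq_len(n_cells) <= s$n_ref_cells,
                     stringsAsFactors = FALSE)
  expr <- expression_matrix(V, meta)

  # ceRNA reference: all planted pairs + random pairs to coverage
  n_random <- round(s$cerna_coverage * choose(G, 2))
  ia <- sample.int(G, n_random, replace = TRUE)
  ib <- sample.int(G, n_random, replace = TRUE)
  ok <- ia != ib
  ref_a <- c(planted_edges$gene_a, genes[ia[ok]])
  ref_b <- c(planted_edges$gene_b, genes[ib[ok]])
  mir <- sprintf("miR-%03d", sample.int(300, length(ref_a), replace = TRUE))
  cerna <- cerna_reference(ref_a, ref_b, shared_mirnas = mir)
  planted_edges$in_cerna <- cerna_contains(cerna, planted_edges$gene_a,
                                           planted_edges$gene_b)

  # gene-set collection: hallmark-like pair plus random sets for enrichment
  extra <- lapply(1:3, function(i) sort(sample(genes, 25)))
  names(extra) <- sprintf("RANDOM_SET_%d", 1:3)
  gs <- gene_set_collection(c(list(EARLY_RESPONSE = early_set,
                                   LATE_RESPONSE = late_set), extra),
                            source = "synthetic")

  # annotation: biotypes, a few aliases, random marker tags
  biotype <- ifelse(seq_len(G) %in% gn$lnc_idx, "lncRNA", "mRNA")
  aliases <- rep("", G)
  aliases[1:3] <- paste0(genes[1:3], "-ALT")
  tags <- rep("", G)
  tagged <- sample.int(G, round(G * 0.2))
  tags[tagged] <- sample(.marker_tags, length(tagged), replace = TRUE)
  ann <- gene_annotation(genes, biotype, aliases, tags)

  list(expr = expr, cerna = cerna, gene_sets = gs, annotation = ann,
       truth = list(planted_edges = planted_edges, subtype = truth_subtype,
                    early_set = early_set, late_set = late_set),
       scenario = s)
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Writes `expr.tsv`, `meta.tsv`, `cerna.tsv`, `sets.gmt`,
#' `annotation.tsv`, `truth_edges.tsv`, `truth_subtype.tsv` in exactly the
#' formats the readers of this package consume, so a write/read cycle
#' round-trips.
#'
#' @param sim Output of [generate_synthetic()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(outdir, "expr.tsv"),
             meta = file.path(outdir, "meta.tsv"),
             cerna = file.path(outdir, "cerna.tsv"),
             sets = file.path(outdir, "sets.gmt"),
             annotation = file.path(outdir, "annotation.tsv"),
             truth_edges = file.path(outdir, "truth_edges.tsv"),
             truth_subtype = file.path(outdir, "truth_subtype.tsv"))
  write_expression(sim$expr, paths["expr"], paths["meta"])
  utils::write.table(as.data.frame(sim$cerna), paths["cerna"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_sets(sim$gene_sets, paths["sets"])
  utils::write.table(as.data.frame(sim$annotation), paths["annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$planted_edges, paths["truth_edges"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$subtype, paths["truth_subtype"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
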