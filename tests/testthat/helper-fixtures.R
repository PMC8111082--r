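# Small in-code fixtures shared across test files.

# ExpressionMatrix from a plain matrix; reference cells are the first
# `n_ref` columns, remaining cells get groups cycled from `groups`.
tiny_expr <- function(values, n_ref, groups = "q") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("C%03d", seq_len(ncol(values)))
  n <- ncol(values)
  meta <- data.frame(cell_id = colnames(values),
                     group = c(rep("ref", n_ref),
                               rep_len(groups, n - n_ref)),
                     is_reference = seq_len(n) <= n_ref)
  expression_matrix(values, meta)
}

# CellNetwork straight from edge vectors (bypasses the statistics).
make_network <- function(gene_a, gene_b, delta = NULL, cell_id = "cell1",
                         stage = "CCN") {
  if (is.null(delta)) delta <- rep(0.5, length(gene_a))
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  ord <- order(a, b)
  n <- length(ord)
  edges <- data.frame(gene_a = a[ord], gene_b = b[ord],
                      rho_ref = rep(0, n), rho_pert = delta[ord],
                      delta = delta[ord], z = rep(5, n), p = rep(1e-4, n),
                      stringsAsFactors = FALSE)
  ccnet:::new_cell_network(cell_id, stage, edges, 0.05, 0.05,
                           "delta_positive")
}

# Nonnegative i.i.d. matrix: normal noise around a large positive mean, so
# Pearson correlations are unaffected by the shift.
noise_expr <- function(n_genes, n_ref, n_query = 1, mean = 100) {
  n <- n_ref + n_query
  tiny_expr(matrix(stats::rnorm(n_genes * n, mean, 1), n_genes, n), n_ref)
}

# Deterministic small study used by pipeline/acceptance fixture checks.
small_scenario <- function(seed = 7) {
  synthetic_scenario(n_genes = 60, n_ref_cells = 12, n_query_cells = 12,
                     n_early_cells = 6, n_planted_edges_per_cell = 5,
                     early_set_size = 20, late_set_size = 12,
                     cerna_coverage = 0.08, seed = seed)
}
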