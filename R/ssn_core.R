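#' @importFrom stats cor pt pnorm setNames
NULL

.var_eps <- 1e-12

# Pearson correlation matrix from sufficient statistics.
# S: per-gene sums; C: gene x gene cross-product matrix; n: cell count.
# Genes with (numerically) zero variance get NA rows/columns.
.rho_from_stats <- function(S, C, n) {
  cov_n <- C - tcrossprod(S) / n
  v <- diag(cov_n)
  scale <- mean(v[v > 0])
  if (!is.finite(scale) || scale <= 0) scale <- 1
  degenerate <- v <= .var_eps * scale
  sd_prod <- sqrt(outer(v, v))
  rho <- cov_n / sd_prod
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  rho[degenerate, ] <- NA_real_
  rho[, degenerate] <- NA_real_
  diag(rho)[!degenerate] <- 1
  rho
}

#' Pairwise Pearson correlations over a cell subset
#'
#' Entry (i, j) is the sample Pearson correlation of genes i and j across
#' the listed cells. Genes with zero variance across those cells yield `NA`
#' rows/columns (excluded downstream).
#'
#' @param x An `ExpressionMatrix`.
#' @param cells Character vector of at least 3 cell identifiers.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x, cells) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  unknown <- setdiff(cells, cell_ids(x))
  if (length(unknown))
    ccn_abort("unknown_cell", "unknown cell id(s): %s", paste(unknown, collapse = ", "))
  if (length(cells) < 3L)
    ccn_abort("too_few_cells", "need at least 3 cells, got %d", length(cells))
  V <- x$values[, cells, drop = FALSE]
  # center per gene before forming cross-products: correlations are
  # translation-invariant and this avoids catastrophic cancellation
  Vc <- V - rowMeans(V)
  .rho_from_stats(rowSums(Vc), tcrossprod(Vc), ncol(V))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r Correlation(s) in \[-1, 1\] (NA allowed, propagated).
#' @param n Number of observations (>= 3).
#' @return Two-sided p-value(s) in \[0, 1\].
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) ccn_abort("too_few_cells", "correlation test needs n >= 3")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    ccn_abort("invalid_parameter", "|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) >= 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact
  tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

#' Build the reference-cell correlation panel
#'
#' Computes pairwise Pearson correlations over the cells flagged
#' `is_reference`, marks the reference-significant pairs at level `alpha`,
#' and caches the per-gene sums and cross-products that allow a one-cell
#' incremental correlation update.
#'
#' @param x An `ExpressionMatrix` with at least 3 reference cells.
#' @param alpha Significance level for reference edges (default 0.05).
#' @return Object of class `ReferencePanel`: list with `cell_ids`, `N`,
#'   `gene_ids`, `rho_ref`, `sig_ref`, `alpha`, `stats`.
#' @export
build_reference_panel <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ref_cells <- x$cell_meta$cell_id[x$cell_meta$is_reference]
  if (length(ref_cells) < 3L)
    ccn_abort("too_few_cells", "need at least 3 reference cells, got %d",
              length(ref_cells))
  V <- x$values[, ref_cells, drop = FALSE]
  # sufficient statistics on data centered at the reference means: the
  # one-cell update stays exact while cross-products keep full precision
  center <- rowMeans(V)
  Vc <- V - center
  S <- rowSums(Vc)
  C <- tcrossprod(Vc)
  N <- length(ref_cells)
  rho <- .rho_from_stats(S, C, N)
  p <- matrix(correlation_pvalue(as.vector(rho), N), nrow(rho), ncol(rho))
  sig <- !is.na(p) & p < alpha
  diag(sig) <- FALSE
  structure(list(cell_ids = ref_cells, N = N, gene_ids = gene_ids(x),
                 rho_ref = rho, sig_ref = sig, alpha = alpha,
                 stats = list(S = S, C = C, center = center)),
            class = "ReferencePanel")
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("<ReferencePanel> N=%d reference cells, %d genes\n",
              x$N, length(x$gene_ids)))
  invisible(x)
}

#' Correlation matrix after adding one query cell to the reference panel
#'
#' Recomputes pairwise Pearson correlations over the N + 1 cells
#' (reference panel plus `cell_k`) by incrementally updating the panel's
#' cached sufficient statistics; equal to a direct recomputation to within
#' 1e-10 per entry.
#'
#' @param panel A `ReferencePanel`.
#' @param x The `ExpressionMatrix` the panel was built from.
#' @param cell_k A non-reference cell identifier.
#' @return Symmetric correlation matrix over N + 1 cells.
#' @export
perturbed_correlation <- function(panel, x, cell_k) {
  stopifnot(inherits(panel, "ReferencePanel"), inherits(x, "ExpressionMatrix"))
  if (cell_k %in% panel$cell_ids)
    ccn_abort("reference_cell", "cell %s is a reference cell", cell_k)
  if (!cell_k %in% cell_ids(x))
    ccn_abort("unknown_cell", "unknown cell id: %s", cell_k)
  if (!identical(panel$gene_ids, gene_ids(x)))
    ccn_abort("metadata_mismatch", "panel and matrix gene sets differ")
  v <- x$values[, cell_k] - panel$stats$center
  .rho_from_stats(panel$stats$S + v, panel$stats$C + tcrossprod(v), panel$N + 1L)
}

#' Differential-correlation Z statistic
#'
#' For a gene pair with reference correlation `rho_ref` over N reference
#' cells and perturbed correlation over N + 1 cells, the change
#' `delta = rho_pert - rho_ref` has null mean 0 and null standard deviation
#' `(1 - rho_ref^2) / (N - 1)`, so `Z = delta * (N - 1) / (1 - rho_ref^2)`.
#'
#' @param delta Change in correlation (vectorised).
#' @param rho_ref Reference correlation(s); `|rho_ref|` must be below
#'   `1 - 1e-12` unless `na_degenerate = TRUE`.
#' @param N Number of reference cells (>= 3).
#' @param na_degenerate If TRUE, degenerate pairs yield `NA` instead of an
#'   error (used by the pipeline, which skips and counts them).
#' @return Z value(s).
#' @export
ssn_z <- function(delta, rho_ref, N, na_degenerate = FALSE) {
  if (N < 3) ccn_abort("too_few_cells", "Z statistic needs N >= 3")
  degenerate <- is.na(rho_ref) | abs(rho_ref) >= 1 - .var_eps
  if (any(degenerate) && !na_degenerate)
    ccn_abort("undefined_variance",
              "null variance undefined for |rho_ref| >= 1 - 1e-12")
  z <- delta * (N - 1) / (1 - rho_ref^2)
  z[degenerate] <- NA_real_
  z
}

#' Standard-normal p-value for a Z statistic
#'
#' @param z Z value(s).
#' @param sided `"two"` (default) for `2 * P(|Z| > |z|)`, `"one"` for the
#'   upper tail `P(Z > z)`.
#' @return p-value(s) in \[0, 1\].
#' @export
z_pvalue <- function(z, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (sided == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
}

.canonical_edges <- function(gene_a, gene_b, ...) {
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  df <- data.frame(gene_a = a, gene_b = b, ..., stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

new_cell_network <- function(cell_id, stage, edges, alpha_edge, alpha_diff,
                             direction_rule, edge_universe = "perturbed",
                             n_degenerate = 0L, log = list()) {
  structure(list(cell_id = cell_id, stage = stage, edges = edges,
                 alpha_edge = alpha_edge, alpha_diff = alpha_diff,
                 direction_rule = direction_rule, edge_universe = edge_universe,
                 n_degenerate = n_degenerate, log = log),
            class = "CellNetwork")
}

#' @export
print.CellNetwork <- function(x, ...) {
  cat(sprintf("<CellNetwork:%s> cell %s: %d edges (alpha_edge=%g, alpha_diff=%g, %s)\n",
              x$stage, x$cell_id, nrow(x$edges), x$alpha_edge, x$alpha_diff,
              x$direction_rule))
  invisible(x)
}

#' Build a cell-specific differential co-expression network (RCN)
#'
#' Pipeline for one query cell: (1) candidate pairs are those significant
#' in the perturbed network at `alpha_edge` (configurable via
#' `edge_universe`); (2) `delta = rho_pert - rho_ref` is tested with the
#' differential-correlation Z statistic ([ssn_z()]); (3) pairs with
#' `z_pvalue < alpha_diff` are kept; (4) the direction rule is applied
#' (default: `delta > 0`; `"rho_pert_positive"` additionally requires
#' `rho_pert > 0`). Degenerate pairs (zero variance, `|rho_ref|` at 1) are
#' skipped and counted.
#'
#' @param panel A `ReferencePanel`.
#' @param x The `ExpressionMatrix` the panel was built from.
#' @param cell_k Query (non-reference) cell identifier.
#' @param alpha_edge Significance level for perturbed-network edges.
#' @param alpha_diff Significance level for the differential Z test.
#' @param direction_rule `"delta_positive"` (default) or
#'   `"rho_pert_positive"`.
#' @param edge_universe Candidate-pair universe: `"perturbed"` (default),
#'   `"union"` (perturbed or reference significant), or `"reference"`.
#' @param sided Sidedness of the Z test (`"two"` default).
#' @return A `CellNetwork` with `stage = "RCN"`; its `edges` data frame has
#'   columns `gene_a`, `gene_b`, `rho_ref`, `rho_pert`, `delta`, `z`, `p`
#'   in deterministic (lexicographic canonical-pair) order.
#' @export
build_cell_rcn <- function(panel, x, cell_k, alpha_edge = 0.05,
                           alpha_diff = 0.05,
                           direction_rule = c("delta_positive", "rho_pert_positive"),
                           edge_universe = c("perturbed", "union", "reference"),
                           sided = c("two", "one")) {
  direction_rule <- match.arg(direction_rule)
  edge_universe <- match.arg(edge_universe)
  sided <- match.arg(sided)

  rho_pert <- perturbed_correlation(panel, x, cell_k)
  rho_ref <- panel$rho_ref
  N <- panel$N

  ut <- which(upper.tri(rho_pert), arr.ind = TRUE)
  rp <- rho_pert[ut]
  rr <- rho_ref[ut]
  defined <- !is.na(rp) & !is.na(rr) & abs(rr) < 1 - .var_eps
  n_degenerate <- sum(!defined)

  p_pert <- correlation_pvalue(rp, N + 1L)
  sig_pert <- !is.na(p_pert) & p_pert < alpha_edge
  sig_ref <- panel$sig_ref[ut]
  candidate <- switch(edge_universe,
                      perturbed = sig_pert,
                      reference = sig_ref,
                      union = sig_pert | sig_ref)
  keep <- defined & candidate

  delta <- rp[keep] - rr[keep]
  z <- ssn_z(delta, rr[keep], N, na_degenerate = TRUE)
  p <- z_pvalue(z, sided)
  pass <- !is.na(p) & p < alpha_diff
  if (direction_rule == "delta_positive") {
    pass <- pass & delta > 0
  } else {
    pass <- pass & delta > 0 & rp[keep] > 0
  }

  idx <- which(keep)[pass]
  g <- panel$gene_ids
  edges <- .canonical_edges(g[ut[idx, 1]], g[ut[idx, 2]],
                            rho_ref = rr[keep][pass],
                            rho_pert = rp[keep][pass],
                            delta = delta[pass], z = z[pass], p = p[pass])
  new_cell_network(cell_k, "RCN", edges, alpha_edge, alpha_diff,
                   direction_rule, edge_universe, n_degenerate,
                   log = list(n_candidates = sum(keep), n_retained = sum(pass)))
}

#' Write a cell network edge list to TSV
#'
#' Columns `gene_a`, `gene_b`, `rho_ref`, `rho_pert`, `delta`, `z`, `p`
#' (plus `shared_mirnas` for CCNs carrying evidence), rows in deterministic
#' canonical-pair order.
#'
#' @param net A `CellNetwork`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
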