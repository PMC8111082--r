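#' Expression matrix with cell metadata
#'
#' Container for a genes x cells nonnegative expression matrix (FPKM-like
#' units) plus per-cell metadata. Gene and cell identifiers must be unique;
#' every cell must carry a group label and a reference flag.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   cells in columns (colnames = cell identifiers). All values must be
#'   finite and >= 0.
#' @param cell_meta Data frame with columns `cell_id`, `group`,
#'   `is_reference` (logical or 0/1), one row per cell of `values`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `cell_meta`.
#' @export
expression_matrix <- function(values, cell_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    ccn_abort("invalid_matrix", "`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ccn_abort("invalid_matrix", "`values` must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(values)))
    ccn_abort("duplicate_id", "duplicate gene identifiers: %s",
              paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    ccn_abort("duplicate_id", "duplicate cell identifiers: %s",
              paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    ccn_abort("non_numeric", "expression matrix contains non-finite or missing values")
  if (any(values < 0))
    ccn_abort("negative_value", "expression values must be >= 0")

  req <- c("cell_id", "group", "is_reference")
  if (!is.data.frame(cell_meta) || !all(req %in% names(cell_meta)))
    ccn_abort("metadata_mismatch", "cell_meta must have columns cell_id, group, is_reference")
  cell_meta <- as.data.frame(cell_meta)[, req]
  cell_meta$cell_id <- as.character(cell_meta$cell_id)
  cell_meta$group <- as.character(cell_meta$group)
  cell_meta$is_reference <- as.logical(cell_meta$is_reference)
  if (anyDuplicated(cell_meta$cell_id))
    ccn_abort("duplicate_id", "duplicate cell_id in metadata")
  missing <- setdiff(colnames(values), cell_meta$cell_id)
  if (length(missing))
    ccn_abort("metadata_mismatch", "cells absent from metadata: %s",
              paste(missing, collapse = ", "))
  cell_meta <- cell_meta[match(colnames(values), cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (any(is.na(cell_meta$group)) || any(!nzchar(cell_meta$group)))
    ccn_abort("metadata_mismatch", "every cell must have a non-empty group label")
  if (any(is.na(cell_meta$is_reference)))
    ccn_abort("metadata_mismatch", "is_reference must be 0/1 for every cell")

  structure(list(values = values, cell_meta = cell_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d genes x %d cells (%d reference)\n",
              nrow(x$values), ncol(x$values), sum(x$cell_meta$is_reference)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
cell_ids <- function(x) colnames(x$values)

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix and its cell metadata
#'
#' The expression file is a delimited genes x cells table with a header row
#' of cell identifiers and gene symbols in the first column. The metadata
#' file must map every cell to a group label and a reference flag
#' (columns `cell_id`, `group`, `is_reference`). Delimiter is inferred from
#' the extension (`.csv` comma, otherwise tab).
#'
#' @param path Path to the expression table.
#' @param meta_path Path to the cell metadata table.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, meta_path) {
  sep <- .sep_for(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (length(header) < 2L)
    ccn_abort("malformed_header", "expression header must name at least one cell")
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c("character", rep("numeric", length(header) - 1L)))
  genes <- tab[[1]]
  if (anyDuplicated(genes))
    ccn_abort("duplicate_id", "duplicate gene identifiers in %s: %s", path,
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(vals)))
    ccn_abort("non_numeric", "non-numeric or missing expression values in %s", path)
  rownames(vals) <- genes

  meta <- utils::read.table(meta_path, header = TRUE, sep = .sep_for(meta_path),
                            check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  expression_matrix(vals, meta)
}

#' Write an expression matrix (and optionally its metadata) to disk
#'
#' Values are written with full double precision so that a read/write cycle
#' reproduces them exactly.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path for the expression table.
#' @param meta_path Optional output path for the metadata table.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, meta_path = NULL) {
  sep <- .sep_for(path)
  df <- data.frame(gene = gene_ids(x),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", cell_ids(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- x$cell_meta
    meta$is_reference <- as.integer(meta$is_reference)
    utils::write.table(meta, meta_path, sep = .sep_for(meta_path),
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter genes by minimum expression prevalence
#'
#' Keeps genes whose expression exceeds `min_value` in at least
#' `ceiling(n_cells * min_fraction)` cells (e.g. 84 cells at fraction 0.25
#' gives a threshold of 21 cells). The cell set is unchanged. The integer
#' cell threshold and the number of genes removed are recorded in the
#' `"filter_log"` attribute of the result.
#'
#' @param x An `ExpressionMatrix`.
#' @param min_value Expression must be strictly greater than this (default 1,
#'   i.e. FPKM > 1).
#' @param min_fraction Minimum fraction of cells (default 0.25).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_by_expression <- function(x, min_value = 1, min_fraction = 0.25) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!(min_fraction > 0 && min_fraction <= 1))
    ccn_abort("invalid_parameter", "min_fraction must be in (0, 1]")
  n_cells <- ncol(x$values)
  threshold <- as.integer(ceiling(n_cells * min_fraction))
  keep <- rowSums(x$values > min_value) >= threshold
  if (!any(keep))
    ccn_abort("empty_filter", "no gene passes the expression filter (> %g in >= %d cells)",
              min_value, threshold)
  out <- expression_matrix(x$values[keep, , drop = FALSE], x$cell_meta)
  attr(out, "filter_log") <- list(cell_threshold = threshold,
                                  n_genes_in = nrow(x$values),
                                  n_genes_kept = sum(keep))
  out
}
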