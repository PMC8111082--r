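#' ceRNA reference edge list
#'
#' Stores undirected competing-endogenous-RNA pairs canonically: each pair
#' (a, b) is kept once with `gene_a < gene_b` lexicographically, so
#' membership queries are symmetric. Self-pairs are dropped with a warning.
#' An optional evidence column (shared miRNA identifiers, `|`-separated)
#' is carried along; duplicated rows have their evidence unioned.
#'
#' @param gene_a,gene_b Character vectors of gene symbols.
#' @param shared_mirnas Optional character vector of `|`-separated miRNA ids.
#' @return Object of class `CeRNAReference`: data frame with columns
#'   `gene_a`, `gene_b` and optionally `shared_mirnas`, plus attributes
#'   `n_self_dropped` and `n_duplicates_merged`.
#' @export
cerna_reference <- function(gene_a, gene_b, shared_mirnas = NULL) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b))
    ccn_abort("format", "gene_a and gene_b must have equal length")
  self <- gene_a == gene_b
  n_self <- sum(self)
  if (n_self > 0)
    ccn_warn("self_pair", "dropped %d self-pair(s) from ceRNA reference", n_self)
  gene_a <- gene_a[!self]; gene_b <- gene_b[!self]
  if (!is.null(shared_mirnas)) shared_mirnas <- as.character(shared_mirnas)[!self]

  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\x1f")
  if (is.null(shared_mirnas)) {
    keep <- !duplicated(key)
    df <- data.frame(gene_a = a[keep], gene_b = b[keep],
                     stringsAsFactors = FALSE)
  } else {
    ev <- split(shared_mirnas, factor(key, levels = unique(key)))
    ev <- vapply(ev, function(v) {
      ids <- unique(unlist(strsplit(v[nzchar(v) & !is.na(v)], "|", fixed = TRUE)))
      paste(sort(ids), collapse = "|")
    }, character(1))
    keep <- !duplicated(key)
    df <- data.frame(gene_a = a[keep], gene_b = b[keep],
                     shared_mirnas = unname(ev[key[keep]]),
                     stringsAsFactors = FALSE)
  }
  n_dup <- sum(duplicated(key))
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("CeRNAReference", "data.frame"),
            n_self_dropped = n_self, n_duplicates_merged = n_dup)
}

cerna_keys <- function(ref) paste(ref$gene_a, ref$gene_b, sep = "\x1f")

#' Query ceRNA reference membership
#'
#' Symmetric in its arguments: `cerna_contains(ref, a, b)` equals
#' `cerna_contains(ref, b, a)`.
#'
#' @param ref A `CeRNAReference`.
#' @param gene_a,gene_b Gene symbols (vectorised).
#' @return Logical vector.
#' @export
cerna_contains <- function(ref, gene_a, gene_b) {
  key <- paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\x1f")
  key %in% cerna_keys(ref)
}

#' Read a ceRNA reference edge list
#'
#' Expects a delimited file whose first two columns are gene symbols; a
#' third column, when present, is read as shared-miRNA evidence. Pairs are
#' canonicalized and deduplicated; self-pairs are dropped with a warning.
#'
#' @param path Path to the edge list (tab-separated, or comma for `.csv`).
#' @param header Whether the file has a header row (default TRUE).
#' @return A [cerna_reference()] object.
#' @export
read_cerna_reference <- function(path, header = TRUE) {
  tab <- utils::read.table(path, header = header, sep = .sep_for(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", colClasses = "character")
  if (ncol(tab) < 2L)
    ccn_abort("format", "ceRNA reference must have at least two columns: %s", path)
  ev <- if (ncol(tab) >= 3L) tab[[3]] else NULL
  cerna_reference(tab[[1]], tab[[2]], shared_mirnas = ev)
}

#' Summarise a ceRNA reference
#'
#' @param ref A `CeRNAReference`.
#' @return List with `n_pairs` (distinct canonical pairs) and `n_rnas`
#'   (distinct symbols).
#' @export
cerna_summary <- function(ref) {
  list(n_pairs = nrow(ref),
       n_rnas = length(unique(c(ref$gene_a, ref$gene_b))))
}
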