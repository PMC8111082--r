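.biotypes <- c("lncRNA", "mRNA", "miRNA", "pseudogene", "other")
.marker_tags <- c("CGC", "GAD", "ERG", "ER_DEG")

#' Construct a gene annotation table
#'
#' One row per primary symbol: biotype (lncRNA / mRNA / miRNA / pseudogene /
#' other), `|`-separated aliases, and `|`-separated marker tags (CGC, GAD,
#' ERG, ER_DEG). Aliases may not collide with a different symbol's primary
#' name, and no alias may point to two different primaries.
#'
#' @param symbol Character vector of primary symbols.
#' @param biotype Character vector of biotypes.
#' @param aliases `|`-separated aliases per symbol ("" for none).
#' @param tags `|`-separated marker tags per symbol ("" for none).
#' @return Object of class `GeneAnnotation` (a data frame).
#' @export
gene_annotation <- function(symbol, biotype = "other",
                            aliases = "", tags = "") {
  symbol <- as.character(symbol)
  if (any(!nzchar(symbol)) || anyDuplicated(symbol))
    ccn_abort("duplicate_id", "annotation symbols must be nonempty and unique")
  n <- length(symbol)
  biotype <- rep_len(as.character(biotype), n)
  if (!all(biotype %in% .biotypes))
    ccn_abort("invalid_parameter", "biotype must be one of: %s",
              paste(.biotypes, collapse = ", "))
  aliases <- rep_len(as.character(aliases), n)
  tags <- rep_len(as.character(tags), n)
  bad_tags <- setdiff(unlist(strsplit(tags[nzchar(tags)], "|", fixed = TRUE)),
                      .marker_tags)
  if (length(bad_tags))
    ccn_abort("invalid_parameter", "unknown marker tag(s): %s",
              paste(bad_tags, collapse = ", "))
  df <- data.frame(symbol = symbol, biotype = biotype,
                   aliases = aliases, tags = tags, stringsAsFactors = FALSE)
  alias_map(df)  # validates conflict-freeness
  structure(df, class = c("GeneAnnotation", "data.frame"))
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `symbol`, `biotype`, `aliases`
#' (`|`-separated), `tags` (`|`-separated). Missing alias/tag columns are
#' treated as empty.
#'
#' @param path Path to the annotation table.
#' @return A [gene_annotation()] object.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", colClasses = "character")
  if (!all(c("symbol", "biotype") %in% names(tab)))
    ccn_abort("format", "annotation table needs columns symbol, biotype: %s", path)
  gene_annotation(tab$symbol, tab$biotype,
                  aliases = if ("aliases" %in% names(tab)) tab$aliases else "",
                  tags = if ("tags" %in% names(tab)) tab$tags else "")
}

#' Alias-to-primary-symbol lookup
#'
#' @param ann A `GeneAnnotation`.
#' @return Named character vector mapping alias -> primary symbol.
#' @export
alias_map <- function(ann) {
  alias_lists <- strsplit(ann$aliases, "|", fixed = TRUE)
  alias <- unlist(alias_lists)
  primary <- rep(ann$symbol, lengths(alias_lists))
  keep <- nzchar(alias)
  alias <- alias[keep]; primary <- primary[keep]
  clash <- alias %in% ann$symbol & primary != ann$symbol[match(alias, ann$symbol)]
  if (any(clash))
    ccn_abort("alias_conflict", "alias collides with another primary symbol: %s",
              paste(unique(alias[clash]), collapse = ", "))
  dup <- duplicated(alias) & !duplicated(paste(alias, primary))
  if (any(dup))
    ccn_abort("alias_conflict", "alias maps to multiple primaries: %s",
              paste(unique(alias[dup]), collapse = ", "))
  keep2 <- !duplicated(alias)
  stats::setNames(primary[keep2], alias[keep2])
}

#' Rewrite expression gene identifiers to primary symbols
#'
#' Rows named by an alias are renamed to the alias's primary symbol; rows
#' already named by a primary symbol are untouched. Two rows mapping to the
#' same primary symbol raise an error rather than being merged silently.
#'
#' @param x An `ExpressionMatrix`.
#' @param ann A `GeneAnnotation` providing the alias map.
#' @return The `ExpressionMatrix` with harmonized gene identifiers.
#' @export
harmonize_symbols <- function(x, ann) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  map <- alias_map(ann)
  g <- gene_ids(x)
  is_alias <- g %in% names(map) & !(g %in% ann$symbol)
  g[is_alias] <- map[g[is_alias]]
  if (anyDuplicated(g))
    ccn_abort("duplicate_id", "harmonization maps multiple rows to: %s",
              paste(unique(g[duplicated(g)]), collapse = ", "))
  rownames(x$values) <- g
  x
}

#' Biotype lookup with a default for unannotated genes
#' @param genes Character vector of symbols.
#' @param ann A `GeneAnnotation` (or NULL).
#' @return Character vector of biotypes ("other" when unannotated).
#' @export
biotype_of <- function(genes, ann) {
  if (is.null(ann)) return(rep("other", length(genes)))
  bt <- ann$biotype[match(genes, ann$symbol)]
  bt[is.na(bt)] <- "other"
  bt
}
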