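#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene symbols. Duplicate set names and sets
#' with no members are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return Object of class `GeneSetCollection`: list with `sets` (named list
#'   of character vectors) and `source`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) ccn_abort("format", "empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    ccn_abort("duplicate_id", "duplicate gene-set name(s): %s",
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    members
  })
  if (any(lengths(parts) < 3L) || any(lengths(sets) == 0L))
    ccn_abort("empty_set", "gene set with no members in %s", path)
  names(sets) <- nm
  gene_set_collection(sets, source = path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique names, nonempty sets).
#' @param source Free-text provenance.
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, source = "in-memory") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    ccn_abort("duplicate_id", "gene-set names must be present and unique")
  if (any(lengths(sets) == 0L))
    ccn_abort("empty_set", "gene sets must be nonempty")
  structure(list(sets = lapply(sets, as.character), source = source),
            class = "GeneSetCollection")
}

#' Write a gene-set collection to GMT
#'
#' @param gs A `GeneSetCollection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$source, gs$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("<GeneSetCollection> %d sets (source: %s)\n",
              length(x$sets), x$source))
  invisible(x)
}
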