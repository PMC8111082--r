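#' Fold-change-ranked gene list
#'
#' Scores are `log2((case + pseudocount) / (control + pseudocount))`,
#' sorted descending; ties are broken lexicographically by gene so the
#' order is total and deterministic.
#'
#' @param case_expr,control_expr Named numeric vectors (gene -> expression)
#'   sharing at least one gene.
#' @param pseudocount Added to both sides before the ratio (default 0.01);
#'   with `pseudocount = 0`, zero expression raises an error.
#' @return Object of class `RankedList`: data frame with columns `gene`,
#'   `score`.
#' @export
make_ranked_list <- function(case_expr, control_expr, pseudocount = 0.01) {
  shared <- intersect(names(case_expr), names(control_expr))
  if (!length(shared))
    ccn_abort("empty_background", "case and control share no genes")
  num <- case_expr[shared] + pseudocount
  den <- control_expr[shared] + pseudocount
  if (any(den <= 0) || any(num <= 0))
    ccn_abort("division_by_zero",
              "zero expression with pseudocount %g; use a positive pseudocount",
              pseudocount)
  score <- log2(num / den)
  ord <- order(-score, shared)
  out <- data.frame(gene = shared[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("RankedList", "data.frame")
  out
}

#' Read a ranked list from a 2-column .rnk file
#' @param path Tab-separated file: gene, score (no header by convention).
#' @param header Whether the file has a header row.
#' @return A `RankedList`.
#' @export
read_ranked_list <- function(path, header = FALSE) {
  tab <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 2) ccn_abort("format", ".rnk needs two columns: %s", path)
  if (anyDuplicated(tab[[1]]))
    ccn_abort("duplicate_id", "duplicate genes in ranked list")
  score <- as.numeric(tab[[2]])
  ord <- order(-score, tab[[1]])
  out <- data.frame(gene = as.character(tab[[1]])[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("RankedList", "data.frame")
  out
}

# Enrichment score from sorted hit positions. pos: increasing positions of
# hits in the ranked list; w: |score|^weight at those positions; n: list
# length. The running sum's extrema occur at hits (just after the
# increment) or just before hits, so only 2k candidate points need
# checking.
.es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  nr <- sum(w)
  inc <- if (nr > 0) w / nr else rep(1 / k, k)
  miss_step <- 1 / (n - k)
  hitsum <- cumsum(inc)
  j <- seq_len(k)
  at_hit <- hitsum - (pos - j) * miss_step        # just after hit j
  before_hit <- c(0, hitsum[-k]) - (pos - j) * miss_step  # just before hit j
  # the running sum starts and ends at 0, peaks just after hits and dips
  # just before hits; on an exact |max| = |min| tie the positive side wins
  mx <- max(at_hit, 0)
  mn <- min(before_hit, 0)
  if (mx >= -mn) mx else mn
}

#' Weighted running-sum enrichment score
#'
#' The running sum increments by `|score|^weight / sum_hits |score|^weight`
#' at genes in the set and decrements by `1 / (n - n_hits)` elsewhere; the
#' enrichment score is the signed maximum deviation from zero. At
#' `weight = 0` this reduces to the classical Kolmogorov-Smirnov statistic
#' on ranks.
#'
#' @param ranked A `RankedList`.
#' @param gene_set Character vector; must overlap the ranked genes and not
#'   cover all of them.
#' @param weight Exponent on |score| (default 1).
#' @return Enrichment score in \[-1, 1\].
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  n <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) ccn_abort("empty_overlap", "gene set does not overlap ranked list")
  if (all(hit)) return(1)
  pos <- which(hit)
  w <- abs(ranked$score[pos])^weight
  .es_from_positions(pos, w, n)
}

#' Preranked gene set enrichment analysis
#'
#' For each set, computes the observed enrichment score and a null from
#' `n_perm` random gene sets of equal size drawn from the ranked universe
#' (gene-label permutation). `NES = ES / mean(|null ES| of the same
#' sign)`; `p_perm = (1 + #\{null as or more extreme, same sign\}) /
#' (1 + n_perm)`, so p-values are floored at `1/(n_perm + 1)`.
#' Reproducible under a fixed seed.
#'
#' @param ranked A `RankedList`.
#' @param gs A `GeneSetCollection`.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation null.
#' @param weight Exponent on |score| (default 1).
#' @return Data frame with columns `set_name`, `size`, `ES`, `NES`,
#'   `p_perm`, `n_perm`, `seed`, and a list column `leading_edge`.
#' @export
gsea_preranked <- function(ranked, gs, n_perm = 1000, seed = 1, weight = 1) {
  if (n_perm < 100) ccn_abort("invalid_parameter", "n_perm must be >= 100")
  n <- nrow(ranked)
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)
  absw <- abs(ranked$score)^weight
  rows <- lapply(names(gs$sets), function(nm) {
    set <- gs$sets[[nm]]
    if (length(set) > n)
      ccn_abort("invalid_parameter", "set '%s' larger than ranked universe", nm)
    hit <- ranked$gene %in% set
    k <- sum(hit)
    if (k == 0L) ccn_abort("empty_overlap", "set '%s' does not overlap ranked list", nm)
    es <- if (k == n) 1 else .es_from_positions(which(hit), absw[which(hit)], n)
    null_es <- vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(n, k))
      if (k == n) 1 else .es_from_positions(pos, absw[pos], n)
    }, numeric(1))
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(sign(null_es) == sign(es) & abs(null_es) >= abs(es))) /
      (1 + n_perm)
    # leading edge: hits up to (ES>0) / from (ES<0) the running-sum extremum
    pos <- which(hit)
    w <- absw[pos]
    nr <- sum(w); inc <- if (nr > 0) w / nr else rep(1 / k, k)
    miss_step <- if (k < n) 1 / (n - k) else 0
    run_at_hit <- cumsum(inc) - (pos - seq_len(k)) * miss_step
    le <- if (es >= 0) {
      ranked$gene[pos[seq_len(which.max(run_at_hit))]]
    } else {
      before <- c(0, cumsum(inc)[-k]) - (pos - seq_len(k)) * miss_step
      ranked$gene[pos[which.min(before):k]]
    }
    out <- data.frame(set_name = nm, size = k, ES = es, NES = nes,
                      p_perm = p, n_perm = n_perm, seed = seed,
                      stringsAsFactors = FALSE)
    out$leading_edge <- list(le)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top functional-enrichment terms for a cell network
#'
#' Upper-tail hypergeometric test of the network's genes against each set,
#' sorted ascending by p (ties broken by set name), truncated to `top_k`.
#'
#' @param ccn A `CellNetwork`.
#' @param gs A `GeneSetCollection` (e.g. GO biological process, REACTOME).
#' @param background Background gene symbols.
#' @param top_k Rows to keep (default 10).
#' @return Data frame as [enrich_cell()], sorted, truncated.
#' @export
functional_enrichment <- function(ccn, gs, background, top_k = 10) {
  e <- enrich_cell(ccn, gs, background)
  e <- e[order(e$p, e$set_name), , drop = FALSE]
  e <- e[seq_len(min(top_k, nrow(e))), , drop = FALSE]
  rownames(e) <- NULL
  e
}
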