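# ccnet — cell-specific ceRNA networks from single-cell expression

`ccnet` builds, for every cell in a single-cell RNA-seq experiment, its own
competing-endogenous-RNA (ceRNA) network, and uses those per-cell networks to
classify response subtypes, find edge biomarkers, rank hub lncRNAs, and infer
lncRNA function. It is aimed at transcriptomics researchers who want a
network-level view of how individual cells respond to a stimulus (the
motivating application is estrogen response in breast-cancer cell lines),
rather than per-gene differential expression.

## The method

A panel of *N* baseline cells (e.g. unstimulated cells) is designated as the
**reference**. For each gene pair the reference Pearson correlation
ρ<sub>N</sub> is computed over those cells; adding one query cell *k* gives
the **perturbed** correlation ρ<sub>N+1</sub>. The change

&nbsp;&nbsp;&nbsp;&nbsp;Δρ = ρ<sub>N+1</sub> − ρ<sub>N</sub>

has, for a cell drawn from the reference population, mean 0 and standard
deviation (1 − ρ<sub>N</sub>²)/(N − 1), so

&nbsp;&nbsp;&nbsp;&nbsp;Z = Δρ · (N − 1) / (1 − ρ<sub>N</sub>²)

is tested against the standard normal. Edges that are significant in the
perturbed network (t-test on ρ<sub>N+1</sub>, p < 0.05), significantly
changed (Z-test, p < 0.05), and **positive** (Δρ > 0 — ceRNA partners are
positively co-expressed) form the cell-specific RNA–RNA co-expression network
(RCN). Intersecting the RCN with a ceRNA reference edge list (e.g. a
CLIP-supported miRNA-sharing network) yields the cell-specific ceRNA network
(**CCN**).

Downstream analyses operate on the CCNs:

* **Subtype classification** — each cell's CCN gene set is tested against
  early/late response hallmark gene sets with the upper-tail hypergeometric
  test P = Σ<sub>x≥n</sub> C(K,x)·C(M−K, m−x)/C(M,m); cells with
  p<sub>early</sub> < 0.05 are called early responders.
* **Edge biomarkers** — gene pairs that appear only in one subtype's
  networks, ranked by prevalence then mean |Δρ|.
* **Topology** — degree, betweenness (unordered-pair convention) and
  closeness (per connected component); lncRNAs ranked by average degree
  across a subtype's cells.
* **Preranked GSEA** — weighted running-sum enrichment of a fold-change
  ranked list with a gene-label permutation null.

A synthetic-data generator (`synthetic_scenario()` / `generate_synthetic()`)
produces expression matrices with block-correlated baselines, planted
differential edges, a matching ceRNA reference, hallmark-like gene sets, and
ground-truth tables, so the whole pipeline is testable end to end without
any external downloads.

## Worked example

```r
library(ccnet)

sim  <- generate_synthetic(synthetic_scenario(seed = 42))
expr <- filter_by_expression(sim$expr)        # FPKM > 1 in >= 25% of cells
expr
#> <ExpressionMatrix> 150 genes x 84 cells (20 reference)
attr(expr, "filter_log")$cell_threshold      # ceil(84 * 0.25)
#> [1] 21

ccns <- build_all_ccns(expr, sim$cerna)      # one CCN per query cell
ccns[["CELL001"]]
#> <CellNetwork:CCN> cell CELL001: 30 edges (alpha_edge=0.05, alpha_diff=0.05, delta_positive)

bg    <- intersect(rownames(expr$values),
                   unique(c(sim$cerna$gene_a, sim$cerna$gene_b)))
calls <- classify_cells(ccns, sim$gene_sets$sets$EARLY_RESPONSE,
                        sim$gene_sets$sets$LATE_RESPONSE, bg)
head(calls, 3)
#>   cell_id      p_early    p_late          label alpha
#> 1 CELL001 4.515564e-01 0.1812633          other  0.05
#> 2 CELL002 7.023063e-05 0.8961843 early_response  0.05
#> 3 CELL003 6.509241e-02 0.4137569          other  0.05
table(calls$label)
#> early_response          other
#>             41             23

head(rank_hub_lncrnas(ccns, calls, ann = sim$annotation), 5)
#>     gene biotype average_degree n_cells_present
#> 1 LNC037  lncRNA       4.764706              17
#> 2 LNC006  lncRNA       4.636364              11
#> 3 LNC022  lncRNA       4.333333              12
#> 4 LNC027  lncRNA       4.217391              23
#> 5 LNC032  lncRNA       4.214286              14
```

The cell threshold 21 is the prevalence cutoff for an 84-cell study; the
p-values are upper-tail hypergeometric probabilities of the observed overlap
between a cell's CCN genes and each hallmark set; the hub table averages a
lncRNA's degree over the early-response cells in which it appears. In this
simulation 41 of the 64 query cells were planted as early responders, and
the classification recovers them.

`run_pipeline(config)` executes the whole chain (read → filter → panel →
CCNs → classify → markers → topology) from a JSON config and writes
per-stage TSVs plus a checksummed manifest; `inst/cli/ccnet.R` is a thin
command-line wrapper.

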