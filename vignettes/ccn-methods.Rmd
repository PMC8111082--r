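---
title: "Cell-specific ceRNA networks: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-specific ceRNA networks: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccnet)
```

## The model

Bulk co-expression networks average over cells; `ccnet` asks what a *single*
cell does to the co-expression structure of a baseline population. Given
$N$ reference cells (unstimulated baseline) and one query cell $k$, every
gene pair has a reference Pearson correlation $\rho_N$ and a perturbed
correlation $\rho_{N+1}$ computed after appending cell $k$. Under the null
that cell $k$ is drawn from the reference population, the differential
correlation $\Delta\rho = \rho_{N+1} - \rho_N$ has mean zero and standard
deviation

$$\sigma_{\Delta\rho} = \frac{1 - \rho_N^2}{N - 1},$$

so $Z = \Delta\rho\,(N-1)/(1-\rho_N^2)$ is referred to the standard normal.
The exact null law of $\Delta\rho$ (a sharply peaked, heavy-shouldered
"volcano" shape) is only approximately normal; the approximation is the
method's working assumption and its quality is measured empirically by the
null-calibration test and the acceptance script (see *Limitations*).

A cell's RNA–RNA co-expression network (RCN) keeps pairs that are

1. significant in the perturbed network — two-sided t-test on
   $\rho_{N+1}$ with $N-1$ degrees of freedom, $p < \alpha_{edge}$;
2. significantly changed — $Z$-test, $p < \alpha_{diff}$;
3. positive — $\Delta\rho > 0$, because competing endogenous RNAs are
   positively co-expressed through shared miRNA loss.

Intersecting the RCN with a ceRNA reference edge list (canonical unordered
symbol pairs) yields the cell-specific ceRNA network (CCN). All edge
statistics survive the intersection, so downstream consumers can always
re-derive the filters.

Downstream, CCN gene sets are tested against hallmark gene sets with the
upper-tail hypergeometric probability (tail *including* the observed
overlap), cells are labelled `early_response` when the early-hallmark p is
below $\alpha$ (late is secondary: tested only for cells not already called
early, though both p-values are always emitted so users can re-decide);
subtype-exclusive edges are ranked; degree, betweenness and closeness are
computed per network; and a preranked GSEA with a gene-label permutation
null serves lncRNA function inference.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `min_value`, `min_fraction` | 1, 0.25 | keep genes with expression > 1 (FPKM-like units) in at least `ceil(n_cells * 0.25)` cells; strict inequality, ceiling rule (84 cells gives a threshold of 21) |
| `alpha_ref`, `alpha_edge`, `alpha_diff` | 0.05 each | raw (uncorrected) significance gates for reference edges, perturbed edges and the differential test; the method intentionally uses per-test p-values, matching its single-cell discovery framing |
| `direction_rule` | `delta_positive` | positivity filter; `rho_pert_positive` additionally requires $\rho_{N+1}>0$ for users who read "positive edge" as positive absolute co-expression rather than positive change |
| `edge_universe` | `perturbed` | candidate pairs are those significant *after* adding the cell, so edges absent from the reference remain discoverable; `reference` and `union` are available for sensitivity analysis |
| `background_rule` | `cerna` | the hypergeometric background is the filtered genes that occur in at least one ceRNA-reference pair — the only universe a CCN node can come from, hence the fair null; `all_filtered` widens it |
| `top_k` (markers) | 20 per subtype | how many exclusive edges per subtype; ranking is (number of carrying cells, then mean \|Δρ\|, then lexicographic pair) — an explicit deterministic rule, since prevalence is the property a marker must have and the tie-breaks make output byte-reproducible |
| `presence_rule` (hubs) | `present_only` | hub lncRNA average degree is taken over cells where the lncRNA appears; `all_cells` includes zeros. Both are sensible summaries; the choice is recorded in the output's metadata |
| `weight`, `n_perm` (GSEA) | 1, 1000 | standard weighted running-sum exponent; permutation floor is $1/(n_{perm}+1)$ |

Expression values are used as supplied (no log transform) by default:
Pearson correlation on the raw scale is what the differential statistic is
derived for. Users who prefer correlations on a log scale can transform
before constructing the `ExpressionMatrix`; nothing downstream assumes a
scale.

## Numerical choices

* **Sufficient statistics and centering.** The reference panel caches
  per-gene sums and the gene-by-gene cross-product matrix of *centered*
  reference data (centered at the reference means). Adding one cell is then
  a rank-one update, and because correlations are translation-invariant the
  centering removes the catastrophic cancellation that raw cross-products
  suffer when means dominate variances. The incremental result is required
  (and tested) to match a direct recomputation to 1e-10.
* **Degenerate pairs.** Genes with zero variance across the panel, and
  pairs with $|\rho_N| \ge 1 - 10^{-12}$ (undefined null variance), are
  skipped and counted, never propagated as NaN. The per-network
  `n_degenerate` count is part of the object.
* **Canonical edges.** Every pair is stored with `gene_a < gene_b`
  and emitted in lexicographic order, so reruns produce byte-identical
  files; symbols are case-sensitive and matched exactly (aliases are
  resolved explicitly through the annotation table, never fuzzily).
* **Enrichment-score extrema.** The running sum starts and ends at zero,
  peaks just after hits and dips just before hits, so only those $2k$
  points are evaluated; an exact tie between the positive and negative
  extreme resolves to the positive side. Tests compare this shortcut with
  the naive full running sum and with an independent implementation.
* **Closeness on disconnected graphs.** The textbook formula assumes a
  connected graph; CCNs are usually fragmented. Closeness is computed
  within each node's connected component with $n$ the component size, and
  isolated nodes get 0. Betweenness uses the unordered-pair convention
  (each $\{s,t\}$ once); directed-convention tools report doubled values.

## What the generator emulates — and what it does not

`synthetic_scenario()` mirrors the shape of the motivating study: 20
reference cells plus 64 query cells in three stimulation groups, a gene
panel of 150 symbols (a fifth lncRNA-named), block-correlated baseline
expression, eight planted differential pairs per query cell displaced by 6
latent standard deviations, a ceRNA reference containing every planted pair
plus 5% random coverage, disjoint early/late hallmark-like sets (40 and 30
genes), and 41 of 64 cells planted as early responders whose planted-pair
endpoints are drawn from the early set with probability 0.8. Baselines are
lognormal (Gaussian latent, exponentiated), giving skewed nonnegative
FPKM-like values whose latent correlation structure is exactly the
configured one; correlation targets are therefore specified on the latent
scale.

The generator deliberately does **not** simulate read-count noise, dropout,
library-size variation, or miRNA-mediated dynamics. Passing the recovery
tests therefore demonstrates that the statistics and plumbing do what they
claim on data satisfying the model's assumptions — not that the method is
robust to the technical noise of real scRNA-seq, which the expression
filter only partially addresses.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in about a minute: oracle equivalence on up to 50 genes and
25 cells (100 instances), exhaustive hypergeometric enumeration to
background size 15, 200 random graphs of up to 8 nodes against
breadth-first-search oracles, 300 null-calibration replicates at 8 genes,
200 planted-edge replicates, and 50 (tests) or 20 (script) full runs of the
default 150-gene scenario. These sizes are statements about the validation
design, and the pipeline itself is vectorised over gene pairs, so panels of
a few thousand genes remain practical (memory grows with the square of the
gene count for the cached correlation matrices).

## Limitations

* The normal approximation to the differential-correlation null is mildly
  anticonservative at $\alpha = 0.05$ (the acceptance script's
  `null_rejection_rate` measures the realized size; the calibration test
  bounds it with a replicate-level binomial band around 0.05). Raw p-values
  near the gate should be read accordingly; a BH correction can be applied
  to the emitted edge p-values by users who need strict error control.
* Conditioning edges on perturbed-network significance *before* the
  differential test couples the two gates; the per-edge p-values are
  marginal, not selection-adjusted.
* The ceRNA reference is taken as ground truth; genes absent from it can
  never enter a CCN, which is also why it defines the default enrichment
  background.
* Subtype labels are threshold calls on one test per hallmark; cells near
  $\alpha$ flip between labels under resampling, which is why both
  p-values are always emitted.
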