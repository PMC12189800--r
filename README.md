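# zganet

Integrative network analysis for staged early-embryo transcriptomes —
the kind of study that profiles single embryos across cleavage stages
(e.g. 8-, 16- and 32-cell sheep embryos spanning zygotic genome
activation) and asks which co-expression modules track development and
how their protein-interaction core is organised into functional
communities.

The package chains four analyses behind tibble-first functions:

1. **DEG filtering and contrast overlap** — threshold external
   differential-expression tables (`|log2FC| > 1`, adjusted `p < 0.05`,
   both strict) and compute Venn-style overlap regions across stage
   contrasts.
2. **Weighted co-expression networks (WGCNA-style)** — MAD top-k gene
   selection, soft threshold chosen by scale-free fit of the unsigned
   adjacency `a_ij = |r_ij|^β`, topological overlap
   `TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, static-cut
   module detection, module eigengenes (first PC, unit variance,
   sign-fixed), and module–stage Pearson correlation with t-based
   p-values.
3. **PPI hub cores** — weighted graphs with degrees `k_i = Σ_j A_ij`
   and total weight `m = ½ Σ_ij A_ij` (so `Σ k_i = 2m` exactly), and
   strict-threshold degree filtering on pre-filter degrees.
4. **Louvain community detection, from scratch** — modularity

   `Q = (1/2m) Σ_ij (A_ij − k_i k_j / 2m) δ(c_i, c_j)`

   optimised by greedy local moves (each accepted move has `ΔQ > 0`,
   validated against from-scratch recomputation to 1e−10) alternating
   with super-node aggregation that preserves Q exactly, plus an
   exhaustive set-partition oracle for graphs of ≤ 8 nodes. Per-community
   over-representation uses upper-tail hypergeometric tests with
   Benjamini–Hochberg correction.

Because studies of this kind rarely deposit their raw data, the package
ships generators that simulate every input with known ground truth:
staged negative-binomial counts with planted co-expression modules whose
eigengenes track stage, weighted stochastic-block-model interaction
graphs with hub injection, and annotation sets with planted
community-specific enrichment. Every pipeline stage is tested against
what was planted.

## Worked example

The bundled all-synthetic configuration simulates the full study design
at desk scale and runs the complete chain:

```r
library(zganet)

summary <- run_pipeline(default_synthetic_config(seed = 1))
summary
#> <run_summary>
#>   genes x samples: 700 x 24; selected: 200; beta = 8
#>   modules: 3 (+19 grey); target: blue (60 genes)
#>   core subnetwork: 60 nodes, 452 edges
#>   communities: 2 (sizes 30, 30), Q = 0.4590
#>   enriched terms (p.adj < 0.05): 6
```

Reading: of 700 simulated genes (3 planted modules × 60 plus 520
background), the 200 most variable were selected; three co-expression
modules were detected (19 selected genes stayed unassigned/grey); the
module whose eigengene correlates most with the latest stage (`blue`,
60 genes — the planted rising module) was projected onto the simulated
interaction network; its weighted-degree core of 60 nodes and 452 edges
split into exactly the two planted 30-node communities at modularity
0.459; and the planted annotation terms for those two blocks dominate
the enrichment table:

```r
head(summary$results$enrichment[, c("group", "term_id", "term_name", "k", "n", "p_adj")], 3)
#> # A tibble: 3 × 6
#>   group term_id term_name          k     n      p_adj
#>   <chr> <chr>   <chr>          <int> <int>      <dbl>
#> 1 0     T0013   planted_comm_1    18    30 0.00000561
#> 2 0     T0001   planted_comm_1    16    30 0.0000292
#> 3 0     T0007   planted_comm_1    15    30 0.0000583
```

Individual stages compose just as well — for example, community
detection alone:

```r
tri2 <- weighted_graph(data.frame(from = c("a","b","c","d","e","f"),
                                  to   = c("b","c","a","e","f","d")))
res <- run_louvain(tri2, seed = 1)
res
#> <louvain_result: 2 communities, Q = 0.5000, 1 level(s)>
#> community sizes: 3, 3
brute_force_max_modularity(tri2)$q   # exhaustive optimum agrees
#> [1] 0.5
```

Fitted objects carry `tidy()`/`glance()` methods and `autoplot()`
visualisations (soft-threshold diagnostics, module–stage heatmap,
enrichment dot plot, Q trajectory). A thin command-line wrapper lives at
`inst/cli/zganet.R` (`run-all` and `community` subcommands).

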