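---
title: "Methods: co-expression modules and network communities for staged embryo transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules and network communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zganet)
```

## The analysis this package implements

Zygotic genome activation (ZGA) — the hand-over from maternal transcripts
to embryo-driven transcription — unfolds over a few cleavage stages (in
sheep, across the 8-, 16- and 32-cell stages). A now-common systems-level
strategy for dissecting it chains four steps:

1. **Differential expression filtering.** External DE results (one table
   per stage contrast) are thresholded to genes with `|log2FC| > 1` and
   adjusted `p < 0.05`, and the contrasts' overlap structure is computed.
2. **Weighted co-expression network analysis.** The most variable genes
   form a correlation-power network; hierarchical clustering of the
   topological overlap yields modules; each module is summarised by an
   eigengene whose correlation with stage identifies the developmentally
   relevant module.
3. **Interaction-core extraction.** The genes of the stage-associated
   module are projected onto a weighted protein–protein interaction (PPI)
   graph and thinned to high-degree hubs.
4. **Community detection and enrichment.** Weighted Louvain community
   detection partitions the hub core; each community is tested for
   over-representation against annotation gene sets.

`zganet` implements this chain as composable tibble-in/tibble-out
functions plus a config-driven `run_pipeline()`, and pairs it with
generators that simulate every input with known ground truth, so each
stage — and the chain as a whole — is testable without access to any
particular study's data.

## Differential-expression filtering

`filter_deg_table()` applies both thresholds strictly (`>` and `<`), so a
gene at exactly log2FC 1 or adjusted p 0.05 is excluded; rows with missing
adjusted p (produced by independent filtering in common DE tools) are
dropped. `contrast_overlap()` reports exclusive Venn-style regions: each
gene belongs to exactly one region, the set of contrasts that contain it.
DE testing itself is out of scope — tables are inputs, produced upstream
by dedicated tools.

## The co-expression network

Given a gene-by-sample matrix (by default log2-CPM via `log_cpm()`;
`use_raw_counts = TRUE` bypasses the transform for literal replication of
counts-based analyses), `mad_select_top_k()` keeps the `k` most variable
genes by the raw median absolute deviation `median(|x - median(x)|)`,
with MAD ties broken lexicographically by gene id for reproducibility.
The conventional `k` for genome-wide data is 5000; the bundled synthetic
configuration uses 200 of 700 simulated genes, the same selection
fraction at desk scale.

The network is **unsigned**: `a_ij = |r_ij|^beta`. The power sharpens the
contrast between strong and weak correlations. `pick_soft_threshold()`
scores each candidate power by the scale-free fit of its connectivity
distribution: connectivities `k_i = sum_{j != i} a_ij` are binned, and
log10 frequency is regressed on log10 mean connectivity; the signed fit
index is `-sign(slope) * R^2`, positive when frequency decreases with
connectivity as a scale-free law requires. The chosen power is the
smallest one reaching `r2_cut = 0.85`, falling back (with a warning) to
the best-fitting candidate. An explicit `beta` (8 is typical for unsigned
networks of this kind) can be supplied instead.

Topological overlap is the standard unsigned form

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

and modules come from average-linkage clustering of `1 - TOM` with a
**static cut**. A static cut replaces the dynamic hybrid tree cut used by
full-featured WGCNA implementations; it is simpler and fully
deterministic, at the cost of a tuning parameter. Its default height is
0.9: on both simulated and permuted data, genes of one module finish
merging at dissimilarities around 0.6–0.8, while unrelated pairs — and,
importantly, pairs from mutually *anticorrelated* modules — sit at about
0.94 and above, so 0.9 lies inside the gap. Cutting very close to 1
(e.g. 0.99) empirically merges anticorrelated modules (an unsigned
network cannot tell `r` from `-r`) and chains background genes, which is
why that tempting "almost root" cut is not the default. Clusters smaller
than `min_module_size = 30` are relabelled `grey` (unassigned); surviving
modules take the conventional colour names in decreasing size order
(largest = `turquoise`).

Each module's **eigengene** is the first principal component of its
per-gene z-scored submatrix, scaled to unit variance, signed so that the
mean correlation with member genes is non-negative; the proportion of
variance it explains is reported. `module_trait_correlation()` one-hot
encodes the stages (one indicator per stage, matching the per-stage
columns of the usual module–trait heatmap; stages are *not* treated as
ordinal) and reports the Pearson correlation of each eigengene with each
indicator plus the two-sided p-value from
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.

Two replication caveats are worth stating: whether the original analyses
of this kind transform counts before network construction, and whether
they use signed or unsigned networks, is often unreported. This package
defaults to log-CPM and unsigned, and exposes both choices.

## The interaction graph and its hub core

`weighted_graph()` stores an undirected graph with positive weights
(duplicate orientations merged keeping the maximum, as STRING-style dumps
list both directions; self-pairs rejected). Degrees follow the weighted
definition `k_i = sum_j A_ij` and the total weight is
`m = (1/2) sum_ij A_ij`, so `sum_i k_i = 2m` holds exactly — a testable
identity maintained by every operation.

`filter_by_degree()` keeps nodes with `k_i` strictly above the threshold,
**computed on the graph before filtering**, in a single pass: the
surviving induced subgraph may contain nodes whose post-filter degree
falls below the threshold, may be disconnected, or may be empty. This
single-pass contract is deliberate — an iterated filter would be a
different (also defensible) operation, but the single pass is
order-stable and matches how hub cores are usually described. The
conventional threshold for genome-scale PPI networks is 200; the
synthetic demonstration uses 5 on its ~30-node blocks, the analogous
operating point at desk scale. Whether the degree filter is applied to
the full network before module induction or to the module-induced
subgraph is genuinely ambiguous in practice; `filter_scope` exposes both
orders (`"induced"`, the default, filters after induction).

## Louvain community detection

The community detector is written from first principles around the
weighted modularity

$$Q = \frac{1}{2m} \sum_{ij} \left( A_{ij} - \frac{k_i k_j}{2m} \right)
\delta(c_i, c_j)
= \sum_c \left[ \frac{\Sigma_{in}^c}{2m} -
\left( \frac{\Sigma_{tot}^c}{2m} \right)^2 \right],$$

where `Sigma_in` sums `A_ij` over ordered pairs inside a community and
`Sigma_tot` sums member degrees. The algorithm alternates two phases:

* **Local moving** (`local_moving_phase()`): nodes are swept in a seeded
  random order; each node moves to the neighbouring community with the
  largest strictly positive modularity gain `dQ` (ties broken toward the
  lowest community id), and sweeps repeat until one makes no move. The
  textbook gain expression applies to an isolated node; a general move is
  therefore evaluated as removal-then-insertion on the `Sigma_in` /
  `Sigma_tot` bookkeeping, which makes `dQ` equal the from-scratch
  difference `Q(after) - Q(before)` to machine precision
  (`delta_q_move()` exposes this and is tested against a naive
  double-sum oracle over a thousand random moves).
* **Aggregation** (`aggregate_graph()`): communities collapse into
  super-nodes; crossing weights sum into inter-community edges, and each
  community's internal weight `w` (internal edges plus inherited
  self-loops) is stored as a self-loop contributing `2w` to the
  super-node's degree and `w` to `m`. With this convention
  `sum(k) = 2m` still holds and modularity is preserved *exactly* under
  aggregation, which is what lets the per-level Q trajectory be
  non-decreasing by construction.

Levels repeat until a level improves Q by less than `min_gain = 1e-10`
(the convergence tolerance; modularity is bounded above by 1, so
termination is guaranteed). Final communities are relabelled `0, 1, ...`
in decreasing size order. Sweep order is the algorithm's one source of
randomness; it derives entirely from the `seed` argument, and
`deterministic = TRUE` substitutes sorted node order.

For graphs of up to 8 nodes, `brute_force_max_modularity()` enumerates
every set partition (Bell-number growth: 4140 partitions at n = 8) and
returns a global optimum. It is the independent oracle for the
optimiser's tests: the greedy Q must never exceed the exhaustive Q*, and
must attain it on disjoint-clique fixtures where the optimum is known.

## Over-representation analysis

`enrich_groups()` tests each (group, term) pair with the upper-tail
hypergeometric probability `P(X >= k)` for drawing `k` annotated genes
among `n` from a universe of `N` with `K` annotated (evaluated through
the log-space tail of the standard distribution function), then applies
Benjamini–Hochberg correction. Two conventions are configurable because
published analyses rarely state them: the **universe** defaults to the
genes of the analysed network (an "all annotated genes" universe can be
passed instead), and the **BH family** defaults to each group's own term
list (matching per-community reporting), with a global family available.
Only over-representation is tested; depletion is out of scope. Reported
adjusted p-values from any specific study depend on its annotation
version and universe and are not desk-reproducible; the package
reproduces the structure of such results, not their numbers.

## What the generators simulate

`simulate_expression()` draws counts from a negative binomial with
mean/dispersion parameterisation (`variance = mu + mu^2 / dispersion`,
stated explicitly to avoid the size/probability ambiguity). Gene `g` of
module `m` has mean `baseline_mean * exp(loading_g * e_{m,s})`, where the
planted eigengene `e_{m,s}` is the module's stage trend (defaults: one
rising, one falling, one peaked across the three stages) plus
per-(module, sample) Gaussian jitter; background genes have loading 0.
Defaults: 3 modules x 50 genes + 550 background genes, 8 samples per
stage x 3 stages, loadings Uniform(0.6, 1), dispersion 10, baseline 100,
jitter sd 1.0.

Two generator defaults deserve their rationale:

* **Jitter sd 1.0** (comparable to the trend amplitude) mirrors the
  large within-stage variability of single-embryo transcriptomes. It
  also keeps the planted eigengenes mutually distinguishable: with
  near-zero jitter the rising and falling trends are exact negatives,
  and an unsigned network provably cannot separate modules whose
  profiles differ only in sign — no detector default can fix that
  degeneracy, so the generator avoids planting it.
* **Background fraction ~79%.** When most of a small simulated universe
  is perturbed, per-sample library size tracks stage and CPM
  normalisation induces substantial correlation among "null" genes — a
  compositional artifact of a too-small universe, not a property of real
  genome-wide data. With ~20% of genes perturbed the artifact is
  negligible, matching what a genome-wide study would show.

Even so, with only 24 samples the *realized* correlation between the
rising and falling planted eigengenes occasionally drifts beyond ~0.7,
and in roughly one seed in eight those two modules merge under unsigned
defaults. This is an identifiability limit of unsigned correlation
networks at this sample size, documented rather than patched.

`simulate_ppi()` is a weighted stochastic block model (within-block edge
probability `p_in = 0.3`, between `p_out = 0.01`, blocks 60 + 60 by
default) with Uniform(0.4, 1) weights mimicking normalised STRING
confidence scores. Designated hubs receive extra within-block edges —
edges, not reweighting, so weighted and unweighted degree filters are
both exercised. `simulate_annotations()` emits GMT-compatible term sets;
planted terms draw 90% of members from one community, null terms draw
uniformly.

What the generators do **not** emulate: read-level sequencing noise,
transcript-length and GC bias, dropout structure, real annotation-graph
topology (term nesting and propagation), and the heavy-tailed degree
distributions of real PPI networks. Tests passing on these simulations
show the algorithms recover the structure they plant, under the stated
noise model — not that any particular biological claim holds.

## The synthetic demonstration pipeline

`default_synthetic_config(seed)` wires the full chain at desk scale:
3 x 60 module genes + 520 background; the interaction graph spans the
module genes with each planted module split into two 30-node blocks
(`p_in` 0.5, `p_out` 0.02), so whichever stage-tracking module the
analysis selects, its induced subgraph carries exactly two planted
communities; 60 annotation terms, 30% planted on single blocks. Analysis
parameters are scaled accordingly (top 200 genes by MAD, beta 8,
weighted-degree threshold 5). The target module is chosen as the one
whose eigengene has maximal `|r|` with the latest stage, overridable by
name. All randomness derives from the config's seeds, and rerunning the
pipeline reproduces byte-identical artifacts (timestamps aside).

Problem sizes throughout the test-suite and the acceptance script — 700
simulated genes, 120-node SBM graphs, 250 null annotation terms, 1000
randomised dQ checks, 100 aggregation pairs — were chosen so the planted
effects are comfortably detectable at the statistical power these sizes
give, while a full run completes in well under a minute.

## Numerical and degenerate-input choices

* Modularity requires `m > 0`; empty graphs and all-zero weights are
  errors, as is a brute-force request beyond 8 nodes.
* Accepted Louvain moves must improve Q by more than an internal 1e-12
  guard, so floating-point ties never cause oscillation; `min_gain`
  (1e-10) governs level convergence.
* Constant genes have undefined correlations: an error by default,
  exclusion with a warning under `drop_constant = TRUE`. Missing values
  are not handled; upstream must impute or drop.
* A degree threshold above the maximum degree yields an empty core: a
  warning at the graph level, and a clear halt (before community
  detection) in the pipeline.
* MAD ties, equal-gain Louvain moves, and equal-size modules all break
  deterministically (lexicographic id, lowest community id, original
  cluster order) so that identical inputs give identical outputs.

## Known limitations

* Unsigned networks cannot separate sign-opposed co-expression patterns;
  a signed variant is the natural extension.
* The static tree cut trades the adaptivity of dynamic cutting for
  determinism; very unbalanced module sizes may need a hand-tuned
  height.
* Module merging by eigengene similarity, blockwise computation for
  >20k genes, consensus networks, Leiden refinement, resolution
  parameters other than 1, overlapping communities, and GO-graph
  propagation are all out of scope.
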