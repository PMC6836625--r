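# nodnet

Time-series gene co-expression network analysis for nodulation biomarker
discovery.

## The problem

When legume roots are inoculated with *Rhizobium*, waves of coordinated
gene expression unfold over hours to days in the root zone where nodules
initiate. A time-course RNA-seq design — control vs. inoculated samples at
0, 12, 24, 48 and 72 h post-inoculation with three biological replicates
(30 samples) — can resolve those waves, but per-gene differential
expression alone returns hundreds of isolated hits per time point. nodnet
implements the complementary strategy: build a **condition-aware gene
co-expression network (GCN)** across all samples, partition it into
overlapping **link community modules (LCMs)**, and overlay the
per-time-point differentially expressed genes (DEGs). Modules whose genes
are *all* DEGs in the same direction at a single time point ("pure"
modules, labelled 24U, 24D, 48D, ...) are coherent, temporally specific
candidate biomarker sets.

## What the pipeline computes

1. **Preprocessing** — FPKM → log2 (zeros become missing), pairwise
   Kolmogorov–Smirnov outlier screen (flag at mean D > 0.15), quantile
   normalization.
2. **Differential expression** — per time point, genes with row sums < 50
   removed, median-of-ratios size factors, negative-binomial GLM
   (`~ condition`, log link, offsets) with a Wald test on the condition
   coefficient; Benjamini–Hochberg adjustment; DEG ⇔ padj < 0.05.
3. **Condition-aware similarity** — for every gene pair, samples are
   clustered in the 2-D expression plane with bivariate Gaussian mixtures
   (K = 1..5, selected by ICL, `min_obs = 20`); Pearson correlation is
   computed within each sample cluster, so edges may be specific to a
   subset of samples.
4. **RMT threshold** — the significance cutoff is where the eigenvalue
   nearest-neighbour spacing distribution of the thresholded similarity
   matrix transitions from Poisson statistics (modular signal) to the
   Wigner–Dyson law of the Gaussian orthogonal ensemble (noise); swept
   from 0.990 downward in 0.001 steps. Scale-free topology is summarised
   by the R² of the log–log degree-distribution fit.
5. **Link communities** — network edges are clustered by single linkage on
   the Jaccard similarity of their endpoints' inclusive neighbourhoods and
   cut at maximum partition density (0 = trees, 1 = cliques); modules keep
   ≥ 3 genes; genes may belong to several modules.
6. **Overlay** — modules composed entirely of same-direction DEGs at one
   time point are called pure (24U/24D/48D groups), tabulated with fold
   changes and adjusted p-values.
7. **Enrichment** — DAVID-style Fisher's exact (hypergeometric) test of
   module gene sets against GO/KEGG/Pfam/InterPro annotations, background
   restricted per vocabulary to annotated genes.

A synthetic-data generator (`design_spec()`, `planted_module()`,
`simulate_counts()`, `demo_experiment()`) reproduces the study design with
planted co-expression modules and planted time-point-specific effects, so
the whole pipeline is testable against known ground truth.

## Worked example

```r
library(nodnet)

# the canonical synthetic experiment: 200 genes, 30 samples, 18 planted
# modules; module 1 is tightly co-regulated and down-regulated (3 log2
# units) in inoculated samples at 24 h
exp <- demo_experiment(seed = 1)
sim <- exp$sim

gem <- counts_to_fpkm(sim$counts, sim$gene_length_bp) |>
  expression_matrix(sim$sample_meta, state = "fpkm") |>
  log2_transform() |>
  quantile_normalize()

de    <- run_de(sim$counts, sim$sample_meta)
edges <- all_pairs_similarity(gem)        # ~2 min: 19,900 GMM-clustered pairs
th    <- find_threshold(edges)
net   <- extract_network(edges, th$threshold)
lc    <- link_communities(net)
calls <- classify_modules(lc, de)

glance(de); glance(th); glance(net); glance(lc)
dplyr::filter(calls, pure)
```

Output (seed 1):

```
#> # A tibble: 1 x 5
#>   n_tests n_genes n_timepoints n_degs alpha
#>     <int>   <int>        <int>  <int> <dbl>
#> 1     991     200            5     16  0.05
#> # A tibble: 1 x 3
#>   threshold n_cutoffs_tried chi2_critical
#>       <dbl>           <int>         <dbl>
#> 1     0.823             491          98.3
#> # A tibble: 1 x 4
#>   n_nodes n_edges n_edge_records threshold
#>     <int>   <int>          <int>     <dbl>
#> 1     156     450            450     0.823
#> # A tibble: 1 x 4
#>   n_modules n_genes largest_module partition_density
#>       <int>   <int>          <int>             <dbl>
#> 1        42     111             20             0.397
#> # A tibble: 1 x 6
#>   module time_h direction pure  n_genes label
#>   <chr>   <dbl> <chr>     <lgl>   <int> <chr>
#> 1 M0003      24 down      TRUE        8 24D
```

Reading it: 16 of 200 genes are called differentially expressed somewhere
in the course; the eigenvalue-spacing sweep selects 0.823 as the
correlation cutoff (the bottom edge of the Poisson-statistics regime);
the extracted network has 156 genes and 450 edges and partitions into 42
link communities. Exactly one module is pure — all 8 of its genes are
significant *down* at 24 h — and its gene set is identical to the planted
biomarker module (`setequal(genes, exp$biomarker)` is `TRUE`; recovery
Jaccard 1.0). Plots: `autoplot(th)` shows the chi-square trace of the
threshold sweep, `plot_module_timecourse(gem, exp$biomarker)` the
per-condition means with 68% replicate bands, `plot_deg_counts(de)` the
DEG counts per time point.

The package also ships a transcription of the published pure-module group
tables from the nodulation study it mirrors:

```r
s <- module_group_summary(read_module_groups())
s$per_group
#> # A tibble: 3 x 3
#>   group n_genes n_modules
#>   <chr>   <int>     <int>
#> 1 24D        10         4
#> 2 24U         6         2
#> 3 48D        11         3
s$n_modules_total
#> [1] 9
```

Six genes in two pure up-regulated 24 h modules, ten in four down-24 h
modules, eleven in three down-48 h modules — nine pure modules in all.

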