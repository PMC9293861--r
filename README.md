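# tlromics

Multi-omics integration of TLR-stimulated enhancer and gene regulation in
dendritic cells.

Type-1 conventional dendritic cells sense microbial DNA through TLR9 (ligand:
CpG oligonucleotides) and viral double-stranded RNA through TLR3 (ligand:
poly(I:C), "pIC"). Stimulating both receptors at once does not simply add the
two responses: some genes are induced synergistically, many
interferon-stimulated genes are antagonized, and the underlying enhancer
landscape (H3K27ac) and co-repressor occupancy (NCoR1) are reorganized in a
stimulus-specific way. tlromics packages the complete desk-side analysis of
such an experiment — from count matrices and peak sets to integrated
conclusions — for computational biologists who want each step as a tested,
reusable function rather than a one-off script.

## What it computes

* **Response classes** — genes up-regulated vs unstimulated in CpG only, pIC
  only, or both (`log2FC >= 1`, `padj < 0.05`), via a Wald-style
  negative-binomial differential test on median-of-ratios-normalized counts
  (`estimate_size_factors()`, `differential_test()`,
  `classify_tlr_response()`).
* **Synergy/antagonism** — per gene, the ratio of combined-stimulation
  expression to the sum of the single-stimulation expressions,
  `R = mean(combined) / (mean(CpG) + mean(pIC))`; `R > 1.2` is synergy,
  `R < 0.5` antagonism (`synergy_antagonism()`).
* **Co-repressor binding clusters** — rule-based classification of NCoR1
  peaks into five fold-change patterns (all-stim up, combined-specific,
  pIC-specific, unchanged, down) at a 2-fold cutoff
  (`fold_enrichment_matrix()`, `classify_ncor1_clusters()`).
* **Enhancer patterns** — filtering of acetylated regions (signal sum,
  2-fold change, across-condition variability) and average-linkage
  clustering of z-scaled profiles into CpG-specific / pIC-specific / common /
  down patterns (`select_variable_regions()`, `cluster_enhancer_patterns()`).
* **Super-enhancers** — 12 kb stitching without TSS exclusion and the
  tangent-line cutoff on the scaled ranked-signal curve
  (`stitch_peaks()`, `call_super_enhancers()`).
* **Association statistics** — Fisher exact odds ratios of gene-set overlap
  against an explicit universe, and a within-chromosome permutation test for
  genomic-region overlap (`fisher_overlap()`,
  `region_overlap_permutation()`).
* **Co-expression modules** — soft-power selection, topological overlap
  matrix, static-cut module detection with eigengene merging
  (minModuleSize 30, cutHeight 0.98, merge threshold 0.15), and
  hypergeometric ranking of candidate regulators by the DEG-enrichment of
  their module targets (`pick_soft_power()`, `tom_matrix()`,
  `detect_modules()`, `rank_regulators()`).
* **Synthetic data with planted truth** — a generator that emulates the
  study design (4 conditions x 2 replicates, NB counts, archetypal peak
  patterns, coupled marks) so every stage is testable without external data
  (`simulate_tlr_dataset()`).

All user-facing functions take data frames and return tibbles, so stages
chain with the pipe; results carry `tidy()` / `glance()` methods and
`autoplot()` / `plot_*()` visualisations.

## Worked example

```r
library(tlromics)
library(dplyr)

ds  <- simulate_tlr_dataset(seed = 42)   # planted-truth dataset
res <- run_tlr_pipeline(ds)              # every stage, deterministically

glance(res$synergy)
#> # A tibble: 1 × 7
#>   n_genes n_synergy n_antagonist n_neither n_undefined upper lower
#>     <int>     <int>        <int>     <int>       <int> <dbl> <dbl>
#> 1     599        89          121       389           0   1.2   0.5

glance(res$ncor1_clusters)
#> # A tibble: 1 × 7
#>   n_peaks   n_I  n_II n_III  n_IV   n_V n_multi_rule
#>     <int> <int> <int> <int> <int> <int>        <int>
#> 1     750   129   147   138   188   148            1

res$delta_delta
#> # A tibble: 3 × 5
#>   condition        n     r ci_lo ci_hi
#>   <chr>        <int> <dbl> <dbl> <dbl>
#> 1 CpG            240 0.977 0.970 0.982
#> 2 pIC            240 0.969 0.960 0.976
#> 3 CpG_pIC_IFNg   240 0.972 0.964 0.978
```

Reading the output: of the 599 genes in an induced response class, 89 exceed
the 1.2 synergy threshold and 121 fall below the 0.5 antagonism threshold in
combined stimulation (the dataset plants 80 and 120 — the synergy margin is
only ~1 sigma at this dispersion and replicate number, so some planted
synergy genes are missed and some neutral genes cross the threshold; see the
methods vignette). The five NCoR1 clusters are recovered near their planted
sizes of 150, and one peak matches more than one raw rule, resolved by the
documented precedence. Because the generator couples the two ChIP marks, the
change in NCoR1 binding correlates with the change in H3K27ac intensity at
r ~ 0.97 across the 240 paired peaks, the integration result at the heart of
the analysis.

`autoplot(res$superenhancers)` draws the ranked-signal hockey stick with the
tangent cutoff; `plot_association_heatmap(res$association)` draws the
log-odds heatmap of response classes against binding clusters.

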