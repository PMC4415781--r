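# pairedDE

An R package for paired tumor–normal expression analysis on log2
intensity matrices that profile both mRNA and lncRNA probes — the
standard design in which each patient contributes one tumor and one
adjacent-normal sample and all inference runs on within-patient
differences. It is aimed at analysts who need the complete chain from a
normalized matrix to ranked key genes as tested, scriptable functions
rather than a point-and-click workflow.

The pipeline:

1. **Quantile normalization** with explicit tie handling, and
   PCA/Mahalanobis **sample QC** (χ²₃ rule on the first three principal
   components, pairs dropped when either member is flagged).
2. **Differential expression**: per-probe paired fits
   (β̂_g = mean difference, s²_g on f = n−1 df), empirical-Bayes
   variance shrinkage s̃²_g = (d₀s₀² + f s²_g)/(d₀ + f) with (d₀, s₀²)
   estimated by method of moments on log s², the moderated statistic
   t̃_g = β̂_g / √(s̃²_g/n) on d₀ + f df, Benjamini–Hochberg FDR, and the
   triple threshold |log₂FC| > 1, P < 0.01, FDR < 0.01, summarized by
   biotype.
3. **Gene-set over-representation** per direction: one-sided
   hypergeometric (Fisher) and Pearson χ² tests on the 2×2 table, the
   enrichment ratio (k/n)/(K/N), and a choice of FDR — BH on the Fisher
   P, or the dual-test discordance estimator 1 − N_k/T (N_k = number of
   top-T categories with Fisher P below χ² P). Plus an ontology-tree
   builder over significant terms.
4. **Networks**: the interaction (Gene-Act) graph induced on
   differential genes with a degree > 25 hub rule; a pathway graph
   linked by shared differential genes; and group-specific co-expression
   graphs (|r| ≥ 0.8, P < 0.01 across one group's samples) with degree
   and k-core key-gene ranking.
5. **qPCR concordance**: ΔΔCt fold changes (2^−ΔΔCt) and per-gene
   direction agreement against the array log2FC.

A seeded synthetic-data generator plants differential probes, enriched
gene sets, group-specific co-expression modules and interaction hubs,
so every stage is testable end to end with known ground truth and no
external downloads. See `vignettes/paired-expression-pipeline.Rmd` for
the full methods description and design rationale.

## Worked example

```r
library(pairedDE)
cfg <- pipeline_config(out_dir = "run1", seed = 1)
manifest <- run_pipeline(cfg)
cat(summarize_run(manifest), sep = "\n")
```

```
pairedDE run (version 0.1.0, seed 1)

stage simulate   probes=5000, pairs=26
stage normalize  probes=5000, samples=52
stage qc         flagged=0, pairs_kept=26
stage de         up=105, down=95
  lncRNA down: 10
  lncRNA up: 6
  mRNA down: 85
  mRNA up: 99
stage enrichment go_significant=5, pathway_significant=6
stage networks   gene_act_nodes=114, gene_act_edges=154, hubs=5, pathway_act_nodes=3, pathway_act_edges=2, coexpr_tumor_edges=113, coexpr_normal_edges=188
stage qpcr       genes=10, agreement=1, rank_cor=0.624242424242424

top differential probes (of 200):
  gene_id symbol biotype   log2fc     p_value         fdr status
1  P01940 G01940    mRNA -2.43081 6.29284e-40 3.14642e-36   down
2  P00591 G00591    mRNA -2.32441 1.81575e-37 3.07576e-34   down
3  P02447 G02447    mRNA -2.83584 1.84546e-37 3.07576e-34   down
4  P01341 G01341    mRNA -2.36564 2.78242e-37 3.47803e-34   down
5  P02198 G02198    mRNA  2.28336 3.47709e-36 3.47709e-33     up
```

Reading the output: the generator planted 200 differential probes at
±2 log2 units among 5000; the triple threshold recovers all 200
(105 up + 95 down, split across biotypes) with no false calls. Five of
the significant GO records belong to the planted DE-loaded sets, the
five planted interaction hubs exceed the degree-25 hub rule inside the
Gene-Act graph, the normal-tissue co-expression graph is denser than the
tumor graph (the planted normal-only module), and all 10 assayed genes
agree in direction between simulated qPCR and the array. Per-stage
output files (`de_table.tsv`, `enrichment_go.tsv`, `*.sif` graphs with
node attributes, `key_genes_*.tsv`, `qpcr_concordance.tsv`) land in
`out_dir`, and the manifest records md5 checksums: identical config and
seed reproduce identical bytes.

Real data enter the same way through TSV/GMT readers
(`read_expression_tsv()` with a design table, `read_gmt()`,
`read_interactions()`, `read_qpcr_table()`) by passing file paths
instead of `synth` in `pipeline_config()`.

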