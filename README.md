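# exonsplice

Differential gene expression **and** alternative splicing analysis for exon
microarrays, as one tested, reusable R pipeline.

Exon arrays probe every annotated exon of a gene with ~4 oligonucleotide
probes (an *exon-level probe set*) and collect the ~10 probe sets of a locus
into a *transcript cluster* (~40 probes per gene). That design yields two
readouts from one hybridization: conventional gene-level differential
expression, and differential exon inclusion, quantified by the **splicing
index**

```
SI(exon e, sample s) = log2( exon-level intensity / gene-level intensity of e's cluster )
```

Group differences in SI flag exons whose inclusion changes even when total
gene output does not — the dominant signal in studies such as neonatal
hypoplastic left heart syndrome (HLHS) myocardium, where only 3–4% of
differentially spliced genes are also differentially expressed.

The package is aimed at analysts who want the classic exon-array workflow as
auditable, scriptable functions rather than a chain of GUI tools:

* **Detection filtering** — GC-matched empirical DABG p-values (add-one
  rank rule, Fisher combination per probe set), the two-step detection
  cascade (≥50% of samples in some group at exon level; strictly >50% of
  member exons at cluster level), and reconciliation against the gene-level
  output, with the full count ladder logged.
* **RMA-style preprocessing** — exponential-plus-normal convolution
  background correction, quantile normalization, and median-polish
  summarization at exon and gene level.
* **Statistics** — row-wise one-way ANOVA, pooled / Welch /
  empirical-Bayes-moderated t-tests, Benjamini–Hochberg FDR per test
  family, and the compound selection rule (ANOVA FDR < 0.05, pairwise FDR
  < 0.05, symmetric fold > 1.5).
* **Downstream** — Venn arithmetic and spliced-vs-expressed overlap
  summaries, median centering + centered-correlation average-linkage
  clustering (newick export), PCA, and hypergeometric over-representation
  analysis against the detectable-gene universe (GMT input).
* **Synthetic data with known truth** — a probe-level generator with
  GC-dependent background, non-expressed genes, whole-gene spikes and
  mean-balanced splicing spikes, so every stage is testable end to end.

## Worked example

Simulate a 50-gene exon-array study with the 6/5/5 three-group design, two
whole-gene spikes (log2 fold ±1.5 in the case group) and two balanced
splicing spikes (log2 fold 2, gene-level mean untouched), then run the whole
pipeline:

```r
library(exonsplice)

cfg <- pipeline_config(sim = list(
  n_clusters = 50, seed = 20,
  de_spikes     = data.frame(cluster_id = c("TC0003", "TC0011"),
                             group = "HLHS_RV", log2_fold = c(1.5, -1.5)),
  splice_spikes = data.frame(probeset_id = c("TC0020_PS04", "TC0031_PS07"),
                             group = "HLHS_RV", log2_fold = 2)))
run <- run_pipeline(cfg)
run
#> exonsplice_run
#>   detection ladder: input=500 -> step1=402 -> step2=400 -> reconciled=400 (40 detectable clusters)
#>   HLHS_RV_vs_Control_RV: 2 genes DE, 2 exons spliced
#>   HLHS_RV_vs_Control_LV: 2 genes DE, 2 exons spliced
#>   overlap HLHS_RV_vs_Control_RV: 0/2 spliced genes also DE (0%)
#>   overlap HLHS_RV_vs_Control_LV: 0/2 spliced genes also DE (0%)
#>   truth HLHS_RV_vs_Control_RV: splice sens 1.00 prec 1.00 | DE sens 1.00 prec 1.00
#>   truth HLHS_RV_vs_Control_LV: splice sens 1.00 prec 1.00 | DE sens 1.00 prec 1.00
```

Reading the output: 500 exon probe sets went in; 402 passed step-1 DABG
detection, 400 survived the cluster-level step 2, and all 400 reconciled
against the gene-level matrix, leaving 40 detectable clusters (the 10
non-expressed genes were filtered). Both spiked genes and both spiked exons
were recovered exactly, and — the point of the balanced spike design — the
two spliced genes are *not* called differentially expressed, so the
spliced∩DE overlap is 0.

The per-gene table carries fold changes in the case/control orientation
(values < 1 are down-regulated in the case group):

```r
run$gene_table[match(c("TC0003", "TC0011"), run$gene_table$feature_id),
               c("anova_fdr", "fc_HLHS_RV_vs_Control_RV", "fdr_HLHS_RV_vs_Control_RV")]
#>   anova_fdr fc_HLHS_RV_vs_Control_RV fdr_HLHS_RV_vs_Control_RV
#> 3         0                   2.7304                         0
#> 7         0                   0.3695                         0
```

`run_pipeline(cfg, out_dir = "out/")` additionally writes every stage table
as TSV (matrices, detection report, differential tables, selections, newick
trees, PCA scores) plus a `manifest.json` echoing all parameters, the count
ladder and per-file md5 hashes; reruns with the same configuration are
byte-identical. A thin command-line wrapper over the same functions lives at
`inst/scripts/exonsplice.R` (`simulate` and `run-all` subcommands, YAML
config). Individual stages are exported too — `compute_dabg()`,
`rma_summarize()`, `splicing_index()`, `build_differential_table()`,
`select_features()`, `venn2()`, `average_linkage()`, `pca()`,
`hypergeometric_ora()`, `qpcr_fold_change()` — see the methods vignette
(`vignettes/exonsplice-methods.Rmd`) for the models and conventions.

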