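---
title: "Methods: exon-array expression and splicing analysis with exonsplice"
author: "exonsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-array expression and splicing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonsplice)
options(exonsplice.verbose = FALSE)
```

## The problem

Exon microarrays interrogate every annotated exon of a gene with a small
group of oligonucleotide probes (an *exon-level probe set*, typically 4
probes), and aggregate all probe sets of a gene locus into a *transcript
cluster* (roughly 40 probes per gene). This design supports two analyses in
the same hybridization: conventional gene-level differential expression, and
differential exon inclusion (alternative splicing), read out as exon signal
that moves relative to its own gene. The motivating application is the
comparison of right-ventricle myocardium from neonates with hypoplastic left
heart syndrome (HLHS) against the right and left ventricles of non-diseased
controls — a three-group design with 6/5/5 samples — where most transcript
changes turn out to be splicing changes that leave total gene expression
unchanged.

`exonsplice` implements that analysis end to end: detection filtering,
RMA-style preprocessing, splicing-index statistics, compound significance
selection, set comparison, clustering/ordination, and over-representation
analysis — plus a synthetic exon-array generator with known truth so every
stage is testable without array data.

## Detection filtering

Non-expressed genes are removed before any hypothesis testing, in three
steps driven by detection-above-background (DABG) p-values.

**DABG.** Each probe is compared to genomic background probes with matched
GC content (4 equal-width GC bins on $[0,1]$ by default). The per-probe
empirical p-value uses add-one smoothing,
$p = (1 + \#\{\text{background} \ge x\}) / (1 + N_\text{bin})$, so it lies
in $(0,1]$ and is invariant under any joint monotone transform of target and
background intensities. Probe p-values are combined per probe set with
Fisher's method ($-2\sum\log p_i \sim \chi^2_{2k}$). The vendor's exact
probe-set combination rule is not published; Fisher's method is our
documented choice and is exercised against a closed-form oracle in the
tests.

**Step 1 (exon probe sets).** A probe set is *detected* when, in at least
one treatment group, at least half of that group's samples have DABG
p < 0.05. We read the filtration rule as "p < 0.05 in **at least** 50% of
the samples of at least one group": a rule demanding detection in *fewer*
than half the samples would mark essentially everything detected and
contradicts the purpose of the filter. The comparator is configurable
(`>=` by default, strict `>` available).

**Step 2 (transcript clusters).** A cluster is detected when *strictly more
than* 50% of its member probe sets pass step 1; a cluster with exactly half
its exons detected is not called. This comparator is also configurable.

**Reconciliation.** Exons of undetected clusters are dropped, and exons
whose cluster is absent from the gene-level summarized output are dropped
too (summarization can lose clusters, e.g. when their probes are filtered
upstream); the detectable clusters are those present in the gene-level
matrix with at least one detectable exon. The counts at every stage (input
→ step 1 → step 2 → reconciled) are logged and are monotone non-increasing
by construction.

## RMA-style preprocessing

Summaries are produced in the canonical RMA order: convolution background
correction per array, quantile normalization across arrays at probe level,
log2, then median-polish summarization.

**Background correction.** Observed intensity is modeled as exponential
signal plus normal background, $X = S + B$, $S \sim \text{Exp}(\alpha)$,
$B \sim N(\mu, \sigma^2)$; the corrected value is the closed-form
$E[S \mid X]$, which is strictly positive. Parameters are estimated per
array by the standard mode-based heuristic with a two-pass mode search: the
global density mode of a right-skewed intensity distribution overshoots the
background peak, so the mode is re-estimated on the sub-mode points; σ comes
from the left half-normal tail (doubled mean square) and α from the mean
exceedance above the mode. The conditional expectation is verified against
a numeric-quadrature oracle to 1e-6 relative.

**Quantile normalization.** Every column is mapped onto the mean quantile
profile; ties within a column receive the mean of the reference values their
ranks span, which makes the transform idempotent (checked to 1e-12).

**Median polish.** Each probe-set (exon level) or cluster (gene level)
block of the log2 probe matrix is decomposed into overall + row (probe
affinity) + column (sample) effects by Tukey's median polish; the per-sample
summary is overall + column effect. Probe affinities are swept into row
effects, so between-sample contrasts of the summaries are exactly invariant
to per-probe shifts. Defaults are the classic 10 sweeps with an absolute
L1-change tolerance of 0.01; single-probe blocks pass through unchanged.
Gene-level summaries use *all* core probes of a cluster, not only detected
exons, matching a workflow that summarizes before filtering.

## Differential statistics

**Splicing index.** For exon $e$ with owning cluster $c$ in sample $s$,
$\mathrm{SI}_{e,s} = \log_2 \text{exon}_{e,s} - \log_2 \text{gene}_{c,s}$:
the exon's abundance relative to its own gene. Whole-gene expression changes
cancel; group differences in SI indicate differential exon inclusion.

**Tests.** One-way fixed-effects ANOVA across the three groups and
two-group t-tests for the named comparisons (case-RV vs each control), on
gene-level log2 intensities and on splicing indexes. The default t is the
pooled-variance statistic (consistent with the ANOVA family; the $F = t^2$
identity is a test oracle); Welch and an empirical-Bayes moderated variant
are available. The moderated variant shrinks each feature's pooled variance
toward a prior $s_0^2$ with prior df $d_0$ estimated by moment matching of
the across-feature variance distribution against $s^2/s_0^2 \sim F(d, d_0)$
— the published analysis used a moderated framework but printed no
moderation parameters, so neither variant claims to regenerate the printed
tables. Zero-variance features are flagged degenerate and excluded from FDR
families with a logged count.

**FDR.** Benjamini–Hochberg step-up, computed separately within each family
(gene-level ANOVA, exon-level ANOVA, and each pairwise test at each level),
mirroring per-test FDR columns in published result tables.

**Selection.** A feature is called for a comparison when ANOVA FDR < 0.05,
that comparison's t-test FDR < 0.05, and the fold change exceeds 1.5-fold
*symmetrically*, i.e. $\max(\mathrm{FC}, 1/\mathrm{FC}) > 1.5$ — published
tables count genes at 0.3-fold as changed, so sub-unity folds must qualify.
Fold changes are reported as-is in the case/control orientation (0.3 means
about 3.3-fold down). At the exon level the fold is
$2^{|\Delta \overline{\mathrm{SI}}|}$, a documented choice since no exon
fold formula is published. For clustering displays the same significance
gates apply but with 2-fold (gene) and 5-fold (splicing-index) thresholds.

## Set comparison, clustering, PCA, enrichment

Venn arithmetic runs on selected-id sets; exon selections are collapsed to
their owning clusters before spliced-versus-expressed comparisons, since
those are made at gene granularity. Overlap percentages are rounded to the
nearest integer, ties away from zero.

Clustering follows the classic two-way heatmap workflow: log2 data (or SI)
median-centered per feature, centered correlation ($1 - r$) as the
dissimilarity, UPGMA/average linkage, both sample and feature axes
supported; trees serialize to newick. Leaf order is the deterministic order
of the agglomeration (no optimal-leaf-ordering). PCA operates on the
feature-centered sample matrix via SVD; by default it is run on gene-level
expression (an SI ordination can be run by passing the SI matrix).

Over-representation uses the one-sided hypergeometric tail
$P[X \ge k]$ for $X \sim \text{Hypergeom}(N, K, n)$ with BH adjustment
across sets. The universe is the *detectable* genes, not the genome — the
universe choice changes p-values materially and is tested against an
enumeration oracle. Sets with fewer than 3 in-universe members are skipped
(configurable). Under-representation and rank-based (GSEA-style) statistics
are out of scope.

## The synthetic-data generator

`simulate_exon_array()` emits linear-scale probe intensities

$$ 2^{\,\beta_0 + a_c + b_p + \phi_i + g_{c(\cdot)} + \varepsilon} + B $$

with baseline $\beta_0$ (default 8 log2 units), cluster abundance
$a_c \sim N(0, 1.5^2)$, probe-set offset $b_p \sim N(0, 0.5^2)$, fixed
per-probe affinity $\phi_i \sim N(0, 0.7^2)$ shared across samples (exactly
the structure median polish must remove), per-observation noise
$\varepsilon \sim N(0, 0.25^2)$, and log-normal background $B$ whose log2
mean is $4 + 2\cdot\mathrm{GC}$ (sd 0.5) — giving DABG a genuine GC effect.
Defaults mirror the target study design: 10 exon probe sets of 4 probes per
cluster (≈40 probes per gene, 4 per exon) and groups of 6/5/5. Noise
magnitudes are not published for the real arrays; the values above were
chosen once as realistic for modern expression arrays and are module
parameters, not claims about any particular dataset. A fraction of clusters
(default 20%) is non-expressed and emits background only.

Two spike types define the truth: whole-gene spikes add a log2 fold to one
group's cluster effect; splicing spikes shift one exon probe set by
$+f$ and its $m-1$ siblings by $-f/(m-1)$, leaving the cluster's mean log2
effect — the gene-level truth — unchanged. This balanced design makes
"spliced but not differentially expressed" a testable truth category, the
dominant observation in the motivating study (only 3–4% of spliced genes
were also differentially expressed). An unbalanced mode exists behind the
`balanced` flag. Spiked clusters are kept expressed; a configuration whose
non-expressed fraction cannot be honored without silencing a spiked cluster
is rejected.

All draws derive from the single mandatory seed in a fixed order, so runs
are bit-reproducible; rerunning the pipeline with the same configuration
yields byte-identical output tables (manifest hashes are compared in the
tests).

### What passing tests do and do not show

The generator emulates the data model the pipeline assumes: log-normal
signal, additive GC-dependent background, fixed probe affinities, balanced
group structure. It deliberately omits scanner and spatial artifacts, batch
effects, probe cross-hybridization beyond the annotation flag,
heavy-tailed noise, and clinical covariates (age, gestational age). Monte
Carlo results below therefore validate the *machinery* — estimator
consistency, FDR control, spike recovery under the stated noise — not the
biology of any real dataset, whose gene lists additionally depend on the
arrays themselves.

## Numerical choices and degenerate inputs

- DABG p-values are clamped away from exact 0 at the double minimum; empty
  GC bins and zero-probe sets are hard errors.
- Background correction errors on (near-)constant arrays; corrected values
  are guarded at $2^{-20}$ against roundoff.
- Median polish: 10 sweeps / 0.01 L1 tolerance by default, configurable;
  tested to 1e-9 against an independent implementation at tight tolerance.
- Degenerate statistics: identical groups give $t = 0, p = 1$; zero residual
  variance with unequal means gives $p = 0$ flagged degenerate; constant
  features are undefined and excluded from FDR with a logged count.
- UPGMA ties break deterministically (lowest-index pair, via the stock
  agglomeration); duplicate rows merge first at height 0.
- PCA requests beyond the matrix rank are truncated with a warning.

## Problem sizes used in validation

The packaged Monte-Carlo suites run at 50 clusters × 10 exon probe sets × 4
probes × 16 samples (8,000 target probes, 1,000 background probes): null
FDR control over 20 replicates, balanced splice-spike recovery (log2 fold 2,
noise sd 0.25) over 50 replicates, fold-estimate consistency over 20–50
replicates. These sizes give stable Monte-Carlo estimates for the properties
checked while keeping the default test run fast; all of them scale linearly
if larger runs are wanted.

## Known limitations

- Fold estimates for signals near the background level are attenuated
  toward 1 — the familiar RMA shrinkage — so consistency holds for genes
  expressed comfortably above background (which is what the detection
  filter retains); spike-recovery results are reported after detection.
- The moderated t's moment-matching prior is simpler than the full
  empirical-Bayes machinery of dedicated packages; it is provided as a
  fidelity option, with the pooled t as the reproducible default.
- Groups are treated as independent; the paired structure of control RV/LV
  samples from the same subjects is not modeled, and no covariate
  adjustment or permutation testing is provided.
- Three-set Venn counts are computed but not drawn; no interactive heatmap
  rendering.
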