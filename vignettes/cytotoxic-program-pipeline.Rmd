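---
title: "Dissecting the cytotoxic CD4 T-cell program: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the cytotoxic CD4 T-cell program: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxomics)
```

## The scientific question

Human CD4 T cells can acquire perforin-dependent cytotoxic activity along
the Th1 differentiation pathway, ending in a terminally differentiated
CD28&minus; cytotoxic population (CD4~CTX~) whose transcriptional program
overlaps the CD8 lineage. The analysis this package implements asks two
linked questions on paired multi-donor array data:

1. which genes are *specifically* expressed by a T-cell subset, and are the
   cytotoxic-subset signatures enriched in CD8-lineage comparisons
   (gene set enrichment analysis, GSEA); and
2. is the promoter DNA methylation of those signature genes selectively
   lost in the cytotoxic subsets (450K-style differential methylation
   integrated with the expression signatures by pre-ranked GSEA on
   delta-beta values)?

Around this core sit the bench-assay calculators used to validate single
genes: delta-delta-Cp qPCR fold changes against the EEF1A1 housekeeping
gene, ChIP-qPCR percent-input with pan-H3 normalization, percent specific
lysis from active-caspase-3 positivity, single-cell co-expression
proportions anchored on perforin, and per-CpG summaries of a 34-site
bisulphite pyrosequencing tiling of the *PRF1* promoter.

## Subset-specific signatures: the min/max rule

A probe is specific for a test subset versus a reference subset when its
*minimum* over the test replicates strictly exceeds the *maximum* over the
reference replicates. Before this rule is applied, probes whose
linear-scale max/min ratio across **all** samples of the study falls below
1.2 are discarded as unregulated. Two readings of "ratio of expression
values" exist for log2-stored data; we take the linear-scale reading
(log2 range &ge; log2 1.2 &approx; 0.263) because a ratio of log2 values is
dimensionally meaningless, and expose the alternative through
`regulation_filter(scale = "log2-input")`. Surviving probes are flattened
to unique gene symbols: a gene enters the signature if *any* of its probes
is specific. Ties (minimum equal to maximum) are not specific.

With zero measurement noise the rule is exact — every planted gene and
nothing else — which is the calibration the end-to-end tests rely on; with
noise it trades sensitivity for an essentially empty false-positive
region, because a single aberrant replicate vetoes a probe.

## The GSEA engine

`gsea_run()` is a complete re-implementation of weighted
Kolmogorov–Smirnov GSEA:

* **Ranking metric.** `rank_by_metric()` scores each gene by the
  difference of class means of log2 values — a log2 fold change, the
  appropriate metric for log-scale data. Multi-probe genes are collapsed
  first; the default representative is the maximum-variance probe
  (configurable: `mean`, `max_mean`), since one score per identifier is
  required by the walk. Ties in ranking order are broken by identifier
  (radix order), making every ranking platform- and locale-independent.
* **Enrichment score.** Walking the ranked list, hits increment the
  running sum by |score|^p normalized over the set's members (p = 1 by
  default; p = 0 gives the unweighted KS statistic) and misses decrement
  by 1/(N&nbsp;&minus;&nbsp;N~hit~); the ES is the signed maximum
  deviation. An exact tie between the positive and negative extremes —
  possible because the steps are rational numbers — resolves to the
  positive side, with a 1e-12 guard so floating-point accumulation cannot
  flip the choice.
* **Null model.** Gene-set permutation: the null for a set of size k is
  the ES of `n_perm` (default 1000) uniformly drawn k-subsets of the
  ranked universe. With 4–6 samples per class a phenotype permutation
  would be underpowered, and the class structure never enters the null.
  Each set's permutations are drawn from a sub-stream seeded by a hash of
  the set *name*, so results are identical whatever the evaluation order.
* **Normalization and significance.** Nominal p is the same-sign tail
  fraction of the null; NES divides the ES by the mean |null ES| of
  matching sign; the FDR compares the observed NES distribution with the
  pooled per-set-normalized permutation NES distribution, sign-stratified
  and capped at 1. FDR &lt; 0.25 is the conventional significance rule.
  Calibration is part of the test suite: under random gene sets the
  nominal p is uniform and the FDR rule's null call rate stays near its
  nominal level.

## The methylation pipeline

Beta-values are methylated-signal fractions M/(U&nbsp;+&nbsp;M); zero
total signal yields a missing value. M-values are logit2 of beta, computed
after clipping beta to [1e-6, 1&nbsp;&minus;&nbsp;1e-6] so fully
(un)methylated probes stay finite. Probe filtering removes probes failing
the detection p &lt; 0.05 threshold — by default in *any* sample, the
strictest reading, with `all`/`fraction` rules exposed — and
cross-reactive probes, while retaining SNP-overlapping probes, which do
not confound within-donor comparisons.

**Type-I/II peak correction.** The two Infinium chemistries have
different dynamic ranges; type-II beta distributions are compressed. Per
sample we locate the unmethylated (M &lt; 0) and methylated (M &gt; 0)
density modes of each design type (kernel density, Silverman bandwidth)
and linearly rescale type-II M-values on each side of zero so their modes
align with the type-I modes. The correction is monotone within a sample's
type-II values, leaves type-I untouched, cannot push beta across 0 or 1,
and degrades gracefully: a sample whose type distribution lacks a mode on
one side is left uncorrected with a warning.

**Differential methylation.** Per probe, a two-sided paired t-test on
M-values across donor pairs (pairing key: donor label), plus a
delta-beta as the difference of group *median* beta-values, stored signed
(test&nbsp;&minus;&nbsp;reference) because the integration step ranks by
it. A probe is called differentially methylated when p &lt; 1e-4 **and**
|delta-beta| &gt; 0.1. Zero-variance difference vectors are reported as
t = 0, p = 1 when the mean difference is zero (identical groups), and
p = 0 otherwise, rather than NaN.

The p &lt; 1e-4 threshold with five donor pairs is extremely strict:
|t| must exceed 15.5 at 4 degrees of freedom. The suite therefore checks
two properties computed by independent simulation oracles: the type-I
rate at p &lt; 1e-4 on null data stays at its nominal level over 2&times;10^5
probe-tests, and the call probability for a planted delta-beta of 0.3
with beta-sd 0.03 sits in the 0.5–0.7 band that the non-central t
distribution dictates (the non-centrality, &approx;16, barely clears the
threshold, so certainty is impossible at this noise level; near-certain
calls require beta-sd &approx; 0.01).

## Cross-omics integration

Expression signatures are converted to methylation probe sets by mapping
every gene to its promoter probes — TSS1500, TSS200, 5'UTR and 1st exon,
the promoter definition used throughout — and taking the union; unmapped
genes are reported, never dropped silently. Pre-ranked GSEA then runs on
probes ordered by signed delta-beta (descending), so a *negative*
enrichment means the signature's promoters concentrate among probes
hypomethylated in the test subset. Ranking uses delta-beta of medians,
not t statistics, matching how the barcode rankings are defined. To give
the permutation FDR a realistic background, size-matched random decoy
probe sets (default 100) accompany the converted set, playing the role a
large external catalog plays in array-scale runs; promoter-only
conversion is the default with `promoter_only = FALSE` for sensitivity
analysis.

## What the synthetic generator emulates — and what it does not

`make_study()` reproduces the statistical skeleton the pipeline assumes:
five donors crossed with six subsets (naive CD4, central-memory Th1,
CD28+ effector-memory Th1, CD4~CTX~, naive CD8, CD8~CTX~), paired by
donor; log2-normal expression (baseline N(8, 1.5), measurement noise
sd 0.25, a per-donor/probe shift sd 0.15 shared across subsets — the
component paired tests remove); a 50-gene cytotoxic signature shifted
+2 log2 units in both cytotoxic subsets; bimodal beta baselines (modes
near 0.1 and 0.85, as on real arrays) with concentration 150
(beta-sd &approx; 0.03–0.04), planted promoter hypomethylation of
&minus;0.3 for the signature genes in the cytotoxic subsets; a 30/70
type-I/II probe split with type-II betas linearly compressed toward 0.5
by 0.2 (the simplest bias the peak correction must undo); detection
failures (~0.5% of probes), ~1% cross-reactive and ~2% SNP-overlap flags.
Every planted gene is guaranteed at least one promoter probe. All draws
descend from a single integer seed.

It does **not** emulate probe-level genomic annotation beyond the fields
the pipeline consumes, spatial correlation of neighbouring CpGs, batch or
chip effects, intensity-dependent noise, or realistic gene–probe
multiplicity. Passing tests therefore demonstrate the *algorithms* behave
as specified under the assumed noise model, not that the pipeline is
robust to artefacts these simplifications exclude.

## Numerical and design choices

* Variance filtering uses the unbiased (n&minus;1) variance of
  log2-normalized values with a strict "&gt;" at the 0.01 default.
* Quantile normalization delegates to the standard microarray
  implementation (ties receive the mean of the candidate quantile
  values); it is idempotent and is cross-checked in the tests against an
  independent rank-and-average oracle.
* Sample clustering uses 1&nbsp;&minus;&nbsp;Pearson correlation between
  sample profiles with Ward.D2 linkage; cluster support is the plain
  bootstrap probability (fraction of probe-resampled trees containing the
  same leaf bipartition) over 1000 replicates by default. Multiscale
  (approximately unbiased) p-values are deliberately out of scope; BP is
  sufficient for property testing and has no tuning parameters.
* Fixture and permutation reproducibility: every stochastic routine takes
  an explicit seed; sub-streams are derived by integer hashing, and all
  derived seeds stay below 2^31.
* Problem sizes in the shipped tests and drivers — 2000 expression and
  4000 methylation probes for end-to-end runs, 2&times;10^5 probe-tests
  for the null-rate check, 500–1000 permutations, 100 decoy sets, 20-seed
  recovery loops — were chosen as the smallest scales at which the
  planted effects and the calibration properties are measured with
  comfortable margins.

## Known limitations

* The min/max signature rule has no error model; with many replicates or
  heavy-tailed noise it becomes conservative to the point of emptiness.
  It is kept because it is the derivation rule the signatures are defined
  by.
* The FDR of permutation GSEA is a point estimate from pooled nulls; with
  very few gene sets it is close to the nominal p and should be read
  accordingly (the drivers always add decoy sets).
* The peak correction assumes both methylation modes are populated in
  every sample and type; sorted, highly homogeneous cell populations
  satisfy this, single-cell-derived or tumour data may not.
* The paired t at p &lt; 1e-4 with five pairs is intentionally strict;
  users with weaker planted effects should expect the 0.5–0.7 power
  regime quantified above, and interpret call counts, not call
  completeness.
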