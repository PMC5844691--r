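# ctxomics

Cross-omics analysis of the cytotoxic CD4 T-cell program: an R package
plus a scripted analysis that links subset-specific gene expression to
promoter DNA methylation in paired multi-donor T-cell subset studies.

Human CD4 T cells can acquire perforin-dependent cytotoxicity along the
Th1 differentiation pathway. The pipeline here asks (i) which genes are
specific to each T-cell subset, (ii) whether the cytotoxic-subset
signatures are enriched in CD8-lineage comparisons, and (iii) whether the
promoters of those signature genes are selectively demethylated — the
epigenetic fingerprint of a de-repressed cytotoxic program.

## What's inside

| Module | Core method |
|---|---|
| signatures | min/max rule: a probe is subset-specific if min(test replicates) > max(reference replicates), after excluding probes with linear max/min ratio < 1.2 across all samples |
| GSEA | weighted Kolmogorov–Smirnov running score: hits add \|s\|^p / Σ\|s\|^p, misses subtract 1/(N−N_hit); ES = signed max deviation; gene-set permutation null (1000 perms), NES = ES / mean\|null ES\| (same sign), sign-stratified pooled-null FDR, significance at FDR < 0.25 |
| methylome | β = M/(U+M); M-value = log2(β/(1−β)); detection/cross-reactive probe filtering (SNP probes kept); per-sample two-mode peak correction of the type-I/II bias; paired t-test on M-values + Δβ of medians; call = p < 1e-4 ∧ \|Δβ\| > 0.1 |
| integration | signature genes → promoter probes (TSS1500/TSS200/5'UTR/1st exon) → pre-ranked GSEA on the signed Δβ ranking; NES < 0 ⇔ promoter hypomethylation in the test subset |
| assays | ΔΔCp qPCR fold change (EEF1A1 reference), ChIP %input = 100·2^(adjusted input Cp − IP Cp) with pan-H3 normalization, % lysis, single-cell co-expression, 34-CpG pyrosequencing summaries |
| synthetic data | seeded generator of the full paired study (5 donors × 6 subsets) with planted signature genes and coupled promoter hypomethylation, so every stage is testable without external data |

## Worked example

```r
library(ctxomics)

study <- make_study(study_spec(seed = 101))

# subset-specific signature, min/max rule
sig <- derive_geneset(study$expression, "CD4_CTX", "CD4_naive")
length(sig$genes)
#> [1] 54

# promoter methylation of the signature, integrated by pre-ranked GSEA
res <- integrate_methylation(sig, study$methylation,
                             "CD4_CTX", "CD4_naive",
                             gsea_config(n_perm = 1000, seed = 606))
res[, c("size", "ES", "NES", "FDR")]
#>   size         ES       NES FDR
#> 1  125 -0.9989783 -2.497308   0
```

The signature's 54 genes map to 125 promoter probes; their enrichment
score on the Δβ ranking is −0.999 (they sit almost entirely at the
hypomethylated extreme), NES −2.50, FDR 0 against 100 size-matched decoy
sets — the planted coupling between upregulation and promoter
demethylation, recovered end to end.

The full analysis is scripted under `analysis/` (run in order):
`01_simulate.R` writes the synthetic study; `02` clusters and ordinates
the expression samples (the cytotoxic clade reaches bootstrap support
1.0); `03` derives the signatures (100% planted-gene recovery);
`04` runs permutation GSEA with control and decoy sets; `05` runs the
methylation chain (49/49 differential calls hypomethylated in CD4_CTX);
`06` integrates the two; `07` exercises the bench-assay calculators.
Outputs land in `results/`.

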