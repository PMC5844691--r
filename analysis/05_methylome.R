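#!/usr/bin/env Rscript
# 450K-style methylation pipeline: beta from raw signals, probe filtering,
# peak-based type-I/II correction, paired differential methylation.

suppressPackageStartupMessages(library(ctxomics))

study <- make_study(study_spec(seed = 101))
meth <- study$methylation

# recompute beta from the raw signals to exercise the full chain
beta <- compute_beta(meth$raw_M, meth$raw_U)
cat("max |beta(raw) - stored beta|:",
    signif(max(abs(beta - meth$beta), na.rm = TRUE), 3), "\n")

filt <- filter_probes(meth)
rm_counts <- attr(filt, "removed")
cat("probes removed:", rm_counts["detection"], "failing detection,",
    rm_counts["cross_reactive"], "cross-reactive;",
    nrow(filt$beta), "retained\n")

corr <- peak_correct(filt)

dm <- dm_test(corr, "CD4_CTX", "CD4_naive")
dir.create("results", showWarnings = FALSE)
write.table(dm, "results/dm_cd4ctx_vs_cd4naive.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("differentially methylated (p<1e-4 & |delta-beta|>0.1):",
    sum(dm$called), "probes;",
    sum(dm$called & dm$delta_beta < 0), "hypomethylated in CD4_CTX\n")
planted <- intersect(study$truth$hypo_probes, dm$probe_id)
cat(sprintf("planted promoter probes with |delta-beta| > 0.1: %.0f%%\n",
            100 * mean(abs(dm$delta_beta[match(planted, dm$probe_id)]) > 0.1)))

# promoter-region composition of a planted gene, RUNX3-heatmap style
g <- study$truth$signature_genes$CD4_CTX[1]
cat("promoter-region composition of", g, ":\n")
print(round(region_proportions(corr, g), 2))
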