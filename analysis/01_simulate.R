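#!/usr/bin/env Rscript
# Simulate the paired six-subset T-cell study (5 donors, expression +
# 450K-style methylation with a planted cytotoxic signature) and write it
# to results/study/ through the package's format writers.

suppressPackageStartupMessages(library(ctxomics))

spec <- study_spec(seed = 101)
study <- make_study(spec)

dir.create("results", showWarnings = FALSE)
write_study(study, "results/study")
# downstream scripts regenerate the study from the same seed instead of
# re-reading these files; the TSVs are the shareable export

cat("Simulated study (seed", spec$seed, "):\n")
print(study$expression)
print(study$methylation)
cat("planted signature genes :", length(study$truth$signature_genes$CD4_CTX),
    "(upregulated in", paste(names(study$truth$signature_genes),
                             collapse = ", "), ")\n")
cat("planted hypomethylated promoter probes:",
    length(study$truth$hypo_probes), "\n")
cat("written to results/study/ (expression.tsv, beta.tsv, design.tsv, ...)\n")
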