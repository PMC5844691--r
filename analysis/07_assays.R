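#!/usr/bin/env Rscript
# Bench-assay calculators on their seeded fixtures: ddCp qPCR fold change,
# ChIP percent-input with H3 normalization, cytotoxicity, single-cell
# co-expression, pyrosequencing region summaries.

suppressPackageStartupMessages(library(ctxomics))
dir.create("results", showWarnings = FALSE)

q <- make_qpcr_fixture(707)
dd <- ddcp_fold_change(q, "PRF1", "EEF1A1", "CD4_naive")
cat("qPCR PRF1 log2 fold change vs naive CD4 (median [IQR] across donors):\n")
print(dd$summary, row.names = FALSE)
write.csv(dd$per_sample, "results/qpcr_prf1.csv", row.names = FALSE)

ch <- make_chip_fixture(707)
ci <- chip_percent_input(ch, "H3K4me3")
by_region <- tapply(ci$normalized, ci$region, median)
cat(sprintf("\nChIP H3K4me3 (H3-normalized %%input): promoter/control ratio %.2f (planted %.1f)\n",
            by_region["promoter"] / by_region["minus15kb"],
            attr(ch, "truth")$fold_enrichment))
write.csv(ci, "results/chip_h3k4me3.csv", row.names = FALSE)

cat(sprintf("\ncytotoxicity example: 35%% caspase3+ with effectors, 5%% control -> %.0f%% lysis\n",
            percent_lysis(35, 5)))

sc <- make_singlecell_fixture(707)
co <- coexpression_proportions(sc, "PRF1", c("RUNX3", "TBX21", "ZBTB7B",
                                             "EOMES"),
                               housekeeping = "EEF1A1")
cat("\nsingle-cell PRF1+ proportion by subset:\n")
print(round(co$anchor_proportion, 2))
cat("co-expression among PRF1+ cells (double-positive / PRF1+):\n")
print(round(co$coexpression, 2))

py <- make_pyroseq_fixture(707)
ps <- pyroseq_summary(py, group = "subset")
cat("\npyrosequencing: median methylation % of the intermediate region (CpG 16-28):\n")
inter <- ps$per_region[ps$per_region$region == "intermediate", ]
print(setNames(round(inter$median, 1), inter$group))
write.csv(ps$per_cpg, "results/pyroseq_per_cpg.csv", row.names = FALSE)
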