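#!/usr/bin/env Rscript
# Unsupervised structure of the expression data: variance filtering,
# bootstrapped Pearson/Ward.D2 clustering of samples, PCA.

suppressPackageStartupMessages(library(ctxomics))

study <- make_study(study_spec(seed = 101))
expr <- study$expression

filt <- variance_filter(expr, threshold = 0.01)
cat("variance filter (>0.01):", attr(filt, "n_probes"), "probes,",
    attr(filt, "n_genes"), "unique genes retained\n")

bd <- bootstrap_cluster(filt, n_boot = 200, seed = 202)
keys <- vapply(bd$clusters, function(m) paste(sort(m), collapse = ";"),
               character(1))
tree_tab <- data.frame(cluster = keys, bp = bd$bp)
dir.create("results", showWarnings = FALSE)
write.table(tree_tab, "results/cluster_support.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
# the two cytotoxic subsets should form a well-supported clade: report the
# support of the bipartition separating CTX samples from the rest
ctx <- sort(filt$design$sample_id[filt$design$subset %in%
                                    c("CD4_CTX", "CD8_CTX")])
ctx_key <- paste(ctx, collapse = ";")
cat("bootstrap support of the cytotoxic-subset clade:",
    if (ctx_key %in% keys) tree_tab$bp[keys == ctx_key] else "not a clade",
    "\n")

p <- expr_pca(filt)
write_matrix_tsv(t(p$scores), "results/pca_scores.tsv",
                 id_column = "component")
cat("PCA: first three components explain",
    paste0(round(100 * p$var_explained[1:3], 1), "%", collapse = ", "),
    "of the variance\n")
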