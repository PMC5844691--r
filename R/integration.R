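#' Convert an expression gene set to a methylation probe set
#'
#' Maps every gene of the set to its (promoter) methylation probes and
#' takes the union. Genes contributing no probe are reported in
#' `source_genes_unmapped`, never silently dropped; a set in which no gene
#' maps at all is an error (unusable for enrichment).
#'
#' @param geneset A [gene_set].
#' @param study A [methylation_study] providing the probe annotation.
#' @param promoter_only If `TRUE` (default) only promoter-region probes
#'   (TSS1500, TSS200, 5'UTR, 1st exon) are used; otherwise all probes of
#'   the gene.
#' @return List of class `probe_set`: `name`, `probes`,
#'   `source_genes_mapped` (count), `source_genes_unmapped` (genes).
#' @export
genes_to_probes <- function(geneset, study, promoter_only = TRUE) {
  stopifnot(inherits(geneset, "gene_set"),
            inherits(study, "methylation_study"))
  ann <- study$annotation
  present <- ann$probe_id %in% rownames(study$beta)
  ok_region <- if (promoter_only) ann$region %in% PROMOTER_REGIONS
               else rep(TRUE, nrow(ann))
  probes_of <- function(g)
    ann$probe_id[present & ok_region & ann$gene == g]
  per_gene <- lapply(geneset$genes, probes_of)
  mapped <- lengths(per_gene) > 0
  if (!any(mapped))
    stop_fmt("gene set '%s': no gene maps to a %sprobe (unusable)",
             geneset$name, if (promoter_only) "promoter " else "")
  probes <- unique(unlist(per_gene[mapped]))
  structure(list(name = geneset$name, probes = probes,
                 source_genes_mapped = sum(mapped),
                 source_genes_unmapped = geneset$genes[!mapped]),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("<probe_set>", x$name, "-", length(x$probes), "probes from",
      x$source_genes_mapped, "genes (",
      length(x$source_genes_unmapped), "unmapped )\n")
  invisible(x)
}

#' Rank methylation probes by signed delta-beta
#'
#' Orders probes by the signed difference of group median beta-values
#' (test minus reference), descending: the most hypermethylated probes in
#' the test subset come first, the most hypomethylated last. This is the
#' pre-ranked input of the methylation-expression integration.
#'
#' @param study A [methylation_study] (donor-paired subsets).
#' @param test_subset,reference_subset Subset labels.
#' @return A [ranked_list] of probe IDs scored by delta-beta.
#' @export
rank_delta_beta <- function(study, test_subset, reference_subset) {
  dm <- dm_test(study, test_subset, reference_subset)
  ranked_list(dm$probe_id, dm$delta_beta)
}

#' Methylation-expression integration by pre-ranked GSEA
#'
#' Tests whether the promoter methylation probes of an expression-derived
#' gene set concentrate at one end of the delta-beta ranking between two
#' subsets. The gene set is converted to a promoter probe set, a
#' configurable number of size-matched random decoy probe sets is added
#' for a robust permutation FDR, and pre-ranked GSEA is run on the signed
#' delta-beta ranking (test minus reference, descending). A negative
#' enrichment (NES < 0) means the set's promoter probes are
#' hypomethylated in the test subset.
#'
#' @param geneset A [gene_set] (expression signature).
#' @param study A [methylation_study].
#' @param test_subset,reference_subset Subset labels.
#' @param config A [gsea_config].
#' @param promoter_only Restrict conversion to promoter probes (default
#'   `TRUE`).
#' @param n_decoys Random size-matched decoy probe sets (default 100).
#' @return One-row `enrichment_results` data frame for the converted set
#'   (attributes: `probe_set`, `all_results` incl. decoys).
#' @export
integrate_methylation <- function(geneset, study, test_subset,
                                  reference_subset,
                                  config = gsea_config(),
                                  promoter_only = TRUE, n_decoys = 100) {
  ps <- genes_to_probes(geneset, study, promoter_only = promoter_only)
  ranked <- rank_delta_beta(study, test_subset, reference_subset)
  sets <- list(gene_set(ps$name, ps$probes,
                        description = "converted probe set"))
  if (n_decoys > 0) {
    k <- length(ps$probes)
    universe <- ranked$id
    decoys <- with_seed(derive_seed(config$seed, 999983L), {
      lapply(seq_len(n_decoys), function(i)
        gene_set(sprintf("decoy_%03d", i), sample(universe, min(k, length(universe) - 1L)),
                 description = "size-matched random decoy"))
    })
    sets <- c(sets, decoys)
  }
  res <- gsea_preranked(ranked, sets, config)
  out <- res[1L, , drop = FALSE]
  attr(out, "probe_set") <- ps
  attr(out, "all_results") <- res
  out
}
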