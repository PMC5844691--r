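#' Regulation pre-filter for signature derivation
#'
#' Excludes probes whose linear-scale max/min expression ratio across all
#' samples of the study falls below `ratio` (default 1.2): such probes are
#' considered not regulated in any subset. On the log2 scale this keeps
#' probes with range >= log2(ratio). With `scale = "log2-input"` the ratio
#' is instead taken directly on the stored values (the alternative literal
#' reading).
#'
#' @param study An [expression_study] (log2 values).
#' @param ratio Minimal max/min ratio to call a probe regulated; must be
#'   > 1.
#' @param scale `"linear"` (default): ratio of 2^values; `"log2-input"`:
#'   ratio of the stored values themselves.
#' @return Character vector of retained probe IDs.
#' @export
regulation_filter <- function(study, ratio = 1.2,
                              scale = c("linear", "log2-input")) {
  stopifnot(inherits(study, "expression_study"))
  scale <- match.arg(scale)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 1)
    stop_fmt("ratio must be a single number > 1")
  x <- study$values
  rng_ok <- if (scale == "linear") {
    apply(x, 1L, max) - apply(x, 1L, min) >= log2(ratio)
  } else {
    mx <- apply(x, 1L, max); mn <- apply(x, 1L, min)
    mx / mn >= ratio
  }
  rownames(x)[rng_ok]
}

#' Derive a subset-specific gene set by the min/max rule
#'
#' A probe is specific for the test subset if its minimal expression across
#' the test replicates is strictly higher than its maximal expression
#' across the reference replicates (ties are not specific). Probes failing
#' the regulation pre-filter are excluded first; surviving probes are
#' flattened to unique gene symbols (a gene enters the set if any of its
#' probes is specific).
#'
#' @param study An [expression_study].
#' @param test_subset,reference_subset Subset labels from the design.
#' @param ratio Regulation pre-filter ratio (see [regulation_filter()]);
#'   `NULL` disables the pre-filter.
#' @return A [gene_set] named `<test>_vs_<reference>`; empty if no probe is
#'   specific (not an error). Attribute `probes` lists the specific probes.
#' @export
derive_geneset <- function(study, test_subset, reference_subset,
                           ratio = 1.2) {
  stopifnot(inherits(study, "expression_study"))
  ti <- subset_columns(study$design, test_subset)
  ri <- subset_columns(study$design, reference_subset)
  x <- study$values
  if (!is.null(ratio)) {
    keep <- regulation_filter(study, ratio)
    x <- x[rownames(x) %in% keep, , drop = FALSE]
  }
  if (nrow(x)) {
    tmin <- apply(x[, ti, drop = FALSE], 1L, min)
    rmax <- apply(x[, ri, drop = FALSE], 1L, max)
    specific <- rownames(x)[tmin > rmax]
  } else specific <- character(0)
  genes <- study$probe_gene$gene[
    match(specific, study$probe_gene$probe_id)]
  genes <- unique(genes[!is.na(genes)])
  out <- gene_set(paste0(test_subset, "_vs_", reference_subset),
                  genes,
                  description = sprintf("min/max specific probes (%d)",
                                        length(specific)))
  attr(out, "probes") <- specific
  out
}
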