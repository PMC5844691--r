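#' Study containers
#'
#' `expression_study()` holds a probes x samples log2 expression matrix with
#' a probe-to-gene map and a sample design (subset and donor labels, the
#' paired structure every downstream comparison relies on).
#' `methylation_study()` holds a probes x samples beta-value matrix in
#' \[0,1\] with per-probe annotation (gene, Infinium promoter-region class,
#' type I/II design, cross-reactive and SNP-overlap flags) and optionally
#' the raw methylated/unmethylated signals and detection p-values.
#'
#' @param values Numeric probes x samples matrix (log2 scale).
#' @param probe_gene Data frame with columns `probe_id`, `gene`.
#' @param design Data frame with columns `sample_id`, `subset`, `donor`;
#'   `sample_id` must match the matrix column names one-to-one.
#' @return An object of class `expression_study` or `methylation_study`.
#' @export
expression_study <- function(values, probe_gene, design) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_fmt("expression values must be numeric")
  design <- check_design(design, colnames(values))
  probe_gene <- check_probe_gene(probe_gene, rownames(values))
  structure(list(values = values, probe_gene = probe_gene, design = design),
            class = "expression_study")
}

#' @rdname expression_study
#' @param beta Numeric probes x samples matrix of beta-values in \[0,1\].
#' @param annotation Data frame with columns `probe_id`, `gene`, `region`
#'   (one of TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR, intergenic),
#'   `type` ("I" or "II"), `cross_reactive`, `snp_overlap` (logical).
#' @param raw_M,raw_U Optional raw signal matrices (>= 0), same shape as
#'   `beta`.
#' @param detection_p Optional detection p-value matrix in \[0,1\].
#' @export
methylation_study <- function(beta, annotation, design,
                              raw_M = NULL, raw_U = NULL,
                              detection_p = NULL) {
  beta <- as.matrix(beta)
  if (!is.numeric(beta)) stop_fmt("beta values must be numeric")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_fmt("beta values must lie in [0,1]")
  design <- check_design(design, colnames(beta))
  annotation <- check_annotation(annotation, rownames(beta))
  for (m in list(raw_M = raw_M, raw_U = raw_U, detection_p = detection_p)) {
    if (!is.null(m) && !identical(dim(as.matrix(m)), dim(beta)))
      stop_fmt("signal/detection matrices must match beta dimensions")
  }
  structure(list(beta = beta, annotation = annotation, design = design,
                 raw_M = raw_M, raw_U = raw_U, detection_p = detection_p),
            class = "methylation_study")
}

REGION_CLASSES <- c("TSS1500", "TSS200", "5'UTR", "1stExon",
                    "Body", "3'UTR", "intergenic")
PROMOTER_REGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon")

check_design <- function(design, sample_ids) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample_id", "subset", "donor")
  if (!all(need %in% names(design)))
    stop_fmt("design must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop_fmt("duplicate sample_id in design: %s",
             design$sample_id[duplicated(design$sample_id)][1L])
  if (anyDuplicated(design[c("subset", "donor")]))
    stop_fmt("(subset, donor) pairs must be unique in design")
  if (is.null(sample_ids)) stop_fmt("matrix must have sample column names")
  if (!setequal(design$sample_id, sample_ids) ||
      length(design$sample_id) != length(sample_ids))
    stop_fmt("design sample_id must match matrix columns one-to-one")
  design[match(sample_ids, design$sample_id), , drop = FALSE]
}

check_probe_gene <- function(probe_gene, probe_ids) {
  probe_gene <- as.data.frame(probe_gene, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene") %in% names(probe_gene)))
    stop_fmt("probe_gene must have columns probe_id, gene")
  if (is.null(probe_ids)) stop_fmt("matrix must have probe row names")
  missing <- setdiff(probe_ids, probe_gene$probe_id)
  if (length(missing))
    warning(sprintf("%d probes without gene annotation (first: %s)",
                    length(missing), missing[1L]), call. = FALSE)
  probe_gene
}

check_annotation <- function(annotation, probe_ids) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "region", "type")
  if (!all(need %in% names(annotation)))
    stop_fmt("annotation must have columns: %s", paste(need, collapse = ", "))
  if (!all(probe_ids %in% annotation$probe_id))
    stop_fmt("annotation must cover all probes in the beta matrix")
  if (!all(annotation$region %in% REGION_CLASSES))
    stop_fmt("unknown region class: %s",
             setdiff(annotation$region, REGION_CLASSES)[1L])
  if (!all(annotation$type %in% c("I", "II")))
    stop_fmt("probe design type must be 'I' or 'II'")
  if (is.null(annotation$cross_reactive)) annotation$cross_reactive <- FALSE
  if (is.null(annotation$snp_overlap)) annotation$snp_overlap <- FALSE
  annotation
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study>", nrow(x$values), "probes x", ncol(x$values),
      "samples;", length(unique(x$design$subset)), "subsets,",
      length(unique(x$design$donor)), "donors\n")
  invisible(x)
}

#' @export
print.methylation_study <- function(x, ...) {
  cat("<methylation_study>", nrow(x$beta), "probes x", ncol(x$beta),
      "samples;", sum(x$annotation$type == "II"), "type-II probes\n")
  invisible(x)
}

# columns of a study matrix belonging to one subset, ordered by donor label
subset_columns <- function(design, subset) {
  idx <- which(design$subset == subset)
  if (!length(idx)) stop_fmt("unknown subset label: %s", subset)
  idx[order(design$donor[idx], method = "radix")]
}

# check complete donor pairing between two subsets; returns the donor-aligned
# column indices (test, reference)
paired_columns <- function(design, test_subset, reference_subset) {
  ti <- subset_columns(design, test_subset)
  ri <- subset_columns(design, reference_subset)
  td <- design$donor[ti]; rd <- design$donor[ri]
  miss <- c(setdiff(td, rd), setdiff(rd, td))
  if (length(miss))
    stop_fmt("subsets are not donor-paired; donors missing a sample: %s",
             paste(sort(unique(miss)), collapse = ", "))
  list(test = ti, reference = ri[match(td, rd)])
}
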