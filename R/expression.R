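#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same value distribution: each
#' column's sorted values are replaced by the row-wise mean of all sorted
#' columns, with tied values receiving the mean of the candidate quantile
#' values. Delegates to [limma::normalizeQuantiles()] (ties averaged), the
#' standard microarray implementation. Idempotent.
#'
#' @param raw Numeric probes x samples matrix (>= 2 samples).
#' @return Normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop_fmt("expression matrix must be numeric")
  if (ncol(raw) < 2L)
    stop_fmt("quantile normalization needs >= 2 samples, got %d", ncol(raw))
  if (anyNA(raw)) stop_fmt("missing values not supported")
  out <- limma::normalizeQuantiles(raw, ties = TRUE)
  dimnames(out) <- dimnames(raw)
  out
}

#' Filter probes by expression variance
#'
#' Retains probes whose sample variance (unbiased, n-1 denominator) of the
#' log2-normalized values is strictly greater than `threshold`. The
#' retained probe count and the count of unique genes they map to are
#' attached as attributes (the scale on which array-wide summaries such as
#' "14,372 probes / 11,200 genes" are reported).
#'
#' @param study An [expression_study] (normalized).
#' @param threshold Variance cutoff (default 0.01); must be >= 0.
#' @return The filtered [expression_study] with attributes `n_probes` and
#'   `n_genes`.
#' @export
variance_filter <- function(study, threshold = 0.01) {
  stopifnot(inherits(study, "expression_study"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop_fmt("threshold must be a single number >= 0")
  v <- row_vars(study$values)
  keep <- v > threshold
  out <- expression_study(study$values[keep, , drop = FALSE],
                          study$probe_gene, study$design)
  kept_genes <- study$probe_gene$gene[
    match(rownames(out$values), study$probe_gene$probe_id)]
  attr(out, "n_probes") <- sum(keep)
  attr(out, "n_genes") <- length(unique(kept_genes[!is.na(kept_genes)]))
  out
}

# unbiased row variances without apply() overhead
row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1)
}

#' Bootstrap hierarchical clustering of samples
#'
#' Agglomerates samples with Ward.D2 linkage on the Pearson correlation
#' distance (1 - r between sample expression profiles). Cluster support is
#' assessed by resampling probes with replacement `n_boot` times and
#' recording, for every internal node of the original tree, the fraction of
#' replicate trees containing the same sample bipartition (plain bootstrap
#' probability, BP).
#'
#' @param study An [expression_study] with >= 3 samples and >= 2 probes.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @return List of class `boot_dendrogram`: `hclust` (the tree), `clusters`
#'   (leaf sets of the internal nodes) and `bp` (their bootstrap
#'   probabilities in \[0,1\]).
#' @export
bootstrap_cluster <- function(study, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(study, "expression_study"))
  n_boot <- check_count(n_boot, "n_boot")
  x <- study$values
  if (ncol(x) < 3L) stop_fmt("need >= 3 samples to cluster")
  if (nrow(x) < 2L) stop_fmt("need >= 2 probes to cluster")
  hc <- hclust_pearson_ward(x)
  ref <- merge_clusters(hc)
  ref_keys <- vapply(ref, cluster_key, character(1))
  hits <- numeric(length(ref_keys))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(x), nrow(x), replace = TRUE)
      bc <- tryCatch(hclust_pearson_ward(x[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(bc)) next
      keys <- vapply(merge_clusters(bc), cluster_key, character(1))
      hits <- hits + as.numeric(ref_keys %in% keys)
    }
  })
  structure(list(hclust = hc, clusters = ref, bp = hits / n_boot),
            class = "boot_dendrogram")
}

hclust_pearson_ward <- function(x) {
  r <- stats::cor(x)
  if (anyNA(r)) stop_fmt("undefined correlation (constant sample profile)")
  stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
}

# leaf-label sets below each internal node of an hclust tree
merge_clusters <- function(hc) {
  labs <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  n <- nrow(hc$merge)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    members <- unlist(lapply(hc$merge[i, ], function(j)
      if (j < 0) labs[-j] else out[[j]]))
    out[[i]] <- members
  }
  out
}

cluster_key <- function(members) paste(sort(members), collapse = "\r")

#' @export
print.boot_dendrogram <- function(x, ...) {
  cat("<boot_dendrogram>", length(x$hclust$labels), "samples;",
      "node BP:", paste(format(x$bp, digits = 2), collapse = " "), "\n")
  invisible(x)
}

#' Principal component analysis of samples
#'
#' PCA of the probe-centered expression matrix; samples are observations.
#'
#' @param study An [expression_study] with >= 2 samples.
#' @return List of class `expr_pca`: `scores` (samples x components),
#'   `sdev`, and `var_explained` (fractions, non-increasing).
#' @export
expr_pca <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$values) < 2L) stop_fmt("PCA needs >= 2 samples")
  pc <- stats::prcomp(t(study$values), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, sdev = pc$sdev, var_explained = ve,
                 rotation = pc$rotation, center = pc$center),
            class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  cat("<expr_pca>", nrow(x$scores), "samples; PC1-3 variance:",
      paste0(round(100 * x$var_explained[1:min(3, length(x$var_explained))],
                   1), "%", collapse = ", "), "\n")
  invisible(x)
}
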