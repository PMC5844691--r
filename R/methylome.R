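#' Beta-values from raw Infinium signals
#'
#' beta = M / (U + M), the methylated fraction of total signal, computed
#' elementwise. Cells with zero total signal become `NA` (no measurement).
#'
#' @param raw_M,raw_U Non-negative methylated / unmethylated signal
#'   matrices of identical shape.
#' @return Beta-value matrix in \[0,1\].
#' @export
compute_beta <- function(raw_M, raw_U) {
  raw_M <- as.matrix(raw_M); raw_U <- as.matrix(raw_U)
  if (!identical(dim(raw_M), dim(raw_U)))
    stop_fmt("signal matrices must have identical dimensions")
  if (any(raw_M < 0, na.rm = TRUE) || any(raw_U < 0, na.rm = TRUE))
    stop_fmt("raw signals must be >= 0")
  tot <- raw_M + raw_U
  beta <- raw_M / tot
  beta[tot == 0] <- NA_real_
  beta
}

#' M-values (logit2 of beta)
#'
#' M = log2(beta / (1 - beta)). Beta-values are clipped to
#' \[1e-6, 1 - 1e-6\] first so M stays finite at fully (un)methylated
#' probes.
#'
#' @param beta Beta-value matrix or vector in \[0,1\].
#' @return M-value matrix of the same shape.
#' @export
m_values <- function(beta) {
  b <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  log2(b / (1 - b))
}

#' Filter methylation probes by detection quality and annotation flags
#'
#' Removes probes that fail the detection p-value threshold and probes
#' flagged cross-reactive; probes overlapping SNPs are kept (SNPs are not
#' an important confounder in within-donor comparisons). The removal
#' counts by reason are attached as attribute `removed`.
#'
#' @param study A [methylation_study] with `detection_p` present.
#' @param detection_threshold Detection p-value cutoff (default 0.05).
#' @param detection_rule `"any"` (default): drop a probe if any sample
#'   fails; `"all"`: drop only if all samples fail; `"fraction"`: drop if
#'   more than `max_fail_fraction` of samples fail.
#' @param max_fail_fraction Used with `detection_rule = "fraction"`.
#' @return Filtered [methylation_study] with attribute
#'   `removed = c(detection = , cross_reactive = )`.
#' @export
filter_probes <- function(study, detection_threshold = 0.05,
                          detection_rule = c("any", "all", "fraction"),
                          max_fail_fraction = 0.1) {
  stopifnot(inherits(study, "methylation_study"))
  detection_rule <- match.arg(detection_rule)
  if (is.null(study$detection_p))
    stop_fmt("filter_probes needs detection p-values")
  fails <- study$detection_p >= detection_threshold
  bad_det <- switch(detection_rule,
                    any = rowSums(fails) > 0,
                    all = rowSums(fails) == ncol(fails),
                    fraction = rowMeans(fails) > max_fail_fraction)
  ann <- study$annotation[match(rownames(study$beta),
                                study$annotation$probe_id), ]
  bad_cr <- ann$cross_reactive
  keep <- !(bad_det | bad_cr)
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  out <- methylation_study(study$beta[keep, , drop = FALSE],
                           study$annotation, study$design,
                           raw_M = sub(study$raw_M),
                           raw_U = sub(study$raw_U),
                           detection_p = sub(study$detection_p))
  attr(out, "removed") <- c(detection = sum(bad_det),
                            cross_reactive = sum(bad_cr & !bad_det))
  out
}

#' Peak-based correction of the Infinium type-I/type-II bias
#'
#' Type-II probes have a compressed dynamic range relative to type-I
#' probes. Per sample, the unmethylated (M < 0) and methylated (M > 0)
#' density modes of each design type are located by kernel density
#' estimation (Silverman bandwidth), and type-II M-values are linearly
#' rescaled on each side of zero so their modes align with the type-I
#' modes; values are then mapped back to the beta scale. Type-I values are
#' unchanged, the correction is monotone within each sample's type-II
#' values, and beta-values never cross 0 or 1. A sample in which either
#' type lacks a mode on one side is left uncorrected with a warning.
#'
#' @param study A [methylation_study] with type annotation.
#' @return Corrected [methylation_study].
#' @export
peak_correct <- function(study) {
  stopifnot(inherits(study, "methylation_study"))
  ann <- study$annotation[match(rownames(study$beta),
                                study$annotation$probe_id), ]
  is2 <- ann$type == "II"
  if (!any(is2)) return(study)
  beta <- study$beta
  M <- m_values(beta)
  for (j in seq_len(ncol(M))) {
    p1 <- density_peaks(M[!is2, j])
    p2 <- density_peaks(M[is2, j])
    if (anyNA(c(p1, p2))) {
      warning(sprintf("sample '%s': unimodal type distribution, left uncorrected",
                      colnames(M)[j]), call. = FALSE)
      next
    }
    m2 <- M[is2, j]
    scaled <- ifelse(m2 >= 0, m2 * (p1["meth"] / p2["meth"]),
                     m2 * (p1["unmeth"] / p2["unmeth"]))
    beta[is2, j] <- 2^scaled / (1 + 2^scaled)
  }
  methylation_study(beta, study$annotation, study$design,
                    raw_M = study$raw_M, raw_U = study$raw_U,
                    detection_p = study$detection_p)
}

# unmethylated (most prominent mode at M<0) and methylated (M>0) peak
# positions of an M-value vector; NA if a side has no mode
density_peaks <- function(m) {
  if (length(m) < 10L) return(c(unmeth = NA_real_, meth = NA_real_))
  d <- stats::density(m, bw = "nrd0")
  loc <- which(diff(sign(diff(d$y))) == -2) + 1L
  px <- d$x[loc]; py <- d$y[loc]
  pick <- function(side) {
    sel <- if (side < 0) px < 0 else px > 0
    if (!any(sel)) NA_real_ else px[sel][which.max(py[sel])]
  }
  c(unmeth = pick(-1), meth = pick(1))
}

#' Paired differential methylation test
#'
#' For every probe: a two-sided paired t-test on M-values across donor
#' pairs between the test and reference subsets, and the delta-beta as the
#' difference of group median beta-values (test minus reference, stored
#' signed). A probe is called differentially methylated when
#' p < `p_threshold` AND |delta-beta| > `delta_threshold` (defaults 1e-4
#' and 0.1). Probes with zero-variance differences are reported with t = 0
#' and p = 1 when the mean difference is 0, and p = 0 otherwise.
#'
#' @param study A [methylation_study]; both subsets must be donor-paired
#'   with >= 3 pairs.
#' @param test_subset,reference_subset Subset labels.
#' @param p_threshold,delta_threshold Call thresholds.
#' @return Data frame of class `dm_result`: `probe_id`, `delta_beta`,
#'   `t_statistic`, `p_value`, `called`.
#' @export
dm_test <- function(study, test_subset, reference_subset,
                    p_threshold = 1e-4, delta_threshold = 0.1) {
  stopifnot(inherits(study, "methylation_study"))
  pc <- paired_columns(study$design, test_subset, reference_subset)
  n <- length(pc$test)
  if (n < 3L) stop_fmt("need >= 3 donor pairs, got %d", n)
  Mt <- m_values(study$beta[, pc$test, drop = FALSE])
  Mr <- m_values(study$beta[, pc$reference, drop = FALSE])
  D <- Mt - Mr
  dbar <- rowMeans(D)
  sd_d <- sqrt(pmax(rowSums((D - dbar)^2), 0) / (n - 1))
  tt <- dbar / (sd_d / sqrt(n))
  degen <- sd_d == 0
  tt[degen & dbar == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  p[degen & dbar == 0] <- 1
  p[degen & dbar != 0] <- 0
  med_t <- apply(study$beta[, pc$test, drop = FALSE], 1L, stats::median)
  med_r <- apply(study$beta[, pc$reference, drop = FALSE], 1L,
                 stats::median)
  db <- med_t - med_r
  out <- data.frame(probe_id = rownames(study$beta), delta_beta = db,
                    t_statistic = tt, p_value = p,
                    called = p < p_threshold & abs(db) > delta_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("dm_result", "data.frame")
  out
}

#' Promoter probes of a gene
#'
#' Returns the methylation probes annotated to `gene` whose region class
#' belongs to the promoter (TSS1500, TSS200, 5'UTR, 1st exon). Unknown
#' genes give an empty vector.
#'
#' @param study A [methylation_study].
#' @param gene Gene symbol.
#' @return Character vector of probe IDs.
#' @export
promoter_probes <- function(study, gene) {
  stopifnot(inherits(study, "methylation_study"))
  ann <- study$annotation
  ann$probe_id[ann$gene == gene & ann$region %in% PROMOTER_REGIONS &
                 ann$probe_id %in% rownames(study$beta)]
}

#' Promoter-region composition of a gene's probes
#'
#' Counting helper: the proportion of a gene's promoter probes in each
#' promoter region class (e.g. the share located in the distal promoter,
#' TSS1500).
#'
#' @param study A [methylation_study].
#' @param gene Gene symbol.
#' @return Named numeric vector of proportions over the promoter classes.
#' @export
region_proportions <- function(study, gene) {
  probes <- promoter_probes(study, gene)
  ann <- study$annotation
  reg <- ann$region[match(probes, ann$probe_id)]
  tab <- table(factor(reg, levels = PROMOTER_REGIONS))
  if (length(probes) == 0)
    return(stats::setNames(rep(NA_real_, 4), PROMOTER_REGIONS))
  stats::setNames(as.numeric(tab) / length(probes), PROMOTER_REGIONS)
}
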