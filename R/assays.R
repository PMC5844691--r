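#' Delta-delta-Cp relative qPCR quantification
#'
#' Per sample: delta-Cp = Cp(target) - Cp(reference housekeeping gene);
#' delta-delta-Cp = delta-Cp(sample) - delta-Cp(calibrator sample of the
#' same donor, from the calibrator subset); log2 fold change =
#' -delta-delta-Cp; fold change = 2^(-delta-delta-Cp). Technical
#' replicates are averaged per (sample, gene) first. Summaries across
#' donors are the median and interquartile range per subset, the
#' convention for reporting lineage-wise expression.
#'
#' @param table Cp table: columns `sample_id`, `donor`, `subset`, `gene`,
#'   `cp` (and optionally `replicate`).
#' @param target_gene Gene to quantify.
#' @param reference_gene Housekeeping reference (default `"EEF1A1"`).
#' @param calibrator_subset Subset serving as the per-donor calibrator.
#' @return List of class `ddcp_result`: `per_sample` (data frame with
#'   `log2_fc`, `fold_change`) and `summary` (per-subset median and IQR of
#'   log2 fold change).
#' @export
ddcp_fold_change <- function(table, target_gene,
                             reference_gene = "EEF1A1",
                             calibrator_subset) {
  need <- c("sample_id", "donor", "subset", "gene", "cp")
  if (!all(need %in% names(table)))
    stop_fmt("Cp table must have columns: %s", paste(need, collapse = ", "))
  cp <- stats::aggregate(cp ~ sample_id + donor + subset + gene,
                         data = table, FUN = mean)
  wide <- function(g) {
    sub <- cp[cp$gene == g, c("sample_id", "donor", "subset", "cp")]
    names(sub)[4] <- g
    sub
  }
  tg <- wide(target_gene); rg <- wide(reference_gene)
  m <- merge(tg, rg[, c("sample_id", reference_gene)], by = "sample_id",
             all.x = TRUE)
  if (anyNA(m[[reference_gene]]))
    stop_fmt("missing reference gene '%s' Cp for sample '%s'",
             reference_gene, m$sample_id[is.na(m[[reference_gene]])][1L])
  if (anyNA(m[[target_gene]]))
    stop_fmt("missing target gene '%s' Cp", target_gene)
  m$delta_cp <- m[[target_gene]] - m[[reference_gene]]
  cal <- m[m$subset == calibrator_subset, c("donor", "delta_cp")]
  if (!nrow(cal)) stop_fmt("no calibrator samples in subset '%s'",
                           calibrator_subset)
  m$ddcp <- m$delta_cp - cal$delta_cp[match(m$donor, cal$donor)]
  if (anyNA(m$ddcp))
    stop_fmt("donor '%s' has no calibrator sample",
             m$donor[is.na(m$ddcp)][1L])
  m$log2_fc <- -m$ddcp
  m$fold_change <- 2^m$log2_fc
  per_sample <- m[, c("sample_id", "donor", "subset", "delta_cp", "ddcp",
                      "log2_fc", "fold_change")]
  summ <- do.call(rbind, lapply(split(per_sample, per_sample$subset),
    function(d) data.frame(subset = d$subset[1L],
                           median_log2_fc = stats::median(d$log2_fc),
                           iqr_log2_fc = stats::IQR(d$log2_fc),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(per_sample = per_sample, summary = summ),
            class = "ddcp_result")
}

#' ChIP-qPCR percent input with pan-H3 normalization
#'
#' Percent input per region and antibody:
#' adjusted input Cp = Cp(input) - log2(1 / input_fraction) (dilution
#' correction for the input aliquot), then
#' \%input = 100 x 2^(adjusted input Cp - Cp(IP)). The reported enrichment
#' is \%input(target) / \%input(pan-H3) per region (`mode = "ratio"`,
#' default, the arithmetic equivalent of normalizing by the delta-Cp of
#' the H3 IP); `mode = "subtractive"` instead reports
#' \%input(target) computed after subtracting the H3 delta-Cp.
#'
#' @param table Cp table: columns `region`, `antibody`, `cp` and optional
#'   grouping columns (e.g. `donor`); the `antibody` column must contain
#'   `"input"`, the target antibody and `"H3"` rows per region.
#' @param ip_antibody Target antibody label.
#' @param input_fraction Fraction of the IP reaction used as input
#'   (default 0.01, i.e. 1\%).
#' @param mode H3 normalization mode (see above).
#' @return Data frame: per (group, region) `pct_input` (target),
#'   `pct_input_h3`, `normalized` (H3-normalized enrichment).
#' @export
chip_percent_input <- function(table, ip_antibody,
                               input_fraction = 0.01,
                               mode = c("ratio", "subtractive")) {
  mode <- match.arg(mode)
  need <- c("region", "antibody", "cp")
  if (!all(need %in% names(table)))
    stop_fmt("ChIP table must have columns: %s", paste(need, collapse = ", "))
  if (input_fraction <= 0 || input_fraction > 1)
    stop_fmt("input_fraction must lie in (0, 1]")
  group_cols <- setdiff(names(table), c("antibody", "cp"))
  cp <- stats::aggregate(table$cp,
                         by = c(table[group_cols],
                                list(antibody = table$antibody)),
                         FUN = mean)
  names(cp)[ncol(cp)] <- "cp"
  key <- interaction(cp[setdiff(group_cols, character(0))], drop = TRUE)
  out <- do.call(rbind, lapply(split(cp, key), function(d) {
    get_cp <- function(ab) {
      v <- d$cp[d$antibody == ab]
      if (!length(v)) stop_fmt("missing '%s' row for region '%s'", ab,
                               d$region[1L])
      v[1L]
    }
    adj <- get_cp("input") - log2(1 / input_fraction)
    pct_t <- 100 * 2^(adj - get_cp(ip_antibody))
    pct_h3 <- 100 * 2^(adj - get_cp("H3"))
    norm <- if (mode == "ratio") pct_t / pct_h3 else
      100 * 2^(adj - (get_cp(ip_antibody) - (get_cp("H3") - adj)))
    cbind(d[1L, setdiff(group_cols, character(0)), drop = FALSE],
          data.frame(pct_input = pct_t, pct_input_h3 = pct_h3,
                     normalized = norm))
  }))
  rownames(out) <- NULL
  out
}

#' Percent specific lysis from active-caspase-3 positivity
#'
#' Lysis = \% caspase-3-positive target cells in effector wells minus the
#' \% in control wells (targets without effectors), floored at 0 — a
#' negative difference has no biological meaning and triggers a warning.
#' Vectorized over effector/target ratios.
#'
#' @param caspase3_pos_with_effectors,caspase3_pos_control Percentages in
#'   \[0,100\].
#' @return Percent lysis, same length as the inputs.
#' @export
percent_lysis <- function(caspase3_pos_with_effectors,
                          caspase3_pos_control) {
  e <- caspase3_pos_with_effectors; ctl <- caspase3_pos_control
  if (any(e < 0 | e > 100) || any(ctl < 0 | ctl > 100))
    stop_fmt("caspase-3 positivity must lie in [0, 100]")
  d <- e - ctl
  if (any(d < 0))
    warning("effector wells below control; lysis floored at 0",
            call. = FALSE)
  pmax(d, 0)
}

#' Single-cell co-expression proportions
#'
#' Per subset: the proportion of cells positive for the anchor gene
#' (anchor+/total), and for each partner gene the proportion of
#' anchor-positive cells co-expressing it (double-positive / anchor+),
#' the heat-map-ready co-expression matrix. A gene is positive in a cell
#' when its expression exceeds `threshold` (limit of detection). Cells
#' failing the housekeeping QC cutoff or the IQR outlier fence on the
#' housekeeping gene are excluded first. Subsets with zero anchor-positive
#' cells get `NA` (undefined) partner proportions, never 0.
#'
#' @param table Cells x genes data frame with a `subset` column and
#'   numeric gene columns.
#' @param anchor_gene Anchor gene (default `"PRF1"`).
#' @param partner_genes Partner gene columns.
#' @param threshold Positivity threshold on the expression scale
#'   (default 0: any detected expression).
#' @param housekeeping Optional housekeeping gene column for QC.
#' @param hk_min Minimal housekeeping expression for a cell to pass QC.
#' @param iqr_fence Tukey fence multiplier for housekeeping outliers
#'   (default 3; `Inf` disables).
#' @return List of class `coexpression_result`: `anchor_proportion` (per
#'   subset), `coexpression` (subsets x partners matrix), `n_cells`,
#'   `n_anchor_positive`.
#' @export
coexpression_proportions <- function(table, anchor_gene = "PRF1",
                                     partner_genes,
                                     threshold = 0,
                                     housekeeping = NULL,
                                     hk_min = -Inf, iqr_fence = 3) {
  if (!"subset" %in% names(table))
    stop_fmt("single-cell table needs a 'subset' column")
  for (g in c(anchor_gene, partner_genes, housekeeping))
    if (!g %in% names(table)) stop_fmt("gene column '%s' missing", g)
  if (!is.null(housekeeping)) {
    hk <- table[[housekeeping]]
    q <- stats::quantile(hk, c(0.25, 0.75))
    fence <- iqr_fence * (q[2] - q[1])
    ok <- hk >= hk_min & hk >= q[1] - fence & hk <= q[2] + fence
    table <- table[ok, , drop = FALSE]
  }
  subsets <- unique(table$subset)
  anchor_prop <- stats::setNames(numeric(length(subsets)), subsets)
  n_cells <- n_pos <- stats::setNames(integer(length(subsets)), subsets)
  co <- matrix(NA_real_, length(subsets), length(partner_genes),
               dimnames = list(subsets, partner_genes))
  for (s in subsets) {
    d <- table[table$subset == s, , drop = FALSE]
    apos <- d[[anchor_gene]] > threshold
    n_cells[s] <- nrow(d); n_pos[s] <- sum(apos)
    anchor_prop[s] <- mean(apos)
    if (sum(apos) > 0) {
      for (g in partner_genes)
        co[s, g] <- mean(d[[g]][apos] > threshold)
    }
  }
  structure(list(anchor_proportion = anchor_prop, coexpression = co,
                 n_cells = n_cells, n_anchor_positive = n_pos),
            class = "coexpression_result")
}

#' Bisulphite pyrosequencing summaries over a 34-CpG promoter tiling
#'
#' Per CpG site: median and interquartile range of the methylation
#' percentage across donors (optionally within groups); per region
#' (distal sites 1-15, intermediate 16-28, proximal 29-34 by default):
#' the median of the per-CpG medians.
#'
#' @param table Data frame with 34 CpG columns (`CpG_1` ... `CpG_34`,
#'   values in \[0,100\]) and optional `subset`/`donor` columns.
#' @param regions Named list of site indices defining the regions.
#' @param group Optional grouping column name (e.g. `"subset"`).
#' @return List of class `pyroseq_summary`: `per_cpg` (long data frame
#'   with median and IQR) and `per_region` (region medians).
#' @export
pyroseq_summary <- function(table,
                            regions = list(distal = 1:15,
                                           intermediate = 16:28,
                                           proximal = 29:34),
                            group = NULL) {
  cpg_cols <- sprintf("CpG_%d", 1:34)
  if (!all(cpg_cols %in% names(table)))
    stop_fmt("pyrosequencing table must have 34 CpG columns (CpG_1..CpG_34)")
  vals <- as.matrix(table[cpg_cols])
  if (any(vals < 0 | vals > 100, na.rm = TRUE))
    stop_fmt("methylation percentages must lie in [0, 100]")
  groups <- if (is.null(group)) rep("all", nrow(table)) else table[[group]]
  per_cpg <- do.call(rbind, lapply(unique(groups), function(g) {
    m <- vals[groups == g, , drop = FALSE]
    data.frame(group = g, cpg = 1:34,
               median = apply(m, 2L, stats::median),
               iqr = apply(m, 2L, stats::IQR),
               stringsAsFactors = FALSE)
  }))
  rownames(per_cpg) <- NULL
  per_region <- do.call(rbind, lapply(unique(per_cpg$group), function(g) {
    med <- per_cpg$median[per_cpg$group == g]
    data.frame(group = g, region = names(regions),
               median = vapply(regions, function(idx)
                 stats::median(med[idx]), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_region) <- NULL
  structure(list(per_cpg = per_cpg, per_region = per_region),
            class = "pyroseq_summary")
}

#' Group-comparison helper for assay summary tables
#'
#' Thin wrapper reproducing the conventional testing cascade for bench
#' readouts: Kruskal-Wallis (or one-way ANOVA) across groups followed by
#' pairwise Wilcoxon (Mann-Whitney) tests with the requested p-adjustment.
#'
#' @param values Numeric readouts.
#' @param groups Group labels.
#' @param method `"kruskal"` (default) or `"anova"` for the omnibus test.
#' @param p_adjust Adjustment method for the pairwise tests (see
#'   [stats::p.adjust.methods]).
#' @return List: `omnibus_p`, `pairwise` (matrix of adjusted p-values).
#' @export
subset_compare <- function(values, groups, method = c("kruskal", "anova"),
                           p_adjust = "holm") {
  method <- match.arg(method)
  groups <- factor(groups)
  omnibus <- if (method == "kruskal")
    stats::kruskal.test(values, groups)$p.value
  else summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1]
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = p_adjust,
                                exact = FALSE)$p.value)
  list(omnibus_p = omnibus, pairwise = pw)
}
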