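#' Specification of a synthetic paired T-cell subset study
#'
#' Describes the simulated design the pipeline is exercised on: donors
#' crossed with T-cell subsets (paired by donor), log2-normal expression
#' with planted subset-specific signature genes, and beta-distributed
#' 450K-style methylation with planted promoter hypomethylation coupled to
#' the planted upregulated genes. Type-II probes are compressed toward 0.5
#' before output to mimic the Infinium type-I/type-II dynamic-range bias
#' that peak-based correction targets.
#'
#' Defaults emulate the study design the pipeline was built around: five
#' CMV-seropositive donors, six subsets spanning the CD4 Th1 lineage and
#' the CD8 lineage, a shared cytotoxic signature planted in the two
#' terminally differentiated cytotoxic subsets (log2 shift +2), and
#' promoter hypomethylation of the same genes (delta-beta -0.3).
#'
#' @param n_donors Number of donors (each donor contributes one sample per
#'   subset).
#' @param subsets Subset labels.
#' @param signature_subsets Subsets carrying the planted signature.
#' @param n_probes_expr,n_probes_meth Expression / methylation probe counts.
#' @param n_signature_genes Planted signature size (genes).
#' @param expr_effect Log2 shift planted in signature subsets.
#' @param meth_effect Delta-beta planted on promoter probes of signature
#'   genes in signature subsets (negative = hypomethylation).
#' @param expr_noise_sd Residual log2 noise SD per measurement.
#' @param donor_sd SD of the per-donor, per-probe expression shift shared
#'   across subsets (what the paired design removes).
#' @param beta_concentration Beta-distribution concentration (a+b); larger
#'   means tighter beta-values around the probe mean.
#' @param typeII_compression Linear compression of type-II beta-values
#'   toward 0.5, in (0,1); 0 disables the planted bias.
#' @param seed Integer seed; fully determines the study.
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(n_donors = 5,
                       subsets = c("CD4_naive", "CM_Th1", "EM28_Th1",
                                   "CD4_CTX", "CD8_naive", "CD8_CTX"),
                       signature_subsets = c("CD4_CTX", "CD8_CTX"),
                       n_probes_expr = 2000,
                       n_probes_meth = 4000,
                       n_signature_genes = 50,
                       expr_effect = 2.0,
                       meth_effect = -0.3,
                       expr_noise_sd = 0.25,
                       donor_sd = 0.15,
                       beta_concentration = 150,
                       typeII_compression = 0.2,
                       seed = 1L) {
  n_donors <- check_count(n_donors, "n_donors")
  n_probes_expr <- check_count(n_probes_expr, "n_probes_expr")
  n_probes_meth <- check_count(n_probes_meth, "n_probes_meth")
  n_signature_genes <- check_count(n_signature_genes, "n_signature_genes")
  if (length(subsets) < 2L) stop_fmt("need at least two subsets")
  if (!all(signature_subsets %in% subsets))
    stop_fmt("signature_subsets must be a subset of subsets")
  if (typeII_compression < 0 || typeII_compression >= 1)
    stop_fmt("typeII_compression must lie in [0, 1)")
  if (beta_concentration <= 2) stop_fmt("beta_concentration must exceed 2")
  if (expr_noise_sd < 0 || donor_sd < 0) stop_fmt("noise SDs must be >= 0")
  if (n_probes_meth < 2L * n_signature_genes)
    stop_fmt("n_probes_meth must be at least 2 * n_signature_genes")
  if (n_probes_expr < 2L * n_signature_genes)
    stop_fmt("n_probes_expr must be at least 2 * n_signature_genes")
  structure(list(n_donors = n_donors, subsets = subsets,
                 signature_subsets = signature_subsets,
                 n_probes_expr = n_probes_expr,
                 n_probes_meth = n_probes_meth,
                 n_signature_genes = n_signature_genes,
                 expr_effect = expr_effect, meth_effect = meth_effect,
                 expr_noise_sd = expr_noise_sd, donor_sd = donor_sd,
                 beta_concentration = beta_concentration,
                 typeII_compression = typeII_compression,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate a paired expression + methylation study with known ground truth
#'
#' Expression: per-probe baseline N(8, 1.5) on the log2 scale, a per-donor
#' per-probe shift N(0, donor_sd) shared across subsets (the paired
#' structure), measurement noise N(0, expr_noise_sd), and `expr_effect`
#' added to signature-gene probes in the signature subsets.
#'
#' Methylation: per-probe baseline means drawn from a bimodal mixture
#' (modes near 0.1 and 0.85, as on real 450K arrays); per-sample
#' beta-values drawn from Beta distributions with concentration
#' `beta_concentration` around the (possibly shifted) mean; planted
#' promoter probes of signature genes shifted by `meth_effect` in the
#' signature subsets; type-II probes then compressed toward 0.5. Raw
#' methylated/unmethylated signals and detection p-values consistent with
#' the beta matrix are attached, with a small fraction of probes planted to
#' fail detection and ~1% / ~2% flagged cross-reactive / SNP-overlapping.
#'
#' @param spec A [study_spec].
#' @return List with elements `expression` ([expression_study]),
#'   `methylation` ([methylation_study]) and `truth` (planted signature
#'   genes per subset, planted hypomethylated probes, planted flags).
#' @export
make_study <- function(spec = study_spec()) {
  stopifnot(inherits(spec, "study_spec"))
  with_seed(spec$seed, {
    donors <- sprintf("D%d", seq_len(spec$n_donors))
    design <- expand.grid(donor = donors, subset = spec$subsets,
                          stringsAsFactors = FALSE)[, c(2, 1)]
    design$sample_id <- paste(design$subset, design$donor, sep = ".")
    n_samp <- nrow(design)
    sig_cols <- design$subset %in% spec$signature_subsets

    ## ---- expression ----
    n_genes <- max(spec$n_signature_genes + 10L,
                   ceiling(spec$n_probes_expr * 0.9))
    genes <- sprintf("G%04d", seq_len(n_genes))
    sig_genes <- genes[seq_len(spec$n_signature_genes)]
    # one probe per gene, remaining probes re-measure random genes
    probe_gene_map <- c(genes,
                        sample(genes, spec$n_probes_expr - n_genes,
                               replace = TRUE))
    probes_e <- sprintf("EP%05d", seq_len(spec$n_probes_expr))
    baseline_e <- stats::rnorm(spec$n_probes_expr, 8, 1.5)
    donor_eff <- matrix(stats::rnorm(spec$n_probes_expr * spec$n_donors,
                                     0, spec$donor_sd),
                        spec$n_probes_expr, spec$n_donors,
                        dimnames = list(NULL, donors))
    ev <- baseline_e +
      donor_eff[, design$donor] +
      matrix(stats::rnorm(spec$n_probes_expr * n_samp,
                          0, spec$expr_noise_sd),
             spec$n_probes_expr, n_samp)
    sig_probe_idx <- which(probe_gene_map %in% sig_genes)
    ev[sig_probe_idx, sig_cols] <- ev[sig_probe_idx, sig_cols] +
      spec$expr_effect
    dimnames(ev) <- list(probes_e, design$sample_id)
    expr <- expression_study(
      ev, data.frame(probe_id = probes_e, gene = probe_gene_map,
                     stringsAsFactors = FALSE),
      design)

    ## ---- methylation ----
    nm <- spec$n_probes_meth
    probes_m <- sprintf("cg%06d", seq_len(nm))
    # first block: one guaranteed promoter probe plus one free probe per
    # signature gene, so every planted gene maps to >= 1 promoter probe
    ns <- spec$n_signature_genes
    m_gene <- c(sig_genes, sig_genes,
                sample(genes, nm - 2L * ns, replace = TRUE))
    m_region <- c(sample(PROMOTER_REGIONS, ns, replace = TRUE,
                         prob = c(0.45, 0.2, 0.2, 0.15)),
                  sample(REGION_CLASSES, nm - ns, replace = TRUE,
                         prob = c(0.2, 0.1, 0.1, 0.05, 0.35, 0.1, 0.1)))
    m_type <- sample(c("I", "II"), nm, replace = TRUE, prob = c(0.3, 0.7))
    # bimodal baseline: unmethylated mode ~0.1, methylated mode ~0.85
    low <- stats::runif(nm) < 0.5
    base_m <- ifelse(low, stats::rbeta(nm, 2, 18), stats::rbeta(nm, 17, 3))
    planted_idx <- which(m_gene %in% sig_genes &
                           m_region %in% PROMOTER_REGIONS)
    # planted promoters start on the side that keeps the shift inside
    # (0,1): methylated for planted hypomethylation, unmethylated for
    # planted hypermethylation
    base_m[planted_idx] <- if (spec$meth_effect <= 0)
      stats::runif(length(planted_idx), 0.65, 0.9)
    else stats::runif(length(planted_idx), 0.1, 0.35)
    donor_shift <- matrix(stats::rnorm(nm * spec$n_donors, 0, 0.02),
                          nm, spec$n_donors, dimnames = list(NULL, donors))
    mean_mat <- matrix(base_m, nm, n_samp) + donor_shift[, design$donor]
    mean_mat[planted_idx, sig_cols] <- mean_mat[planted_idx, sig_cols] +
      spec$meth_effect
    mean_mat <- pmin(pmax(mean_mat, 0.02), 0.98)
    conc <- spec$beta_concentration
    beta <- matrix(stats::rbeta(nm * n_samp, mean_mat * conc,
                                (1 - mean_mat) * conc),
                   nm, n_samp)
    is2 <- m_type == "II"
    beta[is2, ] <- 0.5 + (1 - spec$typeII_compression) * (beta[is2, ] - 0.5)
    beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)
    dimnames(beta) <- list(probes_m, design$sample_id)

    total <- matrix(round(stats::rlnorm(nm * n_samp, log(5000), 0.3)),
                    nm, n_samp, dimnames = dimnames(beta))
    raw_M <- round(beta * total)
    raw_U <- total - raw_M

    detection_p <- matrix(stats::runif(nm * n_samp, 0, 0.01), nm, n_samp,
                          dimnames = dimnames(beta))
    free_idx <- setdiff(seq_len(nm), planted_idx)
    fail_idx <- sample(free_idx, max(1L, round(0.005 * nm)))
    detection_p[cbind(fail_idx,
                      sample(n_samp, length(fail_idx), replace = TRUE))] <- 0.2
    cross_idx <- sample(setdiff(free_idx, fail_idx), round(0.01 * nm))
    snp_idx <- sample(setdiff(free_idx, cross_idx), round(0.02 * nm))

    annot <- data.frame(probe_id = probes_m, gene = m_gene,
                        region = m_region, type = m_type,
                        cross_reactive = seq_len(nm) %in% cross_idx,
                        snp_overlap = seq_len(nm) %in% snp_idx,
                        stringsAsFactors = FALSE)
    meth <- methylation_study(beta, annot, design, raw_M = raw_M,
                              raw_U = raw_U, detection_p = detection_p)

    truth <- list(
      signature_genes = stats::setNames(
        rep(list(sig_genes), length(spec$signature_subsets)),
        spec$signature_subsets),
      signature_probes_expr = probes_e[sig_probe_idx],
      hypo_probes = probes_m[planted_idx],
      detection_fail_probes = probes_m[fail_idx],
      cross_reactive_probes = probes_m[cross_idx],
      spec = spec)

    list(expression = expr, methylation = meth, truth = truth)
  })
}

#' Seeded bench-assay fixtures with known planted effects
#'
#' Small tables mimicking the bench-assay readouts the calculator module
#' consumes, each fully determined by its seed and carrying its planted
#' effects as the `truth` attribute.
#'
#' `make_qpcr_fixture()`: a Cp table (sample, donor, subset, gene, cp,
#' replicate) over the CD4 Th1 lineage with EEF1A1 as housekeeping
#' reference and planted per-subset log2 fold changes of PRF1 relative to
#' naive CD4.
#'
#' `make_chip_fixture()`: ChIP-qPCR Cp rows (region, antibody, donor, cp)
#' for a target mark, pan-H3 and 1% input at a promoter and a -15 kb
#' control region, with a planted H3-normalized fold enrichment at the
#' promoter.
#'
#' `make_singlecell_fixture()`: single-cell expression table (43 cells per
#' subset) with planted per-subset PRF1-positive proportions and planted
#' co-expression of partner transcription factors among PRF1+ cells.
#'
#' `make_pyroseq_fixture()`: per-donor methylation percentages at 34 CpG
#' sites of a promoter tiled by 11 amplicons, with stepwise planted
#' demethylation of the intermediate sites (16-28) along the Th1 lineage.
#'
#' @param seed Integer seed.
#' @param effect_scale Multiplier on all planted effects (0 gives a null
#'   fixture).
#' @return A data.frame with a `truth` attribute listing planted effects.
#' @export
make_qpcr_fixture <- function(seed = 1L, effect_scale = 1) {
  with_seed(derive_seed(seed, 101L), {
    donors <- sprintf("D%d", 1:5)
    subsets <- c("CD4_naive", "CM_Th1", "EM28_Th1", "CD4_CTX")
    planted <- c(CD4_naive = 0, CM_Th1 = 1.0, EM28_Th1 = 1.8,
                 CD4_CTX = 2.5) * effect_scale
    rows <- expand.grid(replicate = 1:2, gene = c("PRF1", "EEF1A1"),
                        donor = donors, subset = subsets,
                        stringsAsFactors = FALSE)
    ref_cp <- stats::rnorm(length(donors) * length(subsets), 18, 0.3)
    names(ref_cp) <- paste(rep(subsets, each = length(donors)),
                           rep(donors, length(subsets)), sep = ".")
    key <- paste(rows$subset, rows$donor, sep = ".")
    cp <- ifelse(rows$gene == "EEF1A1", ref_cp[key],
                 ref_cp[key] + 6 - planted[rows$subset])
    rows$cp <- cp + stats::rnorm(nrow(rows), 0, 0.05)
    rows$sample_id <- key
    out <- rows[, c("sample_id", "donor", "subset", "gene", "cp",
                    "replicate")]
    attr(out, "truth") <- list(planted_log2fc = planted,
                               calibrator_subset = "CD4_naive",
                               target_gene = "PRF1")
    out
  })
}

#' @rdname make_qpcr_fixture
#' @param fold_enrichment Planted promoter/control enrichment of the target
#'   mark after H3 normalization.
#' @export
make_chip_fixture <- function(seed = 1L, fold_enrichment = 4) {
  with_seed(derive_seed(seed, 202L), {
    donors <- sprintf("D%d", 1:3)
    regions <- c("promoter", "minus15kb")
    input_fraction <- 0.01
    # percent-input levels: H3 flat across regions, target enriched at the
    # promoter by the planted fold
    pct <- list(H3 = c(promoter = 10, minus15kb = 10),
                H3K4me3 = c(promoter = 0.5 * fold_enrichment,
                            minus15kb = 0.5))
    rows <- expand.grid(antibody = c("input", "H3", "H3K4me3"),
                        region = regions, donor = donors,
                        stringsAsFactors = FALSE)
    cp_input <- stats::rnorm(nrow(rows), 24, 0.2)
    adj <- cp_input - log2(1 / input_fraction)
    cp <- numeric(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      ab <- rows$antibody[i]
      cp[i] <- if (ab == "input") cp_input[i] else
        adj[i] - log2(pct[[ab]][rows$region[i]] / 100)
    }
    rows$cp <- cp + stats::rnorm(nrow(rows), 0, 0.03)
    out <- rows[, c("region", "antibody", "donor", "cp")]
    attr(out, "truth") <- list(fold_enrichment = fold_enrichment,
                               input_fraction = input_fraction,
                               target_antibody = "H3K4me3")
    out
  })
}

#' @rdname make_qpcr_fixture
#' @param n_cells Cells per subset.
#' @export
make_singlecell_fixture <- function(seed = 1L, n_cells = 43) {
  with_seed(derive_seed(seed, 303L), {
    subsets <- c("CD4_naive", "CM_Th1", "EM28_Th1", "CD4_CTX")
    prf1_pos <- c(CD4_naive = 0.05, CM_Th1 = 0.30, EM28_Th1 = 0.50,
                  CD4_CTX = 0.80)
    partners <- c(RUNX3 = 0.60, TBX21 = 0.70, ZBTB7B = 0.90, EOMES = 0.40)
    bg <- 0.10   # partner positivity in PRF1-negative cells
    rows <- list()
    for (s in subsets) {
      anchor <- stats::runif(n_cells) < prf1_pos[s]
      df <- data.frame(cell_id = paste(s, seq_len(n_cells), sep = "."),
                       subset = s, stringsAsFactors = FALSE)
      df$EEF1A1 <- stats::rnorm(n_cells, 10, 1)
      df$PRF1 <- ifelse(anchor, stats::rnorm(n_cells, 5, 1), 0)
      for (g in names(partners)) {
        pos <- stats::runif(n_cells) < ifelse(anchor, partners[g], bg)
        df[[g]] <- ifelse(pos, stats::rnorm(n_cells, 5, 1), 0)
      }
      rows[[s]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(prf1_positive = prf1_pos,
                               partner_coexpression = partners)
    out
  })
}

#' @rdname make_qpcr_fixture
#' @export
make_pyroseq_fixture <- function(seed = 1L) {
  with_seed(derive_seed(seed, 404L), {
    donors <- sprintf("D%d", 1:5)
    subsets <- c("CD4_naive", "CM_Th1", "EM28_Th1", "CD4_CTX")
    # intermediate sites (16-28) demethylate stepwise along the lineage
    inter <- c(CD4_naive = 90, CM_Th1 = 70, EM28_Th1 = 50, CD4_CTX = 25)
    rows <- expand.grid(donor = donors, subset = subsets,
                        stringsAsFactors = FALSE)[, c(2, 1)]
    site_means <- function(s)
      c(rep(80, 15), rep(inter[s], 13), rep(15, 6))
    m <- t(vapply(rows$subset, site_means, numeric(34)))
    m <- m + matrix(stats::rnorm(length(m), 0, 4), nrow(m))
    m <- pmin(pmax(m, 0), 100)
    colnames(m) <- sprintf("CpG_%d", 1:34)
    out <- cbind(rows, as.data.frame(m))
    rownames(out) <- NULL
    attr(out, "truth") <- list(intermediate_means = inter,
                               regions = list(distal = 1:15,
                                              intermediate = 16:28,
                                              proximal = 29:34))
    out
  })
}

#' Write a synthetic study to disk through the package's format writers
#'
#' @param study Result of [make_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(study$expression$values,
                   file.path(dir, "expression.tsv"))
  utils::write.table(study$expression$probe_gene,
                     file.path(dir, "expression_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_design_tsv(study$expression$design, file.path(dir, "design.tsv"))
  write_matrix_tsv(study$methylation$beta, file.path(dir, "beta.tsv"))
  utils::write.table(study$methylation$annotation,
                     file.path(dir, "methylation_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
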