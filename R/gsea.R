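#' GSEA configuration
#'
#' Bundles the permutation GSEA tuning parameters: number of gene-set
#' permutations (default 1000), the weighting exponent of the running
#' Kolmogorov-Smirnov statistic (p = 1, classic weighted GSEA; p = 0 gives
#' the unweighted KS walk), the FDR significance threshold (0.25, the
#' conventional GSEA cutoff), and the permutation seed.
#'
#' @param n_perm Number of gene-set permutations (>= 1).
#' @param weight_exponent Non-negative weighting exponent.
#' @param fdr_threshold FDR significance level in (0,1).
#' @param seed Integer seed; permutations for each gene set are drawn from
#'   a sub-stream derived from (seed, gene-set name), so results do not
#'   depend on the order in which sets are evaluated.
#' @return List of class `gsea_config`.
#' @export
gsea_config <- function(n_perm = 1000, weight_exponent = 1,
                        fdr_threshold = 0.25, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  if (weight_exponent < 0) stop_fmt("weight_exponent must be >= 0")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop_fmt("fdr_threshold must lie in (0,1)")
  structure(list(n_perm = n_perm, weight_exponent = weight_exponent,
                 fdr_threshold = fdr_threshold, seed = as.integer(seed)),
            class = "gsea_config")
}

#' Rank genes by the difference-of-classes metric
#'
#' Scores every gene by mean(log2 expression in `class_a`) minus
#' mean(log2 expression in `class_b`) — the difference-of-classes metric,
#' appropriate for log-scale values where a difference is a log fold
#' change — and returns the descending [ranked_list]. Multi-probe genes
#' are collapsed first (default: the probe with maximal variance across
#' all samples represents the gene).
#'
#' @param study An [expression_study].
#' @param class_a,class_b Subset labels (score is a minus b).
#' @param collapse Probe-to-gene collapse rule.
#' @return A [ranked_list] of gene symbols.
#' @export
rank_by_metric <- function(study, class_a, class_b,
                           collapse = c("max_variance", "mean",
                                        "max_mean")) {
  stopifnot(inherits(study, "expression_study"))
  collapse <- match.arg(collapse)
  ai <- subset_columns(study$design, class_a)
  bi <- subset_columns(study$design, class_b)
  x <- collapse_to_genes(study, collapse)
  score <- rowMeans(x[, ai, drop = FALSE]) -
    rowMeans(x[, bi, drop = FALSE])
  ranked_list(rownames(x), score)
}

# gene x sample matrix after collapsing multi-probe genes
collapse_to_genes <- function(study, collapse = "max_variance") {
  x <- study$values
  gene <- study$probe_gene$gene[match(rownames(x),
                                      study$probe_gene$probe_id)]
  keep <- !is.na(gene)
  x <- x[keep, , drop = FALSE]; gene <- gene[keep]
  if (collapse == "mean") {
    out <- rowsum(x, gene) / as.vector(table(gene)[sort(unique(gene))])
    return(out[order(rownames(out), method = "radix"), , drop = FALSE])
  }
  stat <- if (collapse == "max_variance") row_vars(x) else rowMeans(x)
  o <- order(gene, -stat, method = "radix")
  sel <- o[!duplicated(gene[o])]
  out <- x[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}

#' Running enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list from top to bottom: positions occupied by set
#' members ("hits") increment the running sum by |score|^p normalized by
#' the sum of |score|^p over the members; every other position decrements
#' by 1/(N - N_hit). The enrichment score (ES) is the signed maximum
#' deviation of this walk from zero; it lies in \[-1, 1\]. If all member
#' weights are zero (possible when p > 0 and all member scores are 0),
#' uniform hit increments are used.
#'
#' @param ranked A [ranked_list].
#' @param geneset A [gene_set]; must share at least one identifier with the
#'   ranked list.
#' @param p Weighting exponent (>= 0).
#' @return List with `ES`, `running_profile` (length N) and `peak` (index
#'   of the maximal deviation).
#' @export
enrichment_score <- function(ranked, geneset, p = 1) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(geneset, "gene_set"))
  N <- nrow(ranked)
  pos <- sort(match(geneset$genes, ranked$id))
  pos <- pos[!is.na(pos)]
  if (!length(pos))
    stop_fmt("gene set '%s' shares no identifiers with the ranked list (unusable)",
             geneset$name)
  if (length(pos) >= N)
    stop_fmt("gene set '%s' covers the whole ranked list", geneset$name)
  w <- abs(ranked$score[pos])^p
  if (sum(w) == 0) w <- rep(1, length(pos))
  steps <- rep(-1 / (N - length(pos)), N)
  steps[pos] <- w / sum(w)
  profile <- cumsum(steps)
  # signed maximum deviation; an exact tie (possible with rational step
  # sizes) resolves to the positive side, guarded against rounding noise
  hi <- max(profile); lo <- min(profile, 0)
  if (hi >= -lo - 1e-12) {
    peak <- which.max(profile); es <- hi
  } else {
    peak <- which.min(profile); es <- lo
  }
  list(ES = es, running_profile = profile, peak = peak)
}

# fast signed ES from sorted hit positions; absw = |score|^p for the whole
# ranked list. Extremes of the walk occur only adjacent to hits.
es_stat <- function(pos, absw, N) {
  k <- length(pos)
  wn <- absw[pos]
  s <- sum(wn)
  wn <- if (s == 0) rep(1 / k, k) else wn / s
  cs <- cumsum(wn)
  top <- cs - (pos - seq_len(k)) / (N - k)
  bot <- top - wn
  hi <- max(top); lo <- min(bot, 0)
  if (hi >= -lo - 1e-12) hi else lo
}

#' Permutation GSEA over a ranked list
#'
#' Computes, for every gene set, the enrichment score of
#' [enrichment_score()], a gene-set permutation null (ES of `n_perm`
#' random same-size identifier subsets of the ranked universe), the
#' one-sided nominal p against the same-sign null, the normalized
#' enrichment score NES = ES / mean(|same-sign null ES|), and the FDR by
#' the GSEA procedure: the observed NES distribution is compared with the
#' pooled, per-set-normalized permutation NES distribution, sign-stratified
#' and capped at 1. `gsea_preranked()` is the same engine applied to an
#' externally supplied ranking (e.g. delta-beta values).
#'
#' Gene sets sharing no identifier with the universe, or as large as the
#' universe, are skipped with a warning.
#'
#' @param ranked A [ranked_list] (from [rank_by_metric()] or external).
#' @param genesets List of [gene_set] objects.
#' @param config A [gsea_config].
#' @return Data frame of class `enrichment_results`: `geneset`, `size`
#'   (members found in the universe), `ES`, `NES`, `p_value`, `FDR`,
#'   `leading_edge` (list column). Attribute `profiles` stores the running
#'   profiles.
#' @export
gsea_run <- function(ranked, genesets, config = gsea_config()) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(config, "gsea_config"))
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  if (!length(genesets))
    return(empty_enrichment_results())
  N <- nrow(ranked)
  absw <- abs(ranked$score)^config$weight_exponent
  n_sets <- length(genesets)
  ES <- rep(NA_real_, n_sets); size <- integer(n_sets)
  usable <- logical(n_sets)
  null_es <- vector("list", n_sets)
  profiles <- vector("list", n_sets)
  leading <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    gs <- genesets[[i]]
    pos <- sort(match(gs$genes, ranked$id))
    pos <- pos[!is.na(pos)]
    size[i] <- length(pos)
    if (!length(pos) || length(pos) >= N) {
      warning(sprintf("gene set '%s' unusable (size %d of universe %d); skipped",
                      gs$name, length(pos), N), call. = FALSE)
      next
    }
    usable[i] <- TRUE
    esr <- enrichment_score(ranked, gs, config$weight_exponent)
    ES[i] <- esr$ES
    profiles[[i]] <- esr$running_profile
    leading[[i]] <- if (esr$ES >= 0) ranked$id[pos[pos <= esr$peak]]
                    else ranked$id[pos[pos >= esr$peak]]
    k <- length(pos)
    null_es[[i]] <- with_seed(derive_seed(config$seed,
                                          string_hash(gs$name)), {
      vapply(seq_len(config$n_perm), function(b)
        es_stat(sort.int(sample.int(N, k)), absw, N), numeric(1))
    })
  }
  res <- normalize_and_fdr(ES, null_es, usable)
  out <- data.frame(geneset = vapply(genesets, `[[`, character(1), "name"),
                    size = size, ES = ES, NES = res$NES,
                    p_value = res$p, FDR = res$FDR,
                    stringsAsFactors = FALSE)
  out$leading_edge <- leading
  attr(out, "profiles") <- profiles
  attr(out, "config") <- config
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' @rdname gsea_run
#' @export
gsea_preranked <- function(ranked, genesets, config = gsea_config()) {
  gsea_run(ranked, genesets, config)
}

empty_enrichment_results <- function() {
  out <- data.frame(geneset = character(0), size = integer(0),
                    ES = numeric(0), NES = numeric(0),
                    p_value = numeric(0), FDR = numeric(0),
                    stringsAsFactors = FALSE)
  out$leading_edge <- list()
  class(out) <- c("enrichment_results", "data.frame")
  out
}

# nominal p, NES and sign-stratified pooled-null FDR (GSEA conventions)
normalize_and_fdr <- function(ES, null_es, usable) {
  n <- length(ES)
  p <- NES <- FDR <- rep(NA_real_, n)
  null_nes <- vector("list", n)
  for (i in which(usable)) {
    nul <- null_es[[i]]
    pos_mean <- mean(nul[nul >= 0]); neg_mean <- mean(abs(nul[nul < 0]))
    if (ES[i] >= 0) {
      same <- nul[nul >= 0]
      p[i] <- if (length(same)) mean(same >= ES[i]) else 0
      NES[i] <- if (length(same)) ES[i] / pos_mean else NA_real_
    } else {
      same <- nul[nul < 0]
      p[i] <- if (length(same)) mean(same <= ES[i]) else 0
      NES[i] <- if (length(same)) -abs(ES[i]) / neg_mean else NA_real_
    }
    nn <- nul
    nn[nul >= 0] <- if (is.finite(pos_mean) && pos_mean > 0)
      nul[nul >= 0] / pos_mean else NA_real_
    nn[nul < 0] <- if (is.finite(neg_mean) && neg_mean > 0)
      nul[nul < 0] / neg_mean else NA_real_
    null_nes[[i]] <- nn
  }
  pool <- unlist(null_nes)
  pool <- pool[is.finite(pool)]
  obs <- NES[usable & is.finite(NES)]
  for (i in which(usable)) {
    if (!is.finite(NES[i])) next
    if (NES[i] >= 0) {
      denom_pool <- sum(pool >= 0)
      num <- if (denom_pool) sum(pool >= NES[i]) / denom_pool else 0
      denom_obs <- sum(obs >= 0)
      den <- if (denom_obs) sum(obs >= NES[i]) / denom_obs else 1
    } else {
      denom_pool <- sum(pool < 0)
      num <- if (denom_pool) sum(pool <= NES[i]) / denom_pool else 0
      denom_obs <- sum(obs < 0)
      den <- if (denom_obs) sum(obs <= NES[i]) / denom_obs else 1
    }
    FDR[i] <- min(1, if (den > 0) num / den else 0)
  }
  list(p = p, NES = NES, FDR = FDR)
}

#' Non-differential control gene set
#'
#' Helper building a negative-control gene set: genes whose
#' difference-of-classes score between two subsets is smallest in absolute
#' value (no differential expression between the two populations).
#'
#' @param study An [expression_study].
#' @param class_a,class_b Subset labels.
#' @param n Number of control genes.
#' @return A [gene_set] named `control_<a>_<b>`.
#' @export
control_geneset <- function(study, class_a, class_b, n = 100) {
  ranked <- rank_by_metric(study, class_a, class_b)
  o <- order(abs(ranked$score), ranked$id, method = "radix")
  gene_set(paste0("control_", class_a, "_", class_b),
           ranked$id[o[seq_len(min(n, nrow(ranked)))]],
           description = "least differential genes (negative control)")
}
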