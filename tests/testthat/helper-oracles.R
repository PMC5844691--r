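# independent oracles and tiny fixture builders used across test files

# brute-force KS-walk enrichment score: plain loop, positive tie preference
es_oracle <- function(scores_desc, is_hit, p) {
  N <- length(scores_desc)
  w <- abs(scores_desc[is_hit])^p
  if (sum(w) == 0) w <- rep(1, sum(is_hit))
  inc <- w / sum(w)
  dec <- 1 / (N - sum(is_hit))
  running <- 0; hi <- -Inf; lo <- Inf; h <- 0
  profile <- numeric(N)
  for (i in seq_len(N)) {
    if (is_hit[i]) { h <- h + 1; running <- running + inc[h] }
    else running <- running - dec
    profile[i] <- running
    hi <- max(hi, running); lo <- min(lo, running)
  }
  lo <- min(lo, 0)
  # exact ties (possible with rational step sizes) resolve to the positive
  # side; the 1e-12 guard keeps accumulated rounding from flipping them
  if (hi >= -lo - 1e-12) hi else lo
}

# rank-and-average quantile normalization oracle (ties -> mean of the
# candidate quantile values)
qn_oracle <- function(x) {
  m <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- (m[floor(r)] + m[ceiling(r)]) / 2
  }
  out
}

# brute-force Ward.D2 agglomeration via the Lance-Williams update on a
# distance matrix; returns the list of merged leaf-label sets
ward_oracle_clusters <- function(d) {
  d <- as.matrix(d)^2   # ward.D2 operates on squared dissimilarities
  labs <- rownames(d)
  active <- lapply(seq_along(labs), function(i) labs[i])
  sizes <- rep(1, length(labs))
  clusters <- list()
  while (length(active) > 1L) {
    n <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    i <- best[2]; j <- best[3]
    merged <- c(active[[i]], active[[j]])
    clusters[[length(clusters) + 1L]] <- sort(merged)
    ni <- sizes[i]; nj <- sizes[j]
    newd <- vapply(seq_len(n), function(k) {
      if (k %in% c(i, j)) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], ni + nj)
  }
  clusters
}

# tiny expression study straight from a matrix; columns become one sample
# per (subset, donor) pair
tiny_expr <- function(values, subsets, donors = NULL,
                      genes = rownames(values)) {
  if (is.null(donors)) {
    donors <- stats::ave(seq_along(subsets), subsets, FUN = seq_along)
    donors <- paste0("D", donors)
  }
  sample_id <- paste(subsets, donors, sep = ".")
  colnames(values) <- sample_id
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  expression_study(values,
                   data.frame(probe_id = rownames(values),
                              gene = genes %||% rownames(values),
                              stringsAsFactors = FALSE),
                   data.frame(sample_id = sample_id, subset = subsets,
                              donor = donors, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny methylation study from a beta matrix + region/type vectors
tiny_meth <- function(beta, subsets, donors, genes = NULL, regions = NULL,
                      types = NULL, ...) {
  sample_id <- paste(subsets, donors, sep = ".")
  colnames(beta) <- sample_id
  if (is.null(rownames(beta)))
    rownames(beta) <- paste0("cg", seq_len(nrow(beta)))
  n <- nrow(beta)
  methylation_study(
    beta,
    data.frame(probe_id = rownames(beta),
               gene = genes %||% paste0("G", seq_len(n)),
               region = regions %||% rep("TSS200", n),
               type = types %||% rep("I", n),
               cross_reactive = FALSE, snp_overlap = FALSE,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, subset = subsets, donor = donors,
               stringsAsFactors = FALSE),
    ...)
}

# bipartition-set view of a bootstrapped dendrogram: key -> BP
bp_map <- function(bd) {
  keys <- vapply(bd$clusters, function(m) paste(sort(m), collapse = "|"),
                 character(1))
  stats::setNames(bd$bp, keys)
}
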