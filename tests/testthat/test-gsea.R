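test_that("difference-of-classes ranking is exact and anti-symmetric", {
  v <- rbind(g1 = c(5, 5, 3, 3), g2 = c(2, 4, 3, 3), g3 = c(1, 1, 6, 2))
  st <- tiny_expr(v, subsets = c("A", "A", "B", "B"))
  r <- rank_by_metric(st, "A", "B")
  expect_equal(r$score[match(c("g1", "g2", "g3"), r$id)],
               c(5 - 3, 3 - 3, 1 - 4))
  r2 <- rank_by_metric(st, "B", "A")
  expect_equal(r2$score[match(r$id, r2$id)], -r$score)
  expect_equal(r2$id, rev(r$id))   # distinct scores -> exact reversal
  expect_error(rank_by_metric(st, "A", "missing"), "unknown subset")
})

test_that("multi-probe genes collapse by the configured rule", {
  v <- rbind(p1 = c(1, 1, 1, 1), p2 = c(9, 1, 5, 1), p3 = c(2, 2, 0, 0))
  st <- tiny_expr(v, subsets = c("A", "A", "B", "B"),
                  genes = c("gX", "gX", "gY"))
  # max-variance probe of gX is p2 -> score (9+1)/2 - (5+1)/2 = 2
  r <- rank_by_metric(st, "A", "B")
  expect_equal(r$score[r$id == "gX"], 2)
  r_mean <- rank_by_metric(st, "A", "B", collapse = "mean")
  expect_equal(r_mean$score[r_mean$id == "gX"], mean(c(1, 9, 1, 1)) -
                 mean(c(1, 5, 1, 1)))
})

test_that("enrichment score reproduces the hand-walk boundary cases", {
  r <- ranked_list(c("a", "b", "c", "d"), c(3, 2, 1, 0.5))
  top <- enrichment_score(r, gene_set("s", "a"), p = 0)
  expect_equal(top$ES, 1)
  bottom <- enrichment_score(r, gene_set("s", "d"), p = 0)
  expect_equal(bottom$ES, -1)
  expect_equal(min(bottom$running_profile), -1)
  # equal scores: p = 1 weights are uniform, identical to p = 0
  re <- ranked_list(c("a", "b", "c", "d"), rep(2, 4))
  gs <- gene_set("s", c("a", "c"))
  expect_equal(enrichment_score(re, gs, p = 1)$ES,
               enrichment_score(re, gs, p = 0)$ES)
  expect_error(enrichment_score(r, gene_set("s", "zz")), "unusable")
})

test_that("enrichment score equals the brute-force oracle exhaustively at N=4", {
  scores <- c(2.5, 1.0, -0.5, -2.0)
  r <- ranked_list(letters[1:4], scores)
  for (k in 1:3) {
    for (hit_idx in utils::combn(4, k, simplify = FALSE)) {
      gs <- gene_set("s", r$id[hit_idx])
      for (p in c(0, 1)) {
        is_hit <- seq_len(4) %in% hit_idx
        expect_equal(enrichment_score(r, gs, p)$ES,
                     es_oracle(r$score, is_hit, p),
                     info = sprintf("k=%d hits=%s p=%g", k,
                                    paste(hit_idx, collapse = ","), p))
      }
    }
  }
})

test_that("enrichment score equals the oracle on 500 random instances", {
  withr::local_seed(2024)
  for (i in 1:500) {
    N <- sample(5:200, 1)
    scores <- rnorm(N)
    r <- ranked_list(sprintf("g%03d", 1:N), scores)
    k <- sample.int(N - 1, 1)
    hits <- sample(r$id, k)
    p <- sample(c(0, 1), 1)
    is_hit <- r$id %in% hits
    expect_equal(enrichment_score(r, gene_set("s", hits), p)$ES,
                 es_oracle(r$score, is_hit, p), tolerance = 1e-12)
  }
})

test_that("enrichment score matches fgsea's statistic", {
  withr::local_seed(88)
  for (i in 1:20) {
    N <- 150
    r <- ranked_list(sprintf("g%03d", 1:N), rnorm(N))
    hits <- sample(r$id, 20)
    stats_vec <- stats::setNames(r$score, r$id)
    ref <- fgsea::calcGseaStat(stats_vec, which(r$id %in% hits),
                               gseaParam = 1)
    expect_equal(enrichment_score(r, gene_set("s", hits), 1)$ES, ref,
                 tolerance = 1e-12)
  }
})

test_that("reversing the ranked list negates every unweighted ES", {
  withr::local_seed(4)
  r <- ranked_list(sprintf("g%02d", 1:40), rnorm(40))
  rev_r <- ranked_list(r$id, -r$score)
  for (i in 1:5) {
    gs <- gene_set("s", sample(r$id, 8))
    expect_equal(enrichment_score(rev_r, gs, 0)$ES,
                 -enrichment_score(r, gs, 0)$ES)
  }
})

test_that("gsea_run is deterministic, order-independent and degenerate-safe", {
  withr::local_seed(6)
  r <- ranked_list(sprintf("g%03d", 1:300), rnorm(300))
  sets <- lapply(1:4, function(i) gene_set(paste0("s", i),
                                           sample(r$id, 10 + i)))
  cfg <- gsea_config(n_perm = 200, seed = 42)
  a <- gsea_run(r, sets, cfg)
  b <- gsea_run(r, sets, cfg)
  expect_identical(a$NES, b$NES)
  expect_identical(a$FDR, b$FDR)
  # per-set ES/p do not depend on evaluation order (per-set sub-streams)
  c <- gsea_run(r, rev(sets), cfg)
  expect_equal(c$ES[match(a$geneset, c$geneset)], a$ES)
  expect_equal(c$p_value[match(a$geneset, c$geneset)], a$p_value)
  # NES sign follows ES sign; FDR capped at 1
  ok <- !is.na(a$NES) & a$ES != 0
  expect_true(all(sign(a$NES[ok]) == sign(a$ES[ok])))
  expect_true(all(a$FDR <= 1))
  # n_perm = 1 stays finite
  d <- gsea_run(r, sets[1], gsea_config(n_perm = 1, seed = 1))
  expect_true(is.finite(d$FDR) || is.na(d$FDR))
  expect_true(d$p_value %in% c(0, 1))
  # empty input, oversized and unmatched sets
  expect_equal(nrow(gsea_run(r, list(), cfg)), 0L)
  expect_warning(gsea_run(r, list(gene_set("none", "zzz")), cfg),
                 "unusable")
  # preranked entry point is the same engine
  expect_identical(gsea_preranked(r, sets, cfg)$NES, a$NES)
})

test_that("planted signature is significant by the FDR<0.25 rule", {
  st <- make_study(study_spec(n_probes_expr = 1000, n_probes_meth = 200,
                              n_signature_genes = 40, seed = 17))
  gs <- derive_geneset(st$expression, "CD4_CTX", "CD4_naive")
  r <- rank_by_metric(st$expression, "CD4_CTX", "CD4_naive")
  withr::local_seed(3)
  decoys <- lapply(1:30, function(i)
    gene_set(paste0("d", i), sample(r$id, length(gs$genes))))
  res <- gsea_run(r, c(list(gs), decoys), gsea_config(n_perm = 300,
                                                      seed = 11))
  expect_gt(res$NES[1], 0)
  expect_lt(res$FDR[1], 0.25)
})

test_that("control gene sets collect the least differential genes", {
  v <- rbind(g1 = c(9, 9, 1, 1), g2 = c(5, 5, 5.1, 5.1),
             g3 = c(1, 1, 9, 9), g4 = c(4, 4, 4, 4))
  st <- tiny_expr(v, subsets = c("A", "A", "B", "B"))
  ctl <- control_geneset(st, "A", "B", n = 2)
  expect_setequal(ctl$genes, c("g2", "g4"))
})
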