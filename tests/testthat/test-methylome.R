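test_that("beta and M-value formulas reproduce the worked cases", {
  expect_equal(compute_beta(matrix(30), matrix(70))[1], 0.3)
  expect_equal(compute_beta(matrix(50), matrix(50))[1], 0.5)
  expect_equal(compute_beta(matrix(0), matrix(10))[1], 0)
  expect_true(is.na(compute_beta(matrix(0), matrix(0))[1]))
  expect_error(compute_beta(matrix(-1), matrix(1)), ">= 0")

  expect_equal(m_values(0.5), 0)
  expect_equal(m_values(0.8), 2)
  expect_equal(m_values(0.2), -2)
  # logit2 and its inverse are mutual identities on (0,1)
  b <- seq(0.01, 0.99, by = 0.01)
  m <- m_values(b)
  expect_equal(2^m / (1 + 2^m), b, tolerance = 1e-12)
})

test_that("probe filtering removes failed/cross-reactive, keeps SNP probes", {
  beta <- matrix(runif(4 * 4), 4, 4)
  det <- matrix(0.001, 4, 4)
  det[2, 3] <- 0.2   # probe 2 fails detection in one sample
  st <- tiny_meth(beta, subsets = c("A", "A", "B", "B"),
                  donors = c("D1", "D2", "D1", "D2"),
                  detection_p = det)
  st$annotation$cross_reactive[3] <- TRUE
  st$annotation$snp_overlap[4] <- TRUE
  f <- filter_probes(st)
  expect_setequal(rownames(f$beta), c("cg1", "cg4"))
  expect_equal(unname(attr(f, "removed")["detection"]), 1)
  expect_equal(unname(attr(f, "removed")["cross_reactive"]), 1)
  # 'all' rule keeps the probe failing in only one sample
  expect_true("cg2" %in% rownames(filter_probes(st,
                                                detection_rule = "all")$beta))
})

test_that("paired DM test matches t.test and handles degenerate rows", {
  withr::local_seed(41)
  n <- 5
  beta <- matrix(runif(20 * 2 * n, 0.2, 0.8), 20, 2 * n)
  subsets <- rep(c("T", "R"), each = n)
  donors <- rep(sprintf("D%d", 1:n), 2)
  st <- tiny_meth(beta, subsets, donors)
  dm <- dm_test(st, "T", "R")
  for (i in c(1, 7, 20)) {
    m <- m_values(beta[i, ])
    ref <- t.test(m[1:n], m[(n + 1):(2 * n)], paired = TRUE)
    expect_equal(dm$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(dm$t_statistic[i], unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(dm$delta_beta[i],
                 median(beta[i, 1:n]) - median(beta[i, (n + 1):(2 * n)]))
  }
  # identical matrices: NaN-free, no calls, delta 0
  st2 <- tiny_meth(cbind(beta[, 1:n], beta[, 1:n]), subsets, donors)
  dm2 <- dm_test(st2, "T", "R")
  expect_false(any(is.nan(dm2$p_value)))
  expect_true(all(dm2$p_value == 1))
  expect_true(all(dm2$delta_beta == 0))
  expect_false(any(dm2$called))
})

test_that("DM test is anti-symmetric and enforces the conjunction rule", {
  withr::local_seed(42)
  n <- 5
  beta <- matrix(runif(30 * 2 * n, 0.1, 0.9), 30, 2 * n)
  subsets <- rep(c("T", "R"), each = n)
  donors <- rep(sprintf("D%d", 1:n), 2)
  st <- tiny_meth(beta, subsets, donors)
  a <- dm_test(st, "T", "R"); b <- dm_test(st, "R", "T")
  expect_equal(a$delta_beta, -b$delta_beta)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  # |delta-beta| = 0.3 but p >> 1e-4 (noisy) -> not called
  noisy <- rbind(c(0.9, 0.2, 0.85, 0.25, 0.8, 0.5, 0.5, 0.5, 0.5, 0.5))
  st3 <- tiny_meth(noisy, subsets, donors)
  dm3 <- dm_test(st3, "T", "R")
  expect_gt(abs(dm3$delta_beta), 0.1)
  expect_gt(dm3$p_value, 1e-4)
  expect_false(dm3$called)
  # unpaired design errors with the missing donors listed
  bad_donors <- c(sprintf("D%d", 1:n), sprintf("D%d", 3:7))
  st4 <- tiny_meth(beta, subsets, bad_donors)
  expect_error(dm_test(st4, "T", "R"), "D1")
})

test_that("DM power at the planted effect matches the Monte-Carlo oracle", {
  # paired t at p<1e-4 with df=4 needs |t| > 15.5; at delta-beta 0.3 and
  # beta-sd 0.03 the non-centrality is ~16, so power sits near 0.5-0.7
  # (computed by the independent per-probe simulation oracle), far from
  # certain despite the large planted effect
  withr::local_seed(7)
  n <- 5; conc <- 0.25 / 0.03^2 - 1   # beta-sd 0.03 at the mean
  nprobe <- 1500
  ref <- matrix(rbeta(nprobe * n, 0.75 * conc, 0.25 * conc), nprobe, n)
  tst <- matrix(rbeta(nprobe * n, 0.45 * conc, 0.55 * conc), nprobe, n)
  st <- tiny_meth(cbind(tst, ref), rep(c("T", "R"), each = n),
                  rep(sprintf("D%d", 1:n), 2))
  dm <- dm_test(st, "T", "R")
  power <- mean(dm$called)
  expect_gt(power, 0.45)
  expect_lt(power, 0.75)
})

test_that("peak correction recovers compressed type-II values", {
  # planted compression: corrected type-II peaks should land near type-I
  recovered <- 0
  for (seed in 1:5) {
    st <- make_study(study_spec(n_probes_meth = 4000, n_probes_expr = 100,
                                typeII_compression = 0.25,
                                meth_effect = 0, expr_effect = 0,
                                seed = seed))$methylation
    corr <- peak_correct(st)
    ann <- st$annotation
    is2 <- ann$type[match(rownames(st$beta), ann$probe_id)] == "II"
    ok_sample <- TRUE
    for (j in seq_len(ncol(corr$beta))) {
      p1 <- ctxomics:::density_peaks(m_values(corr$beta[!is2, j]))
      p2 <- ctxomics:::density_peaks(m_values(corr$beta[is2, j]))
      b1 <- 2^p1 / (1 + 2^p1); b2 <- 2^p2 / (1 + 2^p2)
      if (any(abs(b1 - b2) > 0.03)) ok_sample <- FALSE
    }
    if (ok_sample) recovered <- recovered + 1
    if (seed == 1) {
      # correction is monotone within each sample's type-II values and
      # never crosses 0/1
      for (j in seq_len(ncol(corr$beta))) {
        o <- order(st$beta[is2, j])
        expect_true(!is.unsorted(corr$beta[is2, j][o]))
      }
      expect_true(all(corr$beta > 0 & corr$beta < 1))
      # type-I untouched
      expect_equal(corr$beta[!is2, ], st$beta[!is2, ])
    }
  }
  expect_gte(recovered, 4)
})

test_that("peak correction is near-identity without planted bias", {
  st <- make_study(study_spec(n_probes_meth = 4000, n_probes_expr = 100,
                              typeII_compression = 0, meth_effect = 0,
                              expr_effect = 0, seed = 31))$methylation
  corr <- peak_correct(st)
  expect_lt(max(abs(corr$beta - st$beta)), 0.02)
  # all-type-I study untouched
  st$annotation$type <- "I"
  expect_identical(peak_correct(st)$beta, st$beta)
})

test_that("promoter probe lookup and region proportions", {
  beta <- matrix(runif(4 * 4), 4, 4)
  st <- tiny_meth(beta, subsets = c("A", "A", "B", "B"),
                  donors = c("D1", "D2", "D1", "D2"),
                  genes = c("RUNX3", "RUNX3", "RUNX3", "OTHER"),
                  regions = c("TSS200", "Body", "TSS1500", "TSS200"))
  expect_setequal(promoter_probes(st, "RUNX3"), c("cg1", "cg3"))
  expect_length(promoter_probes(st, "ABSENT"), 0L)
  pr <- region_proportions(st, "RUNX3")
  expect_equal(unname(pr["TSS1500"]), 0.5)
  expect_equal(sum(pr), 1)
})
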