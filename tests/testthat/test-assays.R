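cp_row <- function(sample_id, donor, subset, gene, cp)
  data.frame(sample_id = sample_id, donor = donor, subset = subset,
             gene = gene, cp = cp, stringsAsFactors = FALSE)

test_that("delta-delta-Cp worked cases", {
  tab <- rbind(
    cp_row("cal.D1", "D1", "naive", "TGT", 24), # dCp = 6
    cp_row("cal.D1", "D1", "naive", "REF", 18),
    cp_row("s1.D1", "D1", "ctx", "TGT", 23),    # dCp = 6 -> ddCp 0
    cp_row("s1.D1", "D1", "ctx", "REF", 17),
    cp_row("cal.D2", "D2", "naive", "TGT", 24),
    cp_row("cal.D2", "D2", "naive", "REF", 18),
    cp_row("s1.D2", "D2", "ctx", "TGT", 21),    # dCp = 3 -> ddCp -3
    cp_row("s1.D2", "D2", "ctx", "REF", 18))
  res <- ddcp_fold_change(tab, "TGT", "REF", "naive")
  ps <- res$per_sample
  expect_equal(ps$fold_change[ps$sample_id == "s1.D1"], 1)
  expect_equal(ps$log2_fc[ps$sample_id == "s1.D1"], 0)
  expect_equal(ps$fold_change[ps$sample_id == "s1.D2"], 8)  # ddCp -3
  # missing reference errors with the sample named
  expect_error(ddcp_fold_change(tab[-2, ], "TGT", "REF", "naive"),
               "cal.D1")
})

test_that("ddcp is invariant to a per-sample Cp shift and recovers the fixture", {
  q <- make_qpcr_fixture(5)
  res <- ddcp_fold_change(q, "PRF1", "EEF1A1", "CD4_naive")
  planted <- attr(q, "truth")$planted_log2fc
  summ <- res$summary
  for (s in names(planted))
    expect_equal(summ$median_log2_fc[summ$subset == s],
                 unname(planted[s]), tolerance = 0.35)
  # shifting every Cp of one sample leaves fold changes unchanged
  q2 <- q
  one <- q2$sample_id == q2$sample_id[1]
  q2$cp[one] <- q2$cp[one] + 3
  res2 <- ddcp_fold_change(q2, "PRF1", "EEF1A1", "CD4_naive")
  expect_equal(res2$per_sample$log2_fc, res$per_sample$log2_fc,
               tolerance = 1e-12)
})

test_that("ChIP percent-input worked cases and fixture recovery", {
  tab <- data.frame(
    region = "prom", antibody = c("input", "H3K4me3", "H3"),
    cp = c(24, 24 - log2(100), 24 - log2(100)),  # IP Cp = adjusted input
    stringsAsFactors = FALSE)
  r <- chip_percent_input(tab, "H3K4me3")
  expect_equal(r$pct_input, 100)
  expect_equal(r$normalized, 1)
  tab$cp[2] <- tab$cp[2] + 1                      # one cycle above -> 50%
  r2 <- chip_percent_input(tab, "H3K4me3")
  expect_equal(r2$pct_input, 50)
  expect_error(chip_percent_input(tab[-3, ], "H3K4me3"), "H3")

  ch <- make_chip_fixture(8)
  res <- chip_percent_input(ch, "H3K4me3")
  by_region <- tapply(res$normalized, res$region, median)
  expect_equal(unname(by_region["promoter"] / by_region["minus15kb"]),
               attr(ch, "truth")$fold_enrichment, tolerance = 0.25)
})

test_that("percent input does not depend on the input fraction used", {
  # the same chromatin measured with a smaller input aliquot: input Cp
  # rises by the dilution, the dilution correction compensates
  base <- data.frame(region = "prom",
                     antibody = c("input", "H3K4me3", "H3"),
                     cp = c(24, 20, 19), stringsAsFactors = FALSE)
  r1 <- chip_percent_input(base, "H3K4me3", input_fraction = 0.01)
  half <- base
  half$cp[1] <- half$cp[1] + 1   # half the input fraction -> +1 cycle
  r2 <- chip_percent_input(half, "H3K4me3", input_fraction = 0.005)
  expect_equal(r1$pct_input, r2$pct_input, tolerance = 1e-12)
  expect_equal(r1$normalized, r2$normalized, tolerance = 1e-12)
})

test_that("percent lysis subtracts background, floors at zero, stays monotone", {
  expect_equal(percent_lysis(35, 5), 30)
  expect_equal(percent_lysis(5, 5), 0)
  expect_warning(out <- percent_lysis(3, 5), "floored")
  expect_equal(out, 0)
  expect_error(percent_lysis(120, 5), "\\[0, 100\\]")
  e <- c(10, 20, 40, 80)
  expect_true(!is.unsorted(percent_lysis(e, 5)))
})

test_that("single-cell co-expression proportions and undefined cases", {
  tab <- data.frame(subset = rep("S", 4), PRF1 = c(1, 2, 3, 4),
                    TF = c(1, 1, 2, 3), stringsAsFactors = FALSE)
  r <- coexpression_proportions(tab, "PRF1", "TF")
  expect_equal(unname(r$anchor_proportion["S"]), 1)
  expect_equal(unname(r$coexpression["S", "TF"]), 1)
  # no anchor-positive cells -> NA, not 0
  tab0 <- data.frame(subset = "S", PRF1 = 0, TF = 5)
  r0 <- coexpression_proportions(tab0, "PRF1", "TF")
  expect_true(is.na(r0$coexpression["S", "TF"]))
  expect_equal(unname(r0$anchor_proportion["S"]), 0)
})

test_that("planted single-cell proportions are recovered within binomial error", {
  sc <- make_singlecell_fixture(6)
  truth <- attr(sc, "truth")
  r <- coexpression_proportions(sc, "PRF1",
                                names(truth$partner_coexpression),
                                housekeeping = "EEF1A1")
  n <- 43
  for (s in names(truth$prf1_positive)) {
    expect_lt(abs(r$anchor_proportion[s] - truth$prf1_positive[s]),
              3 * sqrt(0.25 / n) + 0.02)
  }
  # joint proportions bounded by the anchor count
  expect_true(all(r$n_anchor_positive <= r$n_cells))
  expect_true(all(r$coexpression >= 0 & r$coexpression <= 1, na.rm = TRUE))
})

test_that("pyrosequencing summaries respect region boundaries", {
  const <- as.data.frame(matrix(100, 3, 34))
  names(const) <- sprintf("CpG_%d", 1:34)
  s <- pyroseq_summary(const)
  expect_true(all(s$per_cpg$median == 100))
  expect_true(all(s$per_cpg$iqr == 0))
  expect_true(all(s$per_region$median == 100))
  # site 15 distal, 16 intermediate, 29 proximal
  step <- const
  step[, sprintf("CpG_%d", 16:28)] <- 50
  step[, sprintf("CpG_%d", 29:34)] <- 10
  s2 <- pyroseq_summary(step)
  pr <- setNames(s2$per_region$median, s2$per_region$region)
  expect_equal(unname(pr["distal"]), 100)
  expect_equal(unname(pr["intermediate"]), 50)
  expect_equal(unname(pr["proximal"]), 10)
  expect_error(pyroseq_summary(const[, -1]), "34 CpG")
})

test_that("planted stepwise demethylation yields monotone region medians", {
  py <- make_pyroseq_fixture(3)
  s <- pyroseq_summary(py, group = "subset")
  inter <- s$per_region[s$per_region$region == "intermediate", ]
  ord <- c("CD4_naive", "CM_Th1", "EM28_Th1", "CD4_CTX")
  med <- inter$median[match(ord, inter$group)]
  expect_true(all(diff(med) < 0))
})

test_that("group-comparison helper wraps the standard cascade", {
  withr::local_seed(15)
  v <- c(rnorm(10, 0), rnorm(10, 3))
  g <- rep(c("a", "b"), each = 10)
  r <- subset_compare(v, g)
  expect_lt(r$omnibus_p, 0.01)
  expect_true(all(dim(r$pairwise) == c(1, 1)))
})
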