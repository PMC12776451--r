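test_that("cross-tabulation builds the carrier-by-phenotype table", {
  samples <- paste0("S", 1:387)
  carrier <- setNames(as.integer(seq_along(samples) <= 27), samples)
  pheno <- setNames(as.integer(seq_along(samples) %in%
                                 c(1:22, 28 + seq_len(209))), samples)
  tab <- twoByTwo(carrier, pheno)
  expect_equal(as.integer(tab), c(22, 5, 209, 151))

  none <- twoByTwo(setNames(rep(0L, 4), paste0("S", 1:4)),
                   setNames(c(1L, 1L, 0L, 0L), paste0("S", 1:4)))
  expect_equal(as.integer(none), c(0, 0, 2, 2))
  allcase <- twoByTwo(setNames(c(1L, 0L), c("A", "B")),
                      setNames(c(1L, 1L), c("A", "B")))
  expect_equal(as.integer(allcase[c("b", "d")]), c(0, 0))
  expect_error(twoByTwo(setNames(1L, "A"), setNames(1L, "B")), "disjoint")
  # samples missing a value are excluded and counted
  tabNA <- twoByTwo(setNames(c(1L, NA, 0L), c("A", "B", "C")),
                    setNames(c(1L, 1L, 0L), c("A", "B", "C")))
  expect_equal(attr(tabNA, "n_excluded"), 1)
})

test_that("odds ratio and Woolf interval reproduce the worked example", {
  r <- oddsRatioCI(c(22, 5, 209, 151))
  expect_equal(round(r$or, 2), 3.18)
  expect_equal(round(r$ci_low, 2), 1.18)
  expect_equal(round(r$ci_high, 1), 8.6)  # computed 8.58; published print 8.59
  expect_false(r$corrected)

  bal <- oddsRatioCI(c(10, 10, 10, 10))
  expect_equal(bal$or, 1)
  expect_equal(log(bal$ci_low), -log(bal$ci_high))  # symmetric on log scale

  hz <- oddsRatioCI(c(5, 0, 10, 10))  # Haldane-Anscombe +0.5
  expect_true(hz$corrected)
  expect_equal(hz$or, (5.5 * 10.5) / (0.5 * 10.5))  # 11.0
  expect_true(oddsRatioCI(c(0, 0, 5, 5))$undefined)
})

test_that("transposing case/control labels inverts the odds ratio and CI", {
  set.seed(14)
  for (i in 1:20) {
    tab <- rpois(4, 20) + 1
    r <- oddsRatioCI(tab)
    ri <- oddsRatioCI(tab[c(3, 4, 1, 2)])
    expect_equal(ri$or, 1 / r$or)
    expect_equal(ri$ci_low, 1 / r$ci_high)
    expect_equal(ri$ci_high, 1 / r$ci_low)
  }
})

test_that("the chi-square test matches the closed form and the reference", {
  flat <- chiSquareP(c(10, 10, 20, 20))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_two_sided, 1)

  r <- chiSquareP(c(22, 5, 209, 151))
  expect_equal(r$chi2, 387 * (22 * 151 - 5 * 209)^2 /
                 (27 * 360 * 231 * 156))   # ~5.73
  expect_equal(round(r$chi2, 2), 5.73)
  expect_equal(r$p_one_sided, r$p_two_sided / 2)  # OR > 1

  set.seed(6)
  for (i in 1:20) {
    tab <- rpois(4, 30) + 6
    mine <- chiSquareP(tab)
    ref <- chisq.test(matrix(tab, 2, byrow = TRUE), correct = FALSE)
    expect_equal(mine$chi2, unname(ref$statistic))
    expect_equal(mine$p_two_sided, ref$p.value)
    # invariant under row and column permutation
    expect_equal(chiSquareP(tab[c(3, 4, 1, 2)])$chi2, mine$chi2)
    expect_equal(chiSquareP(tab[c(2, 1, 4, 3)])$chi2, mine$chi2)
  }
  expect_warning(chiSquareP(c(2, 2, 2, 2)), "expected cell")
  expect_true(suppressWarnings(chiSquareP(c(0, 0, 5, 5))$undefined))
})

test_that("multiple-testing adjustment follows Bonferroni and BH", {
  # smallest of 13 tests at p = 0.006: BH rank 1 -> 0.006 * 13 = 0.078
  p13 <- c(0.006, runif(12, 0.1, 0.9))
  expect_equal(adjustP(p13, "bh")[1], 0.078)
  expect_equal(adjustP(0.006, "bonferroni", m = 13), 0.078)
  expect_equal(adjustP(1, "bh"), 1)
  expect_equal(adjustP(1, "bonferroni"), 1)
  expect_error(adjustP(1.2), "lie in")
  set.seed(3)
  p <- runif(20)
  for (mth in c("bonferroni", "bh")) {
    adj <- adjustP(p, mth)
    expect_true(all(adj >= p))                      # adjusted >= raw
    expect_equal(order(adj[order(p)]), 1:20)        # monotone in raw p
  }
  expect_gte(adjustP(p, "bonferroni")[which.min(p)],
             adjustP(p, "bh")[which.min(p)])
})

test_that("gene load counts distinct genes overlapped by >= 1 bp", {
  genes <- GenomicRanges::GRanges(
    "chr6", IRanges::IRanges(c(31360000, 31440000, 32000000),
                             c(31380000, 31460000, 32100000)),
    name = c("MICA", "HCG26", "FAR")
  )
  calls <- CNVCalls(
    c("S1", "S2", "S3", "S3"), "chr6",
    c(31355318, 33000000, 31455000, 31459000),
    c(31451476, 33100000, 31465000, 31470000),
    "DEL", 20, "A")
  b <- burdenMetrics(calls, genes)
  expect_equal(b$gene_load[b$sample == "S1"], 2)  # MICA + HCG26
  expect_equal(b$gene_load[b$sample == "S2"], 0)  # non-genic region
  # S3: two CNVs partially overlapping the same gene count it once
  expect_equal(b$gene_load[b$sample == "S3"], 1)
  expect_equal(b$n_cnvs, c(1L, 1L, 2L))
  # samples without calls get zero burden
  b4 <- burdenMetrics(calls, genes, samples = c("S1", "S2", "S3", "S4"))
  expect_equal(b4$n_cnvs[b4$sample == "S4"], 0L)
})

test_that("the burden rank test is exact on separated groups and rank-invariant", {
  burdens <- setNames(c(10, 11, 12, 13, 1, 2, 3, 4), paste0("S", 1:8))
  pheno <- setNames(c(1, 1, 1, 1, 0, 0, 0, 0), paste0("S", 1:8))
  r <- burdenTest(burdens, pheno)
  expect_equal(r$p_two_sided, 2 / 70)
  expect_equal(r$mean_cases, 11.5)
  # invariant to monotone transformation
  r2 <- burdenTest(exp(burdens / 3), pheno)
  expect_equal(r2$p_two_sided, r$p_two_sided)
  expect_error(burdenTest(burdens, setNames(rep(1, 8), paste0("S", 1:8))),
               "non-empty")
})

test_that("case-probability solving hits the target prevalence", {
  pr <- solveCaseProbs(0.6, 0.07, 1)
  expect_equal(unname(pr), c(0.6, 0.6))           # OR = 1
  pr2 <- solveCaseProbs(0.6, 27 / 387, 3.18)
  expect_equal(27 / 387 * pr2[["p1"]] + (1 - 27 / 387) * pr2[["p0"]], 0.6,
               tolerance = 1e-9)
  expect_equal(pr2[["p1"]] / (1 - pr2[["p1"]]) /
                 (pr2[["p0"]] / (1 - pr2[["p0"]])), 3.18, tolerance = 1e-6)
  expect_error(solveCaseProbs(1, 0.5, 2), "prevalence")
  # extreme combinations stay feasible because p0 and p1 rise together
  prx <- solveCaseProbs(0.99, 0.5, 1e-9)
  expect_true(all(prx > 0 & prx < 1))
})

test_that("simulation-based power behaves at the null and the limits", {
  null <- powerBySimulation(387, 0.6, 0.07, 1, reps = 4000, seed = 5)
  expect_lt(abs(null$power - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  rare <- powerBySimulation(387, 0.6, 0.0005, 10, reps = 1500, seed = 5)
  expect_lt(rare$power, 0.1)                      # carrier_freq -> 0
  strong <- powerBySimulation(387, 0.6, 0.07, 10, reps = 1500, seed = 5)
  expect_gt(strong$power, 0.9)
})
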