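test_that("the 2x2 exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70)
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1))), 1)
  # independent cross-check on a battery of random tables
  withr::with_seed(21, {
    for (i in 1:25) {
      tab <- matrix(rpois(4, sample(1:12, 1)), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
  expect_warning(p <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4))), "margin")
  expect_equal(p, 1)
})

test_that("the r x 2 exact test equals brute-force enumeration", {
  # agreement with the 2x2 path to numerical identity
  withr::with_seed(8, {
    for (i in 1:10) {
      tab <- matrix(rpois(4, 5) + 1, 2)
      expect_equal(fisher_exact_rxc(tab), fisher_exact_2x2(tab),
                   tolerance = 1e-12)
    }
  })
  # exhaustive: every 3x2 table with N <= 12 drawn from a systematic sweep
  for (n1 in 1:3) for (n2 in 1:3) for (n3 in 1:3) {
    tab <- rbind(c(n1, 4 - n1), c(n2, 4 - n2), c(n3, 4 - n3))
    expect_equal(fisher_exact_rxc(tab), brute_force_rxc(tab),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact_rxc(rbind(c(2, 0), c(0, 2), c(1, 1))), 0.6)
  expect_equal(fisher_exact_rxc(rbind(c(2, 2), c(2, 2))), 1)
  expect_error(fisher_exact_rxc(matrix(1, 9, 2)), "8")
  expect_error(fisher_exact_rxc(matrix(1, 2, 3)), "two-column")
})

test_that("inheritance-model expectations follow the stated formulas", {
  expect_equal(hwe_expected(allele_freqs(0.5), 48),
               c(ZZ = 12, WZ = 24, WW = 12))
  expect_equal(hwe_expected(1, 10), c(ZZ = 10, WZ = 0, WW = 0))
  expect_equal(hwe_expected(0.75, 96), c(ZZ = 54, WZ = 36, WW = 6))
  expect_equal(model_expected("lethal_ww", 0.5, 48),
               c(ZZ = 16, WZ = 32, WW = 0))
  expect_equal(model_expected("female_w", 0.5, 48),
               c(ZZ = 0, WZ = 48, WW = 0))
  expect_equal(model_expected("autosomal", 1, 5), c(ZZ = 5, WZ = 0, WW = 0))
  # totals are preserved exactly, including the lethal renormalization
  for (p in c(0.3, 0.5, 0.8)) for (m in c("autosomal", "lethal_ww",
                                          "female_w")) {
    expect_equal(sum(model_expected(m, p, 48)), 48)
  }
  expect_error(model_expected("dominance", 0.5, 48), "arg")
})

test_that("Pearson goodness of fit handles supported and empty cells", {
  g <- gof_pearson(c(0, 48, 0), c(12, 24, 12), "autosomal")
  expect_equal(g$chi2, 48)
  expect_equal(g$df, 2L)
  expect_equal(g$p, pchisq(48, 2, lower.tail = FALSE))
  # saturated model: df 0, chi2 0, p 1
  g0 <- gof_pearson(c(0, 48, 0), c(0, 48, 0))
  expect_equal(g0$df, 0L)
  expect_equal(g0$p, 1)
  # zero-expected cell with support only where expected: df drops
  gl <- gof_pearson(c(0, 48, 0), c(16, 32, 0))
  expect_equal(gl$chi2, 24)
  expect_equal(gl$df, 1L)
  # observed counts against a zero-expected cell reject outright
  gr <- gof_pearson(c(0, 40, 8), c(0, 48, 0))
  expect_equal(gr$p, 0)
  # invariant to cell order; p decreasing in chi2 at fixed df
  expect_equal(gof_pearson(c(48, 0, 0), c(24, 12, 12))$p,
               gof_pearson(c(0, 0, 48), c(12, 12, 24))$p)
  p_small <- gof_pearson(c(10, 14), c(12, 12))$p
  p_large <- gof_pearson(c(4, 20), c(12, 12))$p
  expect_gt(p_small, p_large)
  expect_error(gof_pearson(c(1, 2), c(1, 2, 3)), "length")
})

test_that("HWE deviation is detected with estimated allele frequencies", {
  h <- hwe_deviation_test(c(ZZ = 48, WZ = 48, WW = 0))
  expect_equal(h$expected, c(ZZ = 54, WZ = 36, WW = 6))
  expect_equal(h$chi2, 32 / 3, tolerance = 1e-12)
  expect_equal(h$df, 1L)
  expect_lt(h$p, 4.2e-3)
  # perfect Hardy-Weinberg proportions: no deviation
  expect_equal(hwe_deviation_test(c(25, 50, 25))$p, 1)
  # maximal deviation at q = 0.5: all homozygotes
  hx <- hwe_deviation_test(c(10, 0, 10))
  expect_equal(hx$chi2, 20)
  expect_lt(hx$p, 1e-4)
  # monomorphic input is untestable
  expect_equal(hwe_deviation_test(c(30, 0, 0))$p, 1)
})

test_that("association scans rank markers and handle degenerate cohorts", {
  cfg <- sim_config(seed = 3, n_females = 30, n_males = 30,
                    sex_reversal_rate = 0)
  markers <- data.frame(name = c("linked", "loose"),
                        recomb_fraction = c(0, 0.4),
                        position_kbp = c(100, 150))
  scan <- association_scan(gen_cohort(cfg, markers), markers)
  expect_equal(scan$results$marker[1], "linked")
  expect_lt(scan$results$p[1], 1e-10)
  expect_gt(scan$results$p[2], scan$results$p[1])
  expect_equal(dim(scan$tables$linked), c(2L, 2L))
  # single-sex cohort: untestable, all p = 1 with a warning
  coh <- gen_cohort(cfg, markers)
  expect_warning(s1 <- association_scan(coh[coh$sex == "F", ], markers),
                 "single-sex")
  expect_true(all(s1$results$p == 1))
  # dominant markers collapse to presence/absence of the W allele
  domm <- data.frame(name = "linked", position_kbp = 100, dominant = TRUE)
  sd <- association_scan(gen_cohort(cfg, markers), domm)
  expect_setequal(rownames(sd$tables$linked), c("P", "A"))
})

test_that("association type-I error is calibrated on null simulations", {
  markers <- data.frame(name = "null_marker", recomb_fraction = 0.5)
  ps <- vapply(1:400, function(s) {
    coh <- gen_cohort(sim_config(seed = s, n_females = 20, n_males = 20,
                                 sex_reversal_rate = 0), markers)
    association_scan(coh, markers)$results$p[1]
  }, numeric(1))
  rate <- mean(ps <= 0.05)
  # exact tests are conservative on discrete tables: at or below nominal,
  # allowing binomial fluctuation
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("one-way ANOVA reproduces the classical F decomposition", {
  r <- anova_oneway(list(c(1, 2), c(3, 4)))
  expect_equal(r$F, 8)
  expect_equal(r$p, pf(8, 1, 2, lower.tail = FALSE))
  expect_equal(unname(r$df), c(1, 2))
  same <- anova_oneway(list(c(1, 2), c(1, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(anova_oneway(list(c(2, 2), c(2, 2))), "undefined")
  # null calibration: p-values uniform under the null
  withr::with_seed(99, {
    ps <- replicate(400, {
      anova_oneway(list(rnorm(8), rnorm(8), rnorm(8)))$p
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  })
})
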