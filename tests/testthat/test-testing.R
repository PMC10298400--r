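test_that("zero-intercept p-value matches the t reference", {
  f <- worked_fit()
  # chained onto the worked regression: t = 1.13389, df = 2
  expect_equal(null_intercept_pvalue(f), 2 * pt(-abs(f$t_intercept), 2))
  expect_equal(null_intercept_pvalue(f), 0.3744568, tolerance = 1e-6)
  expect_equal(null_intercept_pvalue(f),
               lm_oracle(c(1, 0.5, 2.5, 2), c(0, 1, 2, 3))$p_intercept,
               tolerance = 1e-12)

  # t = 0 gives p = 1 by symmetry
  fz <- f; fz$t_intercept <- 0
  expect_equal(null_intercept_pvalue(fz), 1)
  # |t| at the 0.975 quantile of t_20 gives p = 0.05
  fq <- f; fq$df <- 20L; fq$t_intercept <- qt(0.975, 20)
  expect_equal(null_intercept_pvalue(fq), 0.05, tolerance = 1e-12)
  # degenerate fit propagates p = 1
  expect_equal(null_intercept_pvalue(fit_gene_regression(c(1, 1, 1), 1:3)), 1)
})

test_that("alternative p-value is the upper tail of the shifted t statistic", {
  f <- worked_fit()
  expect_equal(alternative_pvalue(f, f$intercept), 0.5)
  lam <- calibrate_lambda(f, 0.35)$lam
  expect_equal(alternative_pvalue(f, lam),
               1 - pt((0.75 - lam) / f$intercept_se, 2), tolerance = 1e-12)
  # CDF limits
  expect_equal(alternative_pvalue(f, -1e12), 0, tolerance = 1e-9)
  expect_equal(alternative_pvalue(f, 1e12), 1, tolerance = 1e-9)
  expect_error(alternative_pvalue(f, Inf), "finite")
  # degenerate fit propagates p = 1
  expect_equal(alternative_pvalue(fit_gene_regression(c(1, 1, 1), 1:3), 0), 1)
  # the two tail directions are complementary
  expect_equal(alternative_pvalue(f, lam, tail = "lower"),
               1 - alternative_pvalue(f, lam, tail = "upper"), tolerance = 1e-12)
  # exact fit (se = 0): decided by the sign of intercept - lambda
  fe <- fit_gene_regression(c(1, 2, 3, 4), 1:4)
  expect_equal(fe$intercept_se, 0)
  expect_equal(alternative_pvalue(fe, fe$intercept - 1), 0)
  expect_equal(alternative_pvalue(fe, fe$intercept + 1), 1)
  expect_equal(alternative_pvalue(fe, fe$intercept), 0.5)
})

test_that("vectorized p-values over a fit table match per-gene calls", {
  set.seed(301)
  d <- tiny_design(n1 = 8, n2 = 9, m = 12, seed = 5)
  fits <- fit_all_genes(d$contrast_B)
  cal <- calibrate_all(fits, 0.35)
  pv <- alternative_pvalue(fits, cal$lambda)
  pn <- null_intercept_pvalue(fits)
  for (j in seq_len(nrow(fits))) {
    expect_equal(pn[j], null_intercept_pvalue(fits[j, ]), tolerance = 1e-14)
    expect_equal(pv[j], alternative_pvalue(fits[j, ], cal$lambda[j]),
                 tolerance = 1e-14)
  }
})

test_that("Bonferroni rejections follow the level/m threshold", {
  expect_identical(bonferroni_reject(c(0.9, 0.9), 0.025), integer(0))
  expect_identical(bonferroni_reject(c(0.01, 0.9, 0.002), 0.025), 3L)
  expect_identical(bonferroni_reject(rep(0, 4), 0.025), 1:4)
  expect_identical(bonferroni_reject(numeric(0), 0.05), integer(0))
  expect_error(bonferroni_reject(c(0.1), 0), "between 0 and 1")
  expect_error(bonferroni_reject(c(-0.1, 0.5), 0.05), "\\[0, 1\\]")
})

test_that("Benjamini-Hochberg step-up matches its definition", {
  expect_identical(bh_reject(c(0.001, 0.013, 0.04, 0.9), 0.05), c(1L, 2L))
  expect_identical(bh_reject(rep(1, 5), 0.05), integer(0))
  expect_identical(bh_reject(0.04, 0.05), 1L)  # m = 1 is a plain level test
  expect_identical(bh_reject(0.06, 0.05), integer(0))
  # ties at the critical value share its fate
  expect_identical(bh_reject(c(0.025, 0.025, 0.9, 0.9), 0.05), c(1L, 2L))
})

test_that("rejection sets match brute-force oracles on random p-vectors", {
  set.seed(302)
  for (i in 1:300) {
    p <- random_pvec()
    lev <- runif(1, 0.01, 0.2)
    bf <- bonferroni_reject(p, lev)
    bh <- bh_reject(p, lev)
    expect_identical(bf, brute_bonferroni(p, lev))
    expect_identical(bh, brute_bh(p, lev))
    # Bonferroni is dominated by BH
    expect_true(all(bf %in% bh))
    # monotonicity: lowering one p-value never shrinks the rejection set
    if (length(p) > 1) {
      k <- sample(length(p), 1)
      p2 <- p; p2[k] <- p2[k] * runif(1)
      expect_true(all(bh %in% bh_reject(p2, lev)))
      expect_true(all(bf %in% bonferroni_reject(p2, lev)))
    }
  }
})

test_that("dual-family evaluation tests each family at alpha/2", {
  set.seed(303)
  tab <- gene_test_table(paste0("g", 1:5),
                         p_null = c(0.0001, 0.2, 0.004, 0.9, 0.012),
                         p_alt = c(0.5, 0.001, 0.002, 0.9, 0.003),
                         lambda = rnorm(5))
  for (corr in c("bh", "bonferroni")) {
    sets <- evaluate_hypotheses(tab, alpha = 0.05, correction = corr)
    fun <- if (corr == "bh") brute_bh else brute_bonferroni
    expect_identical(sets$rejected_null, fun(tab$p_null, 0.025))
    expect_identical(sets$rejected_alt, fun(tab$p_alt, 0.025))
  }
  # all-ones table rejects nothing
  ones <- gene_test_table(paste0("g", 1:4), rep(1, 4), rep(1, 4), rep(0, 4))
  s1 <- evaluate_hypotheses(ones, 0.05)
  expect_length(s1$rejected_null, 0)
  expect_length(s1$rejected_alt, 0)
})

test_that("findings are exactly the intersection of the two rejection sets", {
  tab <- gene_test_table(c("gB", "gA", "gC"),
                         p_null = c(0.001, 0.001, 0.5),
                         p_alt = c(0.001, 0.6, 0.001),
                         lambda = c(-1, -2, -3))
  sets <- structure(list(correction = "bonferroni", alpha = 0.05,
                         rejected_null = c(1L, 2L), rejected_alt = c(1L, 3L)),
                    class = "rejection_sets")
  f <- report_findings(sets, tab)
  expect_identical(f$gene, "gB")
  expect_identical(attr(f, "criterion"), "FWER")
  # disjoint sets give a valid empty report
  sets$rejected_alt <- 3L
  f2 <- report_findings(sets, tab)
  expect_identical(nrow(f2), 0L)
  # findings always within both rejection sets, sorted by gene name
  set.seed(304)
  for (i in 1:20) {
    m <- 15
    tabr <- gene_test_table(sample(paste0("g", sprintf("%02d", 1:m))),
                            runif(m)^3, runif(m)^3, rnorm(m))
    sets <- evaluate_hypotheses(tabr, 0.2, "bh")
    fr <- report_findings(sets, tabr)
    expect_true(all(fr$gene %in% tabr$gene[sets$rejected_null]))
    expect_true(all(fr$gene %in% tabr$gene[sets$rejected_alt]))
    expect_identical(fr$gene, sort(fr$gene))
  }
})
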