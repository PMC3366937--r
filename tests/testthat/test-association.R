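test_that("trend test reproduces published replication-study p-values", {
  t1 <- trend_test(genotype_table_2x3(c(510, 38, 2), c(487, 66, 2)))
  expect_equal(round(t1$p, 3), 0.008)
  t2 <- trend_test(genotype_table_2x3(c(529, 30, 1), c(527, 46, 2)))
  expect_equal(round(t2$p, 3), 0.062)
  # identical case/control distributions: no trend
  t0 <- trend_test(genotype_table_2x3(c(100, 50, 10), c(100, 50, 10)))
  expect_equal(t0$z, 0, tolerance = 1e-12)
  expect_equal(t0$p, 1)
})

test_that("trend statistic matches prop.trend.test and the logistic score test", {
  withr::with_seed(31, {
    for (i in 1:50) {
      tab <- random_2x3()
      mine <- trend_test(tab)
      ref <- suppressWarnings(prop.trend.test(tab$case, tab$case + tab$control,
                                              score = 0:2))
      expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-6)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
    }
  })
})

test_that("allelic OR reproduces the published estimate and its Woolf CI", {
  res <- allelic_or(genotype_table_2x3(c(510, 38, 2), c(487, 66, 2)))
  expect_equal(round(res$or, 2), 1.70)
  expect_equal(round(res$ci, 2), c(1.15, 2.51))
  expect_lt(res$p, 0.01)
  # identical rows give OR 1
  same <- allelic_or(genotype_table_2x3(c(80, 30, 5), c(80, 30, 5)))
  expect_equal(same$or, 1)
  expect_error(allelic_or(genotype_table_2x3(c(50, 0, 0), c(40, 10, 1))),
               class = "hapghost_zero_cell_error")
  cc <- allelic_or(genotype_table_2x3(c(50, 0, 0), c(40, 10, 1)),
                   continuity = TRUE)
  expect_true(is.finite(cc$log_or))
})

test_that("Woolf CI endpoints match the closed form on random tables", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      tab <- random_2x3()
      res <- allelic_or(tab)
      a <- tab$case[2] + 2 * tab$case[3]; b <- 2 * tab$case[1] + tab$case[2]
      cc <- tab$control[2] + 2 * tab$control[3]; d <- 2 * tab$control[1] + tab$control[2]
      lo <- log(a * d / (b * cc)); se <- sqrt(1/a + 1/b + 1/cc + 1/d)
      expect_equal(res$ci, exp(lo + c(-1.96, 1.96) * se), tolerance = 1e-10)
    }
  })
})

test_that("minor allele frequencies match the published genotype tables", {
  expect_equal(round(genotype_maf(c(510, 38, 2))$maf, 3), 0.038)
  expect_equal(round(genotype_maf(c(487, 66, 2))$maf, 3), 0.063)
  expect_equal(round(genotype_maf(c(529, 30, 1))$maf, 3), 0.029)
  # 50/1150 = 0.04348, printed as 0.044 under half-up rounding
  expect_lt(abs(genotype_maf(c(527, 46, 2))$maf - 0.044), 1e-3)
  # carrier-stratum contrast: exact 93/282 vs the printed two-decimal value
  expect_equal(round(genotype_maf(c(49, 91, 1))$maf, 2), 0.33)
  # allele-orientation edge: all homozygous for the counted allele
  flip <- genotype_maf(c(0, 0, 10))
  expect_equal(flip$maf, 0)
  expect_equal(flip$raw_freq, 1)
  expect_true(flip$flipped)
})

test_that("dosage logistic regression matches an independent Newton fit on hard genotypes", {
  withr::with_seed(41, {
    n <- 800
    g <- rbinom(n, 2, 0.25)
    pc <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.5 * g + 0.3 * pc))
    ph <- phenotype_table(sprintf("s%d", 1:n), y,
                          covariates = data.frame(PC1 = pc))
    res <- dose_logistic(g, ph)
    ora <- irls_oracle(y, cbind(g, pc))
    expect_equal(res$log_or, unname(ora$beta[2]), tolerance = 1e-6)
    expect_equal(res$se, unname(ora$se[2]), tolerance = 1e-6)
    expect_lt(res$p, 0.05)
    expect_equal(res$test, "lrt")
  })
})

test_that("a perfectly antisymmetric cohort gives a zero log-odds ratio", {
  d <- c(0.2, 0.8, 1.2, 1.8)
  dose <- c(d, d)          # cases mirror controls exactly
  y <- rep(c(1, 0), each = 4)
  ph <- phenotype_table(sprintf("s%d", 1:8), y)
  res <- dose_logistic(dose, ph)
  expect_equal(res$log_or, 0, tolerance = 1e-8)
})

test_that("degenerate dosage predictors are rejected with typed errors", {
  ph <- phenotype_table(sprintf("s%d", 1:40), rep(c(0, 1), 20))
  expect_error(dose_logistic(rep(1, 40), ph), class = "hapghost_degenerate_error")
  withr::with_seed(8, d <- runif(40, 0, 2))
  expect_error(conditional_logistic(d, list(same = d), ph),
               class = "hapghost_collinearity_error")
  # constant adjustment columns are dropped: fit equals the unadjusted one
  r0 <- dose_logistic(d, ph)
  r1 <- conditional_logistic(d, list(konst = rep(2, 40)), ph)
  expect_equal(r1$log_or, r0$log_or, tolerance = 1e-10)
  expect_equal(r1$p, r0$p, tolerance = 1e-10)
})

test_that("conditioning on the signal source removes a tagged association", {
  withr::with_seed(55, {
    n <- 3000
    g_causal <- rbinom(n, 2, 0.1)
    # tag correlated with the causal variant, no direct effect
    tag <- rbinom(n, 2, plogis(-3 + 2.5 * g_causal))
    y <- rbinom(n, 1, plogis(-1.5 + 0.9 * g_causal))
    ph <- phenotype_table(sprintf("s%d", 1:n), y)
    crude <- dose_logistic(tag, ph)
    adj <- conditional_logistic(tag, list(causal = g_causal), ph)
    expect_lt(crude$p, 0.01)
    expect_gt(adj$p, crude$p)
    expect_equal(adj$conditioned_on, "causal")
  })
})
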