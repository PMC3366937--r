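test_that("identical columns give perfect LD and independent loci give none", {
  withr::with_seed(1, g <- rbinom(2000, 2, 0.3))
  tf <- two_locus_em(g, g)
  expect_lt(tf$f_Ab, 1e-6)
  expect_lt(tf$f_aB, 1e-6)
  expect_equal(ld_stats(tf)$r2, 1, tolerance = 1e-6)
  withr::with_seed(2, {
    a <- rbinom(1e5, 2, 0.3); b <- rbinom(1e5, 2, 0.4)
  })
  expect_lt(ld_stats(two_locus_em(a, b))$r2, 0.01)
  expect_error(two_locus_em(rep(0L, 50), rbinom(50, 2, 0.3)),
               class = "hapghost_degenerate_error")
})

test_that("EM attains the grid-search maximum likelihood on random tables", {
  withr::with_seed(11, {
    for (i in 1:12) {
      fAB <- runif(1, 0.05, 0.5); fAb <- runif(1, 0.05, 1 - fAB - 0.1)
      faB <- runif(1, 0.02, 1 - fAB - fAb - 0.05)
      f <- c(fAB, fAb, faB, 1 - fAB - fAb - faB)
      sim <- sim_from_haps(f, 200, seed = 100 + i)
      g1 <- sim$gm$calls[, 1]; g2 <- sim$gm$calls[, 2]
      fit <- two_locus_em(g1, g2)
      tab <- matrix(as.numeric(table(factor(g1, 0:2), factor(g2, 0:2))), 3, 3)
      expect_gte(fit$loglik, grid_two_locus_loglik(tab) - 1e-6)
    }
  })
})

test_that("r2 from D agrees with the allele-correlation form to 1e-10", {
  withr::with_seed(5, {
    for (i in 1:1000) {
      f <- as.numeric(rmultinom(1, 500, runif(4, 0.05, 1))) / 500
      if (any(f == 0)) next
      pA <- f[1] + f[2]; pB <- f[1] + f[3]
      if (pA %in% c(0, 1) || pB %in% c(0, 1)) next
      st <- ld_stats(f)
      # correlation of allele indicators over exhaustively enumerated haplotypes
      x <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)
      mx <- sum(f * x); my <- sum(f * y)
      r <- sum(f * (x - mx) * (y - my)) /
        sqrt(sum(f * (x - mx)^2) * sum(f * (y - my)^2))
      expect_equal(st$r2, r^2, tolerance = 1e-10)
      expect_lte(abs(st$d_prime), 1 + 1e-9)
    }
  })
})

test_that("complete association and exact equilibrium hit the D-prime bounds", {
  st <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(st$d_prime, 1)
  expect_equal(st$r2, 1)
  st0 <- ld_stats(c(0.12, 0.18, 0.28, 0.42))  # f_AB = pA * pB exactly
  expect_equal(st0$D, 0, tolerance = 1e-12)
  expect_equal(st0$r2, 0, tolerance = 1e-12)
  expect_error(ld_stats(c(1, 0, 0, 0)), class = "hapghost_degenerate_error")
})

test_that("EM frequencies converge to phase-known counting at large n", {
  f <- c(0.35, 0.25, 0.25, 0.15)
  sim <- sim_from_haps(f, 1e4, seed = 9)
  fit <- two_locus_em(sim$gm$calls[, 1], sim$gm$calls[, 2])
  counted <- tabulate(c(sim$h1, sim$h2) + 1L, 4) / (2e4)
  # code bit order: hap code 3 = AB, 1 = Ab(bit1), 2 = aB(bit2), 0 = ab
  expect_lt(abs(fit$f_AB - counted[4]), 3 / sqrt(1e4))
  expect_lt(abs(fit$f_ab - counted[1]), 3 / sqrt(1e4))
})

test_that("ld_matrix composes pairwise EM results and summarizes the upper triangle", {
  sim <- sim_from_haps(c(0.4, 0.2, 0.15, 0.25), 400, seed = 21)
  g3 <- withr::with_seed(22, rbinom(400, 2, 0.25))
  gm <- genotype_matrix(sim$gm$samples,
                        snp_table(c("s1", "s2", "s3"), "chr1", c(10, 20, 30), "A", "G"),
                        cbind(sim$gm$calls, g3))
  lm_ <- ld_matrix(gm)
  expect_true(isSymmetric(lm_$r2))
  expect_equal(unname(diag(lm_$r2)), rep(1, 3))
  st12 <- ld_stats(two_locus_em(gm$calls[, 1], gm$calls[, 2]))
  expect_equal(lm_$r2["s1", "s2"], st12$r2, tolerance = 1e-12)
  expect_equal(lm_$d_prime["s1", "s2"], st12$d_prime, tolerance = 1e-12)
  up <- lm_$r2[upper.tri(lm_$r2)]
  expect_equal(unname(lm_$summary["median_r2"]), unname(quantile(up, 0.5)))
  # duplicated column gives off-diagonal r2 = 1
  gm2 <- genotype_matrix(gm$samples,
                         snp_table(c("x", "y"), "chr1", c(1, 2), "A", "G"),
                         cbind(gm$calls[, 1], gm$calls[, 1]))
  expect_equal(ld_matrix(gm2)$r2["x", "y"], 1, tolerance = 1e-6)
  expect_error(ld_matrix(gm, start = 99999), class = "hapghost_empty_error")
  long <- ld_long(lm_)
  expect_equal(nrow(long), 3)
  expect_named(long, c("snp_i", "snp_j", "D", "Dprime", "r2"))
})
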