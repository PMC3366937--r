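# control-sample haplotype frequency scale of the three-SNP at-risk system:
# codes 0..7 with bit j set when the minor allele is carried at SNP j
freqs_3snp <- c(0.282, 0.019, 0.356, 0.021, 0.049, 0.260, 0.0065, 0.0065)

test_that("single-SNP haplotype frequencies equal allele frequencies exactly", {
  withr::with_seed(2, g <- rbinom(400, 2, 0.3))
  gm <- genotype_matrix(sprintf("s%d", 1:400),
                        snp_table("snp1", "chr1", 1, "A", "G"),
                        matrix(g, ncol = 1))
  hf <- em_haplotypes(gm)
  p <- mean(g) / 2
  minor <- hf$freqs[hf$hap_labels == "G"]
  expect_equal(unname(minor), p, tolerance = 1e-10)
})

test_that("EM recovers the generating frequencies from unphased 3-SNP data", {
  sim <- sim_from_haps(freqs_3snp, 5000, seed = 13)
  hf <- em_haplotypes(sim$gm)
  est <- hf$f_full
  expect_true(all(abs(est[seq_along(freqs_3snp)] - freqs_3snp) < 0.015))
  # log-likelihood is non-decreasing over iterations
  expect_true(all(diff(hf$loglik_trace) > -1e-8))
  # phase-known counting matches EM on the same data
  counted <- tabulate(c(sim$h1, sim$h2) + 1L, 8) / 1e4
  expect_true(all(abs(est - counted) < 0.01))
})

test_that("two-SNP EM agrees with the two-locus routine to 1e-8", {
  sim <- sim_from_haps(c(0.4, 0.25, 0.2, 0.15), 800, seed = 19)
  hf <- em_haplotypes(sim$gm)
  tl <- two_locus_em(sim$gm$calls[, 1], sim$gm$calls[, 2])
  # code 0 = both major = ab; code 3 = both minor = AB
  expect_equal(hf$f_full[1], tl$f_ab, tolerance = 1e-8)
  expect_equal(hf$f_full[4], tl$f_AB, tolerance = 1e-8)
  expect_equal(hf$f_full[2], tl$f_Ab, tolerance = 1e-8)
})

test_that("posterior expected haplotype counts sum to 2 per sample", {
  sim <- sim_from_haps(freqs_3snp, 600, seed = 23)
  calls <- sim$gm$calls
  calls[1:5, 1] <- NA  # partial missingness must not break the accounting
  gm <- genotype_matrix(sim$gm$samples, sim$gm$snps, calls)
  E <- expected_hap_counts(em_haplotypes(gm))
  expect_true(all(abs(rowSums(E) - 2) < 1e-9))
  pp <- phase_posterior(em_haplotypes(gm), gm$samples[3])
  expect_equal(sum(pp$prob), 1, tolerance = 1e-9)
})

test_that("stochastic EM matches deterministic EM within Monte-Carlo error", {
  sim <- sim_from_haps(freqs_3snp, 2000, seed = 29)
  em <- em_haplotypes(sim$gm)
  s1 <- sem_haplotypes(sim$gm, n_iter = 400, burn_in = 100, seed = 1)
  # align by haplotype code
  gap <- abs(s1$f_full - em$f_full)
  mc <- rep(0, length(s1$f_full)); mc[s1$hap_codes + 1L] <- s1$mc_se
  expect_true(all(gap < pmax(3 * mc, 0.01)))
  # seed-to-seed stability within combined Monte-Carlo error
  s2 <- sem_haplotypes(sim$gm, n_iter = 400, burn_in = 100, seed = 2)
  mc2 <- rep(0, length(s2$f_full)); mc2[s2$hap_codes + 1L] <- s2$mc_se
  expect_true(all(abs(s1$f_full - s2$f_full) <
                    pmax(2 * sqrt(mc^2 + mc2^2), 0.01)))
  expect_error(sem_haplotypes(sim$gm, n_iter = 50, burn_in = 10),
               class = "hapghost_validation_error")
})

test_that("single-SNP stochastic EM reduces to allele counting across seeds", {
  withr::with_seed(3, g <- rbinom(500, 2, 0.2))
  gm <- genotype_matrix(sprintf("s%d", 1:500),
                        snp_table("snp1", "chr1", 1, "A", "G"),
                        matrix(g, ncol = 1))
  p <- mean(g) / 2
  for (sd in 1:3) {
    sf <- sem_haplotypes(gm, n_iter = 50, burn_in = 10, seed = sd)
    expect_equal(unname(sf$f_full[2]), p, tolerance = 1e-9)
  }
})

test_that("haplotype-effect model recovers a Table-2-scale risk haplotype", {
  # at-risk haplotype (code 3) at control frequency ~0.021 with a strong
  # case-control contrast, n close to the larger study
  f_ctrl <- freqs_3snp
  f_case <- f_ctrl; f_case[4] <- 0.058
  f_case <- f_case / sum(f_case)
  ors <- vapply(1:10, function(i) {
    s_ctrl <- sim_from_haps(f_ctrl, 1002, seed = 500 + i)
    s_case <- sim_from_haps(f_case, 1542, seed = 600 + i)
    gm <- genotype_matrix(
      c(paste0("ctrl", 1:1002), paste0("case", 1:1542)),
      s_ctrl$gm$snps, rbind(s_ctrl$gm$calls, s_case$gm$calls))
    ph <- phenotype_table(gm$samples, rep(c(0, 1), c(1002, 1542)))
    hm <- haplotype_logistic(em_haplotypes(gm), ph)
    risk <- hm$effects$haplotype == hap_label_for(gm, 3L)
    expect_equal(hm$global_df, length(hm$effects$haplotype))
    hm$effects$or[risk]
  }, numeric(1))
  expect_gte(mean(ors >= 2.0 & ors <= 4.4), 0.9)
})

test_that("global haplotype test is near zero without case-control contrast", {
  sim <- sim_from_haps(freqs_3snp, 1500, seed = 77)
  # deterministic alternating status independent of genotype
  ph <- phenotype_table(sim$gm$samples, rep_len(c(0, 1), 1500))
  hm <- haplotype_logistic(em_haplotypes(sim$gm), ph)
  expect_gt(hm$global_p, 0.05)
  # AIC bookkeeping: 2k - 2 loglik with k = fitted parameters
  expect_equal(hm$aic, 2 * hm$k - 2 * hm$loglik, tolerance = 1e-9)
})

test_that("adjustment on an independent or constant dose leaves effects unchanged", {
  sim <- sim_from_haps(freqs_3snp, 1200, seed = 88)
  withr::with_seed(89, {
    y <- rbinom(1200, 1, 0.4)
    noise <- runif(1200, 0, 2)
  })
  ph <- phenotype_table(sim$gm$samples, y)
  hf <- em_haplotypes(sim$gm)
  hm0 <- haplotype_logistic(hf, ph)
  hm_const <- haplotype_conditional(hf, ph, adjust_dose = list(k = rep(1, 1200)))
  expect_equal(hm_const$effects$log_or, hm0$effects$log_or, tolerance = 1e-9)
  hm_noise <- haplotype_conditional(hf, ph, adjust_dose = list(z = noise))
  expect_equal(hm_noise$effects$log_or, hm0$effects$log_or, tolerance = 0.15)
})

test_that("the AIC scan enumerates all subsets and recovers the causal signal", {
  withr::with_seed(101, {
    res <- vapply(1:10, function(i) {
      n <- 3000
      m <- 9
      calls <- sapply(1:m, function(j) rbinom(n, 2, runif(1, 0.15, 0.4)))
      causal <- 4L
      y <- rbinom(n, 1, plogis(-1.2 + 0.45 * calls[, causal]))
      gm <- genotype_matrix(sprintf("s%d", 1:n),
                            snp_table(sprintf("snp%d", 1:m), "chr1", 1:m, "A", "G"),
                            calls)
      ph <- phenotype_table(gm$samples, y)
      sc <- aic_scan(gm, ph, max_size = 2)
      expect_equal(sc$n_models, choose(m, 1) + choose(m, 2))
      # the winner is drawn from the equivalence set and is maximally
      # parsimonious within it
      expect_true(sc$winner_index %in% sc$equivalence)
      expect_equal(sc$table$size[sc$winner_index],
                   min(sc$table$size[sc$equivalence]))
      win <- sc$table$model[sc$winner_index]
      c(contains = grepl("snp4", win, fixed = TRUE), singleton = win == "snp4")
    }, logical(2))
    expect_true(all(res["contains", ]))
    # noise supersets occasionally displace the singleton from the
    # equivalence set (extra chi-square > penalty + 2), so the strict
    # singleton rate sits below 1
    expect_gte(mean(res["singleton", ]), 0.5)
  })
})

test_that("parsimony tie-breaking picks the smallest, earliest equivalent model", {
  # a duplicated SNP makes {snp1}, {snp2} and {snp1,snp2} carry identical
  # information: the winner must be the first singleton
  withr::with_seed(202, {
    n <- 1200
    g <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * g))
    gm <- genotype_matrix(sprintf("s%d", 1:n),
                          snp_table(c("snpA", "snpB"), "chr1", c(10, 20), "A", "G"),
                          cbind(g, g))
    ph <- phenotype_table(gm$samples, y)
    sc <- aic_scan(gm, ph, max_size = 2)
    expect_equal(sc$table$model[sc$winner_index], "snpA")
    expect_equal(sc$table$size[sc$winner_index], 1)
  })
})

test_that("oversized haplotype spaces and regions are refused", {
  gm <- sim_from_haps(rep(1 / 16, 16), 50, seed = 1)$gm
  big <- genotype_matrix(gm$samples,
                         snp_table(sprintf("s%d", 1:13), "chr1", 1:13, "A", "G"),
                         matrix(rbinom(50 * 13, 2, 0.3), 50, 13))
  expect_error(em_haplotypes(big), class = "hapghost_capacity_error")
  ph <- phenotype_table(gm$samples, rep_len(c(0, 1), 50))
  expect_error(aic_scan(big, ph, scan_cap = 5), class = "hapghost_capacity_error")
})
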