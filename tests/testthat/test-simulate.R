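spec <- default_ghost_spec()

test_that("the default panel specification satisfies its own frequency algebra", {
  expect_equal(sum(spec$class_freqs), 1, tolerance = 1e-12)
  expect_true(all(spec$causal_carriage >= 0 & spec$causal_carriage <= 1))
  causal_maf <- sum(spec$class_freqs * spec$causal_carriage)
  expect_gt(causal_maf, 0.014); expect_lt(causal_maf, 0.021)
  expect_lt(abs(spec$block_maf - 0.03), 0.002)
  # region geometry: causal sits >= 0.6 Mb from the block
  pos_c <- spec$snps$pos[spec$snps$role == "causal"]
  pos_b <- spec$snps$pos[spec$snps$role == "block"]
  expect_gte(min(abs(pos_b - pos_c)), 6e5)
  expect_gte(max(abs(pos_b - pos_c)), 1e6)
  il <- spec_implied_ld(spec)
  expect_gt(il$r2_causal_block, 0.2); expect_lt(il$r2_causal_block, 0.7)
  expect_lt(il$r2_causal_weak_tag, 0.2)
  expect_gt(il$p_risk_class_given_causal, 0.8)
})

test_that("cohort simulation is fully deterministic under its seed", {
  b1 <- simulate_cohort(spec, 120, 120, seed = 42)
  b2 <- simulate_cohort(spec, 120, 120, seed = 42)
  expect_identical(b1$truth$hap1, b2$truth$hap1)
  expect_identical(b1$observed$dose$dose, b2$observed$dose$dose)
  expect_identical(b1$observed$pheno$status, b2$observed$pheno$status)
  b3 <- simulate_cohort(spec, 120, 120, seed = 43)
  expect_false(identical(b1$truth$hap1, b3$truth$hap1))
  # the causal variant never appears among observed array SNPs
  expect_false("causal_rare" %in% b1$observed$genotypes$snps$id)
})

test_that("truth haplotype frequencies recover the class frequencies", {
  b <- simulate_cohort(spec, 60, 1500, seed = 7, or_causal = 1)
  cls <- c(b$truth$class1, b$truth$class2)
  n2 <- length(cls)
  est <- tabulate(cls, 6) / n2
  expect_true(all(abs(est - spec$class_freqs) < 3 / sqrt(n2) + 0.01))
})

test_that("a null causal effect leaves case and control frequencies equal", {
  b <- simulate_cohort(spec, 700, 700, seed = 3, or_causal = 1)
  ph <- b$observed$pheno
  g <- b$truth$causal_geno
  d <- abs(mean(g[ph$status == 1]) - mean(g[ph$status == 0])) / 2
  expect_lt(d, 3 / sqrt(700))
})

test_that("the default cohort reproduces the published frequency regime", {
  b <- simulate_cohort(spec, 1500, 1200, seed = 1)
  ph <- b$observed$pheno
  g <- b$truth$causal_geno
  maf_ctrl <- mean(g[ph$status == 0]) / 2
  maf_case <- mean(g[ph$status == 1]) / 2
  expect_gt(maf_ctrl, 0.008); expect_lt(maf_ctrl, 0.025)
  expect_gt(maf_case, 0.03); expect_lt(maf_case, 0.07)
  # block SNPs sit in near-perfect mutual LD on true haplotypes
  blocks <- which(spec$snps$role == "block")
  H <- rbind(b$truth$hap1[, blocks], b$truth$hap2[, blocks])
  r2 <- cor(H)^2
  expect_gt(min(r2[upper.tri(r2)]), 0.8)
  # typed background shows the low-LD regime
  lm_ <- ld_matrix(b$observed$genotypes, chrom = "chr11")
  expect_lt(lm_$summary["median_r2"], 0.2)
})

test_that("carrier enrichment reproduces the stratified-frequency contrast", {
  ce <- carrier_enriched_controls(spec, n_total = 600, fraction_carriers = 0.4,
                                  seed = 11)
  ph <- ce$observed$pheno
  g <- ce$truth$causal_geno
  carrier <- ph$carrier == 1
  expect_true(all(g[carrier] == 1))
  block_g <- ce$observed$genotypes$calls[, spec$snps$role == "block"][, 1]
  maf_carrier <- mean(block_g[g >= 1]) / 2
  maf_non <- mean(block_g[g == 0]) / 2
  expect_gt(maf_carrier, 0.2)
  expect_lt(maf_non, 0.03)
  # boundary: every control carries exactly one causal allele
  ce1 <- carrier_enriched_controls(spec, n_total = 80, fraction_carriers = 1,
                                   seed = 12)
  expect_true(all(ce1$truth$causal_geno == 1))
  # fraction 0 matches the plain control distribution
  ce0 <- carrier_enriched_controls(spec, n_total = 900, fraction_carriers = 0,
                                   seed = 13)
  b0 <- simulate_cohort(spec, 30, 900, seed = 13)
  f_ce <- mean(ce0$truth$causal_geno) / 2
  f_b <- mean(b0$truth$causal_geno[b0$observed$pheno$status == 0]) / 2
  expect_lt(abs(f_ce - f_b), 0.01)
})

test_that("seeds are mandatory for every stochastic generator entry point", {
  expect_error(simulate_cohort(spec, 10, 10), class = "hapghost_validation_error")
  expect_error(carrier_enriched_controls(spec, 10), class = "hapghost_validation_error")
  expect_error(degrade_to_dosage(c(0, 1, 2), 0.5), class = "hapghost_validation_error")
})
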