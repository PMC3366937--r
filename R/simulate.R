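# Synthetic ghost-signal cohorts.
#
# The generator emulates the statistical geometry of a long-range "ghost"
# association: a ~700 kb block of rare alleles in near-perfect mutual LD,
# carried on an uncommon three-SNP haplotype (the AGT analog) that also
# carries a rare causal variant ~0.6 Mb away; a background of common SNPs in
# weak LD; and imputed dosages whose quality collapses for the rare causal
# variant because its best common tag has r2 of only ~0.15.

#' Ghost-scenario panel specification
#'
#' Returns the default panel specification: six tag-haplotype classes over
#' three common SNPs with an at-risk analog class at population frequency
#' 0.02; twelve block SNPs (population MAF ~0.03) riding that class; one
#' rare causal variant (population MAF 0.018) carried by the at-risk class
#' with probability 0.9; one common weak tag of the causal variant
#' (pairwise r2 ~0.15); and 100 common background SNPs in weak LD
#' (median pairwise r2 ~0.10).
#'
#' @return an object of class `panel_spec`.
#' @export
default_ghost_spec <- function() {
  class_labels <- c("GGT", "GAT", "GAC", "AGT", "AAC", "AAT")
  class_freqs <- c(0.370, 0.282, 0.049, 0.020, 0.260, 0.019)
  # counted-allele (minor) codes per class at the three tag SNPs:
  # tag1 minor = A, tag2 minor = G, tag3 minor = C
  class_alleles <- rbind(
    GGT = c(0, 1, 0), GAT = c(0, 0, 0), GAC = c(0, 0, 1),
    AGT = c(1, 1, 0), AAC = c(1, 0, 1), AAT = c(1, 0, 0)
  )
  colnames(class_alleles) <- c("tag_1", "tag_2", "tag_3")
  # block indicator carriage per class, tuned so the marginal block-allele
  # frequency is ~0.03 while P(block | AGT) stays high
  block_carriage <- c(GGT = 0.0113, GAT = 0.0113, GAC = 0.0113, AGT = 0.95,
                      AAC = 0.0113, AAT = 0.0113)
  block_concordance <- 0.97   # per-SNP copy fidelity of the block indicator
  # the causal allele rides block-bearing haplotypes, preferentially (but
  # not exclusively) those of the at-risk class, so that >80% of causal
  # copies sit on the AGT analog while conditioning on the block still
  # absorbs most of the causal signal
  causal_given_block <- c(GGT = 0.28, GAT = 0.28, GAC = 0.28, AGT = 0.85,
                          AAC = 0.28, AAT = 0.28)
  causal_carriage <- block_carriage * causal_given_block
  n_block <- 12
  n_background <- 100
  block_pos <- round(seq(47373425, 48064194, length.out = n_block))
  tag_pos <- c(47400000, 47650000, 47900000)
  ptag_pos <- c(47500000, 47700000, 47850000)
  causal_pos <- 46761231
  weak_pos <- 46790000
  bg_pos <- round(seq(46600000, 48100000, length.out = n_background))
  bg_maf <- round(seq(0.05, 0.5, length.out = n_background), 4)
  weak_maf <- 0.109
  ptag_maf <- 0.13
  causal_maf <- sum(class_freqs * causal_carriage)
  snps <- snp_table(
    id = c(sprintf("block_%02d", seq_len(n_block)), colnames(class_alleles),
           "causal_rare", "weak_tag", sprintf("ptag_%d", 1:3),
           sprintf("bg_%03d", seq_len(n_background))),
    chrom = "chr11",
    pos = c(block_pos, tag_pos, causal_pos, weak_pos, ptag_pos, bg_pos),
    ref = "A", alt = "G",
    maf = c(rep(0.03, n_block),
            c(0.299, 0.390, 0.309),
            causal_maf, weak_maf, rep(ptag_maf, 3), bg_maf),
    role = c(rep("block", n_block), rep("tag", 3), "causal",
             rep("background", 4 + n_background))
  )
  block_maf <- sum(class_freqs * block_carriage)
  structure(list(
    snps = snps,
    class_labels = class_labels,
    class_freqs = class_freqs,
    class_alleles = class_alleles,
    causal_carriage = causal_carriage,
    causal_given_block = causal_given_block,
    block_carriage = block_carriage,
    block_concordance = block_concordance,
    block_maf = block_maf,
    weak_tag_maf = weak_maf,
    # probability a non-causal haplotype carries the weak-tag minor allele,
    # chosen so the marginal weak-tag frequency is 0.109 while every
    # causal-bearing haplotype carries it (max common-SNP r2 ~0.15)
    weak_tag_leak = (weak_maf - causal_maf) / (1 - causal_maf),
    # partial typed tags of the block indicator (carried whenever the block
    # is), with marginal frequency 0.13 so their LD with the causal variant
    # stays at r2 ~0.13, below the weak tag's ~0.15
    ptag_maf = ptag_maf,
    ptag_leak = (ptag_maf - block_maf) / (1 - block_maf),
    bg_ar = 0.98,               # latent AR(1) coefficient for background LD
    bg_maf = bg_maf,
    or_causal = 3.0,
    prevalence = 0.05
  ), class = "panel_spec")
}

# marginal block-allele frequency implied by the class algebra
spec_block_freq <- function(spec) {
  pB <- sum(spec$class_freqs * spec$block_carriage)
  conc <- spec$block_concordance
  # x = B with prob conc, else a fresh Bernoulli(pB) draw: marginal is pB
  pB
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("panel_spec: %d SNPs (%d block, 3 tag, 1 causal, %d background)\n",
              nrow(x$snps), sum(x$snps$role == "block"),
              sum(x$snps$role == "background")))
  cat(sprintf("at-risk class freq %.3f, causal MAF %.4f, causal OR %.1f\n",
              x$class_freqs[x$class_labels == "AGT"],
              sum(x$class_freqs * x$causal_carriage), x$or_causal))
  invisible(x)
}

#' Analytic LD implied by a panel specification
#'
#' Closed-form haplotype-level r2 between the causal variant and a block
#' SNP, and between the causal variant and its weak common tag, computed
#' from the class frequency algebra (no simulation).
#'
#' @param spec a `panel_spec`.
#' @return list with `r2_causal_block`, `r2_causal_weak_tag`,
#'   `p_risk_class_given_causal`.
#' @export
spec_implied_ld <- function(spec) {
  fc <- spec$class_freqs
  pC <- sum(fc * spec$causal_carriage)
  pB <- spec_block_freq(spec)
  conc <- spec$block_concordance
  # P(block SNP allele = 1 | B) with per-SNP noise refreshing at rate 1-conc
  a1 <- conc + (1 - conc) * pB
  # joint P(causal = 1, block snp = 1): the causal allele only rides
  # block-bearing haplotypes
  f11 <- sum(fc * spec$block_carriage * spec$causal_given_block * a1)
  D <- f11 - pC * pB
  r2_cb <- D^2 / (pC * (1 - pC) * pB * (1 - pB))
  pW <- spec$weak_tag_maf
  f11w <- pC * 1  # every causal haplotype carries the weak-tag allele
  Dw <- f11w - pC * pW
  r2_cw <- Dw^2 / (pC * (1 - pC) * pW * (1 - pW))
  p_risk <- fc[spec$class_labels == "AGT"] * spec$causal_carriage["AGT"] / pC
  list(r2_causal_block = r2_cb, r2_causal_weak_tag = r2_cw,
       p_risk_class_given_causal = unname(p_risk))
}

# draw n phased haplotypes over the structured SNPs (block, tags, causal,
# weak tag); background is drawn separately
draw_structured_haps <- function(spec, n) {
  cls <- sample.int(length(spec$class_freqs), n, replace = TRUE,
                    prob = spec$class_freqs)
  tags <- spec$class_alleles[cls, , drop = FALSE]
  B <- rbinom(n, 1, spec$block_carriage[cls])
  pB <- spec_block_freq(spec)
  n_block <- sum(spec$snps$role == "block")
  block <- matrix(0L, n, n_block)
  for (j in seq_len(n_block)) {
    copy <- rbinom(n, 1, spec$block_concordance)
    block[, j] <- ifelse(copy == 1L, B, rbinom(n, 1, pB))
  }
  causal <- ifelse(B == 1L, rbinom(n, 1, spec$causal_given_block[cls]), 0L)
  weak <- ifelse(causal == 1L, 1L, rbinom(n, 1, spec$weak_tag_leak))
  ptag <- matrix(0L, n, 3)
  for (j in 1:3) ptag[, j] <- ifelse(B == 1L, 1L, rbinom(n, 1, spec$ptag_leak))
  list(cls = cls, tags = tags, block = block, causal = causal, weak = weak,
       ptag = ptag)
}

# n phased background haplotypes from a latent AR(1) threshold model
draw_background_haps <- function(spec, n) {
  m <- length(spec$bg_maf)
  a <- spec$bg_ar
  z <- matrix(0, n, m)
  z[, 1] <- rnorm(n)
  for (j in 2:m) z[, j] <- a * z[, j - 1] + sqrt(1 - a^2) * rnorm(n)
  thr <- qnorm(spec$bg_maf)
  x <- matrix(0L, n, m)
  for (j in seq_len(m)) x[, j] <- as.integer(z[, j] < thr[j])
  x
}

# assemble a full haplotype matrix (columns ordered as spec$snps)
assemble_haps <- function(spec, st, bg) {
  n <- length(st$cls)
  m <- nrow(spec$snps)
  H <- matrix(0L, n, m, dimnames = list(NULL, spec$snps$id))
  H[, spec$snps$role == "block"] <- st$block
  H[, spec$snps$id %in% c("tag_1", "tag_2", "tag_3")] <- st$tags
  H[, spec$snps$id == "causal_rare"] <- st$causal
  H[, spec$snps$id == "weak_tag"] <- st$weak
  H[, spec$snps$id %in% sprintf("ptag_%d", 1:3)] <- st$ptag
  H[, grepl("^bg_\\d", spec$snps$id)] <- bg
  H
}

disease_alpha <- function(spec, or_causal) {
  p <- sum(spec$class_freqs * spec$causal_carriage)
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  beta <- log(or_causal)
  uniroot(function(a) sum(hwe * stats::plogis(a + beta * (0:2))) - spec$prevalence,
          c(-20, 5))$root
}

#' Simulate a ghost-scenario case-control cohort
#'
#' Draws two haplotypes per individual i.i.d. from the panel specification,
#' assigns disease through `logit P(case) = alpha + log(or_causal) * g_causal`
#' with `alpha` set for the spec's population prevalence, and
#' rejection-samples until the case/control quotas are met. The causal
#' variant is recorded in the truth slot but withheld from the observed
#' array genotypes; block SNPs are observed only as imputed dosages
#' (emulated at `spec$block_impute_r2`), and the causal variant's dosage is
#' produced mechanistically by [tag_impute()] from a small phased reference
#' panel using its weak common tag.
#'
#' @param spec a `panel_spec` from [default_ghost_spec()].
#' @param n_cases,n_controls sample quotas.
#' @param or_causal causal allelic odds ratio.
#' @param seed RNG seed; fully determines the output.
#' @param panel_haplotypes reference panel size (chromosomes) for the causal
#'   tag imputation; its small default is what makes the rare causal variant
#'   impute poorly.
#' @param panel_block_haplotypes reference panel size for imputation of the
#'   common-tagged block SNPs (larger, emulating the stability a
#'   haplotype-mosaic imputation achieves for acceptably tagged SNPs).
#' @param study_label study label written into the phenotype table.
#' @param causal_typed if `TRUE`, the causal variant is genotyped on the
#'   array (positive-control scenario): it joins the observed genotypes and
#'   enters the dosage matrix as its true genotype with quality 1.
#' @return an object of class `cohort_bundle` with slots `truth` (phased
#'   haplotype matrices, causal genotype), `observed` (array
#'   [genotype_matrix()], imputed [dosage_matrix()], [phenotype_table()])
#'   and `params`.
#' @export
simulate_cohort <- function(spec = default_ghost_spec(), n_cases = 1500,
                            n_controls = 1200, or_causal = spec$or_causal,
                            seed, panel_haplotypes = 120,
                            panel_block_haplotypes = 800,
                            study_label = "study1", causal_typed = FALSE) {
  if (missing(seed)) stop_hapghost("seed is mandatory", "hapghost_validation_error")
  stopifnot(n_cases > 0, n_controls > 0, or_causal > 0)
  with_seed_(seed, {
    alpha <- disease_alpha(spec, or_causal)
    beta <- log(or_causal)
    need_draws <- ceiling(n_cases / spec$prevalence + n_controls)
    max_draws <- 50 * need_draws
    got_cases <- 0L; got_controls <- 0L; drawn <- 0L
    keep_h1 <- list(); keep_h2 <- list(); keep_status <- list()
    while ((got_cases < n_cases || got_controls < n_controls) && drawn < max_draws) {
      nb <- min(ceiling(1.2 * need_draws), max_draws - drawn)
      h1 <- draw_structured_haps(spec, nb)
      h2 <- draw_structured_haps(spec, nb)
      g <- h1$causal + h2$causal
      status <- rbinom(nb, 1, stats::plogis(alpha + beta * g))
      take_case <- which(status == 1)[seq_len(min(sum(status == 1), n_cases - got_cases))]
      take_ctrl <- which(status == 0)[seq_len(min(sum(status == 0), n_controls - got_controls))]
      take <- c(take_case, take_ctrl)
      sub <- function(st, ix) lapply(st, function(v)
        if (is.matrix(v)) v[ix, , drop = FALSE] else v[ix])
      keep_h1[[length(keep_h1) + 1L]] <- sub(h1, take)
      keep_h2[[length(keep_h2) + 1L]] <- sub(h2, take)
      keep_status[[length(keep_status) + 1L]] <- status[take]
      got_cases <- got_cases + length(take_case)
      got_controls <- got_controls + length(take_ctrl)
      drawn <- drawn + nb
    }
    if (got_cases < n_cases || got_controls < n_controls)
      stop_hapghost("case/control quota unattainable within the draw limit",
                    "hapghost_quota_error")
    cat_st <- function(lst) {
      nms <- names(lst[[1]])
      setNames(lapply(nms, function(nm) {
        parts <- lapply(lst, `[[`, nm)
        if (is.matrix(parts[[1]])) do.call(rbind, parts) else unlist(parts)
      }), nms)
    }
    h1 <- cat_st(keep_h1); h2 <- cat_st(keep_h2)
    status <- unlist(keep_status)
    n <- length(status)
    # background only for retained individuals (independent of phenotype)
    bg1 <- draw_background_haps(spec, n)
    bg2 <- draw_background_haps(spec, n)
    H1 <- assemble_haps(spec, h1, bg1)
    H2 <- assemble_haps(spec, h2, bg2)
    samples <- sprintf("S%05d", seq_len(n))
    rownames(H1) <- rownames(H2) <- samples
    geno_all <- H1 + H2
    # observed array: tags + weak tag + background (block and causal untyped
    # unless causal_typed)
    array_roles <- c("tag", "background", if (causal_typed) "causal")
    array_ix <- which(spec$snps$role %in% array_roles)
    observed_geno <- genotype_matrix(samples, spec$snps[array_ix, , drop = FALSE],
                                     geno_all[, array_ix, drop = FALSE])
    # imputed dosages by reference-panel tag imputation: block SNPs from the
    # typed tag SNPs (so their doses are functions of the typed haplotypes,
    # as for real panel-based imputation), the causal variant from its weak
    # common tags only
    block_ix <- which(spec$snps$role == "block")
    panel_causal <- reference_panel(spec, panel_haplotypes, targets = "causal_rare")
    panel_block <- reference_panel(spec, panel_block_haplotypes,
                                   targets = spec$snps$id[spec$snps$role == "block"])
    block_tags <- c("tag_1", "tag_2", "tag_3", sprintf("ptag_%d", 1:3))
    block_dose <- vapply(spec$snps$id[block_ix], function(sid) {
      tag_impute(cbind(panel_block$haps[, block_tags, drop = FALSE],
                       target = panel_block$haps[, sid]),
                 geno_all[, block_tags, drop = FALSE], target_col = "target")
    }, numeric(n))
    causal_dose <- if (causal_typed) geno_all[, "causal_rare"] * 1.0
    else tag_impute(cbind(panel_causal$haps[, panel_causal$causal_tags,
                                            drop = FALSE],
                          target = panel_causal$haps[, "causal_rare"]),
                    geno_all[, panel_causal$causal_tags, drop = FALSE],
                    target_col = "target")
    dose <- cbind(block_dose, causal_rare = as.numeric(causal_dose))
    dose_snps <- spec$snps[c(block_ix, which(spec$snps$id == "causal_rare")), ,
                           drop = FALSE]
    qual <- vapply(seq_len(ncol(dose)), function(j)
      dosage_quality(dose[, j])$rsq_hat, numeric(1))
    observed_dose <- dosage_matrix(samples, dose_snps, dose, quality = qual)
    pcs <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("PC", 1:4)))
    pheno <- phenotype_table(samples, status, covariates = as.data.frame(pcs),
                             study = study_label)
    structure(list(
      truth = list(hap1 = H1, hap2 = H2, snps = spec$snps,
                   causal_geno = unname(geno_all[, "causal_rare"]),
                   class1 = h1$cls, class2 = h2$cls),
      observed = list(genotypes = observed_geno, dose = observed_dose,
                      pheno = pheno),
      params = list(spec = spec, n_cases = n_cases, n_controls = n_controls,
                    or_causal = or_causal, seed = seed, alpha = alpha,
                    panel_haplotypes = panel_haplotypes,
                    panel_block_haplotypes = panel_block_haplotypes,
                    n_fallback = attr(causal_dose, "n_fallback"))
    ), class = "cohort_bundle")
  })
}

# phased reference panel over all spec SNPs, redrawn until every rare
# imputation target is polymorphic in it
reference_panel <- function(spec, n_hap,
                            targets = c(spec$snps$id[spec$snps$role == "block"],
                                        "causal_rare")) {
  repeat {
    st <- draw_structured_haps(spec, n_hap)
    bg <- draw_background_haps(spec, n_hap)
    Hp <- assemble_haps(spec, st, bg)
    cs <- colSums(Hp[, targets, drop = FALSE])
    if (all(cs > 0 & cs < n_hap)) break
  }
  list(haps = Hp, causal_tags = c("bg_012", "weak_tag", "bg_013"))
}

#' @export
print.cohort_bundle <- function(x, ...) {
  ph <- x$observed$pheno
  cat(sprintf("cohort_bundle: %d cases / %d controls; %d array SNPs, %d imputed SNPs\n",
              sum(ph$status == 1), sum(ph$status == 0),
              ncol(x$observed$genotypes$calls), ncol(x$observed$dose$dose)))
  cat(sprintf("causal MAF (truth): %.4f; causal dosage quality: %.3f\n",
              mean(x$truth$causal_geno) / 2,
              x$observed$dose$quality[x$observed$dose$snps$id == "causal_rare"]))
  invisible(x)
}

#' Simulate a carrier-enriched control series
#'
#' Mixes standard (disease-free) controls with controls conditioned to carry
#' exactly one causal allele, emulating a replication-study control series
#' enriched in healthy mutation carriers. Unlike [simulate_cohort()], the
#' block and causal variants are directly typed here (replication-study
#' genotyping), so the observed genotype matrix carries all SNPs.
#'
#' @param spec a `panel_spec`.
#' @param n_total number of controls.
#' @param fraction_carriers fraction conditioned to carry one causal allele.
#' @param seed RNG seed.
#' @return a `cohort_bundle` (all status 0) whose phenotype table gains a
#'   `carrier` covariate flagging the conditioned individuals.
#' @export
carrier_enriched_controls <- function(spec = default_ghost_spec(), n_total = 800,
                                      fraction_carriers = 0.4, seed) {
  if (missing(seed)) stop_hapghost("seed is mandatory", "hapghost_validation_error")
  stopifnot(fraction_carriers >= 0, fraction_carriers <= 1)
  n_carrier <- round(n_total * fraction_carriers)
  n_std <- n_total - n_carrier
  with_seed_(seed, {
    alpha <- disease_alpha(spec, spec$or_causal)
    beta <- log(spec$or_causal)
    draw_controls <- function(n_needed, force_carrier) {
      out1 <- list(); out2 <- list(); got <- 0L; tries <- 0L
      while (got < n_needed && tries < 200) {
        nb <- max(2 * (n_needed - got), 50)
        h1 <- draw_structured_haps(spec, nb)
        h2 <- draw_structured_haps(spec, nb)
        if (force_carrier) {
          # resample first haplotype from the causal-bearing distribution
          carrier_pool <- function(k) {
            st <- draw_structured_haps(spec, max(ceiling(k / 0.015), 200))
            ix <- which(st$causal == 1L)
            while (length(ix) < k) {
              st2 <- draw_structured_haps(spec, max(ceiling(k / 0.015), 200))
              st <- mapply(function(a, b) if (is.matrix(a)) rbind(a, b) else c(a, b),
                           st, st2, SIMPLIFY = FALSE)
              ix <- which(st$causal == 1L)
            }
            lapply(st, function(v) if (is.matrix(v)) v[ix[seq_len(k)], , drop = FALSE]
                   else v[ix[seq_len(k)]])
          }
          noncarrier_fix <- which(h2$causal == 1L)
          while (length(noncarrier_fix)) {  # second haplotype must be causal-free
            repl <- draw_structured_haps(spec, length(noncarrier_fix))
            ok <- which(repl$causal == 0L)
            for (nm in names(h2)) {
              if (is.matrix(h2[[nm]]))
                h2[[nm]][noncarrier_fix[ok], ] <- repl[[nm]][ok, , drop = FALSE]
              else h2[[nm]][noncarrier_fix[ok]] <- repl[[nm]][ok]
            }
            noncarrier_fix <- which(h2$causal == 1L)
          }
          h1 <- carrier_pool(nb)
        }
        g <- h1$causal + h2$causal
        status <- rbinom(nb, 1, stats::plogis(alpha + beta * g))
        take <- which(status == 0L)
        take <- take[seq_len(min(length(take), n_needed - got))]
        sub <- function(st, ix) lapply(st, function(v)
          if (is.matrix(v)) v[ix, , drop = FALSE] else v[ix])
        out1[[length(out1) + 1L]] <- sub(h1, take)
        out2[[length(out2) + 1L]] <- sub(h2, take)
        got <- got + length(take)
        tries <- tries + 1L
      }
      if (got < n_needed)
        stop_hapghost("control quota unattainable", "hapghost_quota_error")
      cat2 <- function(lst) {
        nms <- names(lst[[1]])
        setNames(lapply(nms, function(nm) {
          parts <- lapply(lst, `[[`, nm)
          if (is.matrix(parts[[1]])) do.call(rbind, parts) else unlist(parts)
        }), nms)
      }
      list(h1 = cat2(out1), h2 = cat2(out2))
    }
    parts <- list()
    if (n_carrier > 0) parts$carrier <- draw_controls(n_carrier, TRUE)
    if (n_std > 0) parts$std <- draw_controls(n_std, FALSE)
    join <- function(nm, side) {
      ps <- lapply(parts, function(p) p[[side]][[nm]])
      if (is.matrix(ps[[1]])) do.call(rbind, ps) else unlist(ps)
    }
    nms <- c("cls", "tags", "block", "causal", "weak", "ptag")
    h1 <- setNames(lapply(nms, join, side = "h1"), nms)
    h2 <- setNames(lapply(nms, join, side = "h2"), nms)
    n <- length(h1$cls)
    carrier_flag <- c(rep(1L, if (n_carrier > 0) n_carrier else 0),
                      rep(0L, if (n_std > 0) n_std else 0))
    bg1 <- draw_background_haps(spec, n)
    bg2 <- draw_background_haps(spec, n)
    H1 <- assemble_haps(spec, h1, bg1)
    H2 <- assemble_haps(spec, h2, bg2)
    samples <- sprintf("C%05d", seq_len(n))
    rownames(H1) <- rownames(H2) <- samples
    geno_all <- H1 + H2
    observed_geno <- genotype_matrix(samples, spec$snps, geno_all)
    pheno <- phenotype_table(samples, rep(0L, n),
                             covariates = data.frame(carrier = carrier_flag),
                             study = "carrier_enriched")
    structure(list(
      truth = list(hap1 = H1, hap2 = H2, snps = spec$snps,
                   causal_geno = unname(geno_all[, "causal_rare"]),
                   class1 = h1$cls, class2 = h2$cls),
      observed = list(genotypes = observed_geno, dose = NULL, pheno = pheno),
      params = list(spec = spec, n_total = n_total,
                    fraction_carriers = fraction_carriers, seed = seed)
    ), class = "cohort_bundle")
  })
}

# ---- dosage degradation ---------------------------------------------------

# expected dosage-variance ratio for the Gaussian-read posterior-mean model
expected_rsq_sigma <- function(sigma, p) {
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  y <- seq(-6 * sigma, 2 + 6 * sigma, length.out = 4001)
  dy <- y[2] - y[1]
  dens <- vapply(0:2, function(g) hwe[g + 1] * dnorm(y, g, sigma), numeric(length(y)))
  m <- rowSums(dens)
  eg <- (dens %*% (0:2)) / pmax(m, 1e-300)
  v <- sum(m * (eg - 2 * p)^2) * dy
  v / (2 * p * (1 - p))
}

#' Degrade true genotypes into imputation-like dosages
#'
#' Emulates imputation of known quality without a reference panel: each
#' genotype is observed through a Gaussian read `y = g + e` whose noise
#' scale is tuned so that the expected dosage-variance quality equals
#' `target_r2`, and the dosage is the HWE-posterior mean `E[g | y]`. Higher
#' `target_r2` gives stochastically higher concordance with truth, and
#' heterozygotes at rare variants smear toward zero, as observed for real
#' rare-variant imputation.
#'
#' @param truth genotype vector or matrix coded 0/1/2.
#' @param target_r2 desired expected quality in (0, 1]; 1 returns the
#'   genotypes exactly.
#' @param seed RNG seed.
#' @return numeric dosage vector/matrix of the same shape.
#' @export
degrade_to_dosage <- function(truth, target_r2, seed) {
  if (missing(seed)) stop_hapghost("seed is mandatory", "hapghost_validation_error")
  if (target_r2 <= 0 || target_r2 > 1)
    stop_hapghost("target_r2 must lie in (0, 1]; use a constant dose explicitly for 0",
                  "hapghost_validation_error")
  g <- as.matrix(truth)
  if (target_r2 == 1) {
    out <- g * 1.0
    return(if (is.matrix(truth)) out else drop(out))
  }
  out <- with_seed_(seed, {
    res <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
    for (j in seq_len(ncol(g))) {
      gj <- g[, j]
      p <- mean(gj, na.rm = TRUE) / 2
      if (p <= 0 || p >= 1) { res[, j] <- gj; next }
      sigma <- uniroot(function(ls) expected_rsq_sigma(exp(ls), p) - target_r2,
                       c(log(1e-3), log(60)), tol = 1e-6)$root
      sigma <- exp(sigma)
      y <- gj + rnorm(length(gj), 0, sigma)
      hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      dens <- vapply(0:2, function(k) hwe[k + 1] * dnorm(y, k, sigma),
                     numeric(length(y)))
      res[, j] <- pmin(pmax((dens %*% (0:2)) / rowSums(dens), 0), 2)
    }
    res
  })
  if (is.matrix(truth)) out else drop(out)
}
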