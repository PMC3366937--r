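#' Two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for two biallelic loci estimated
#' by EM over the double-heterozygote phase ambiguity, assuming
#' Hardy-Weinberg equilibrium. Alleles "A"/"B" denote the counted (alt)
#' alleles at the first and second locus.
#'
#' @param g1,g2 genotype vectors coded 0/1/2 (copies of counted allele),
#'   `NA` allowed; same samples, used pairwise-complete.
#' @param tol convergence tolerance on the maximum absolute frequency change.
#' @param max_iter maximum EM iterations.
#' @return an object of class `two_locus_freqs`: haplotype frequencies
#'   `f_AB`, `f_Ab`, `f_aB`, `f_ab`, allele frequencies, the maximized
#'   log-likelihood and iteration count.
#' @export
two_locus_em <- function(g1, g2, tol = 1e-8, max_iter = 1000) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(g1) < 2)
    stop_hapghost("need at least 2 non-missing genotype pairs", "hapghost_validation_error")
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    stop_hapghost("monomorphic locus: LD undefined", "hapghost_degenerate_error")
  # 3x3 genotype count table, rows g1 = 0..2, cols g2 = 0..2
  n <- table(factor(g1, 0:2), factor(g2, 0:2))
  n <- matrix(as.numeric(n), 3, 3)
  N <- sum(n)
  pA <- sum(n * matrix(0:2, 3, 3)) / (2 * N)
  pB <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  # init at linkage equilibrium
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    # posterior split of the double heterozygote between AB/ab and Ab/aB
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    pi_cis <- if (denom > 0) unname(f["AB"] * f["ab"] / denom) else 0.5
    cAB <- 2 * n[3, 3] + n[3, 2] + n[2, 3] + n[2, 2] * pi_cis
    cAb <- 2 * n[3, 1] + n[3, 2] + n[2, 1] + n[2, 2] * (1 - pi_cis)
    caB <- 2 * n[1, 3] + n[1, 2] + n[2, 3] + n[2, 2] * (1 - pi_cis)
    cab <- 2 * n[1, 1] + n[1, 2] + n[2, 1] + n[2, 2] * pi_cis
    f_new <- c(AB = cAB, Ab = cAb, aB = caB, ab = cab) / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  structure(list(f_AB = unname(f["AB"]), f_Ab = unname(f["Ab"]),
                 f_aB = unname(f["aB"]), f_ab = unname(f["ab"]),
                 p_A = pA, p_B = pB, n = N, iterations = it,
                 converged = delta < tol,
                 loglik = two_locus_loglik(f, n)),
            class = "two_locus_freqs")
}

# multinomial log-likelihood of a 3x3 genotype table given haplotype freqs
# (HWE); rows/cols indexed by counted-allele copies 0..2
two_locus_loglik <- function(f, n) {
  P <- two_locus_geno_probs(f)
  sum(n[n > 0] * log(P[n > 0]))
}

two_locus_geno_probs <- function(f) {
  fAB <- f[[1]]; fAb <- f[[2]]; faB <- f[[3]]; fab <- f[[4]]
  P <- matrix(0, 3, 3)
  P[1, 1] <- fab^2
  P[1, 2] <- 2 * fab * faB
  P[1, 3] <- faB^2
  P[2, 1] <- 2 * fab * fAb
  P[2, 2] <- 2 * (fAB * fab + fAb * faB)
  P[2, 3] <- 2 * faB * fAB
  P[3, 1] <- fAb^2
  P[3, 2] <- 2 * fAb * fAB
  P[3, 3] <- fAB^2
  P
}

#' Linkage disequilibrium statistics from two-locus haplotype frequencies
#'
#' Computes the gametic disequilibrium `D`, the signed normalized `D'` and
#' the squared allelic correlation `r2`.
#'
#' @param freqs a `two_locus_freqs` object or a numeric vector
#'   `(f_AB, f_Ab, f_aB, f_ab)`.
#' @return an object of class `ld_stats` with fields `D`, `d_prime`, `r2`.
#' @export
ld_stats <- function(freqs) {
  if (inherits(freqs, "two_locus_freqs"))
    f <- c(freqs$f_AB, freqs$f_Ab, freqs$f_aB, freqs$f_ab)
  else f <- as.numeric(freqs)
  if (abs(sum(f) - 1) > 1e-6 || any(f < -1e-12))
    stop_hapghost("haplotype frequencies must be non-negative and sum to 1",
                  "hapghost_validation_error")
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop_hapghost("degenerate locus (allele frequency 0 or 1)", "hapghost_degenerate_error")
  D <- f[1] - pA * pB
  d_max <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (D == 0) 0 else D / d_max
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = D, d_prime = d_prime, r2 = r2, p_A = pA, p_B = pB),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("D = %+.4f, D' = %+.3f, r2 = %.3f\n", x$D, x$d_prime, x$r2))
  invisible(x)
}

#' Pairwise LD matrix over a genomic region
#'
#' Applies [two_locus_em()] + [ld_stats()] to every SNP pair in a region and
#' summarizes the upper-triangle r-squared distribution (the paper-style
#' "median and 90th percentile" summary). Percentiles use linear
#' interpolation between order statistics. Monomorphic SNPs in the region
#' are dropped with a warning.
#'
#' @param genotypes a [genotype_matrix()].
#' @param chrom optional chromosome label restricting the region.
#' @param start,end optional closed positional interval `[start, end]`.
#' @param tol,max_iter passed to [two_locus_em()].
#' @return an object of class `ld_matrix`: symmetric matrices `r2`,
#'   `d_prime`, `D`, the SNP table, and `summary` with median and
#'   90th-percentile r-squared.
#' @export
ld_matrix <- function(genotypes, chrom = NULL, start = NULL, end = NULL,
                      tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  snps <- genotypes$snps
  keep <- rep(TRUE, nrow(snps))
  if (!is.null(chrom)) keep <- keep & snps$chrom == chrom
  if (!is.null(start)) keep <- keep & snps$pos >= start
  if (!is.null(end)) keep <- keep & snps$pos <= end
  if (!any(keep)) stop_hapghost("no SNPs in requested region", "hapghost_empty_error")
  calls <- genotypes$calls[, keep, drop = FALSE]
  poly <- apply(calls, 2, function(g) length(unique(g[!is.na(g)])) > 1)
  if (any(!poly)) {
    warning(sprintf("dropping %d monomorphic SNP(s) from LD matrix", sum(!poly)))
    calls <- calls[, poly, drop = FALSE]
  }
  m <- ncol(calls)
  if (m < 2)
    stop_hapghost("need at least 2 polymorphic SNPs in region", "hapghost_validation_error")
  ids <- colnames(calls)
  r2 <- dp <- Dm <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  diag(r2) <- 1; diag(dp) <- 1; diag(Dm) <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      st <- ld_stats(two_locus_em(calls[, i], calls[, j], tol, max_iter))
      r2[i, j] <- r2[j, i] <- st$r2
      dp[i, j] <- dp[j, i] <- st$d_prime
      Dm[i, j] <- Dm[j, i] <- st$D
    }
  }
  upper <- r2[upper.tri(r2)]
  structure(list(r2 = r2, d_prime = dp, D = Dm,
                 snps = snps[keep, , drop = FALSE][poly, , drop = FALSE],
                 summary = c(median_r2 = unname(quantile(upper, 0.5, type = 7)),
                             p90_r2 = unname(quantile(upper, 0.9, type = 7)))),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d SNPs; median r2 = %.3f, 90th percentile r2 = %.3f\n",
              nrow(x$r2), x$summary["median_r2"], x$summary["p90_r2"]))
  invisible(x)
}

#' Long-format LD table
#'
#' @param x an `ld_matrix`.
#' @return data.frame with columns `snp_i`, `snp_j`, `D`, `Dprime`, `r2`.
#' @export
ld_long <- function(x) {
  stopifnot(inherits(x, "ld_matrix"))
  idx <- which(upper.tri(x$r2), arr.ind = TRUE)
  data.frame(snp_i = rownames(x$r2)[idx[, 1]], snp_j = colnames(x$r2)[idx[, 2]],
             D = x$D[idx], Dprime = x$d_prime[idx], r2 = x$r2[idx],
             stringsAsFactors = FALSE)
}
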