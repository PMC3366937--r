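# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# two-stage grid search maximizing the two-locus multinomial log-likelihood
# over the haplotype-frequency simplex (f_AB, f_Ab, f_aB; f_ab implied)
grid_two_locus_loglik <- function(n_tab, step1 = 0.01, step2 = 5e-4) {
  loglik_f <- function(fAB, fAb, faB) {
    fab <- 1 - fAB - fAb - faB
    P11 <- fab^2; P12 <- 2 * fab * faB; P13 <- faB^2
    P21 <- 2 * fab * fAb; P22 <- 2 * (fAB * fab + fAb * faB); P23 <- 2 * faB * fAB
    P31 <- fAb^2; P32 <- 2 * fAb * fAB; P33 <- fAB^2
    P <- cbind(P11, P12, P13, P21, P22, P23, P31, P32, P33)
    nv <- as.numeric(t(n_tab))
    lp <- log(pmax(P, 1e-300))
    drop(lp %*% nv)
  }
  search <- function(lo, hi, step) {
    g <- seq(max(lo[1], 0), min(hi[1], 1), by = step)
    best <- -Inf; arg <- NULL
    for (fAB in g) {
      g2 <- seq(max(lo[2], 0), min(hi[2], 1 - fAB), by = step)
      for (fAb in g2) {
        g3 <- seq(max(lo[3], 0), min(hi[3], 1 - fAB - fAb), by = step)
        if (!length(g3)) next
        ll <- loglik_f(fAB, fAb, g3)
        i <- which.max(ll)
        if (ll[i] > best) { best <- ll[i]; arg <- c(fAB, fAb, g3[i]) }
      }
    }
    list(best = best, arg = arg)
  }
  s1 <- search(c(0, 0, 0), c(1, 1, 1), step1)
  s2 <- search(s1$arg - 2 * step1, s1$arg + 2 * step1, step2)
  max(s1$best, s2$best)
}

# hand-rolled Newton-Raphson logistic regression (intercept + columns of X)
irls_oracle <- function(y, X, max_iter = 50) {
  Xi <- cbind(1, X)
  b <- rep(0, ncol(Xi))
  for (i in seq_len(max_iter)) {
    eta <- drop(Xi %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- drop(t(Xi) %*% (y - mu))
    info <- t(Xi) %*% (Xi * W)
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  list(beta = b, se = sqrt(diag(solve(info))))
}

# random case-control genotype-count tables with all rows positive
random_2x3 <- function() {
  p <- runif(1, 0.05, 0.45)
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  ctrl <- as.numeric(rmultinom(1, sample(150:400, 1), hw))
  cs <- as.numeric(rmultinom(1, sample(150:400, 1), hw * c(1, 1.3, 1.6)))
  genotype_table_2x3(ctrl + 1, cs + 1)
}

# small genotype_matrix drawn from known haplotype frequencies (phase known)
sim_from_haps <- function(freqs, n, seed) {
  k <- round(log2(length(freqs)))
  withr::with_seed(seed, {
    h1 <- sample(seq_along(freqs) - 1L, n, TRUE, prob = freqs)
    h2 <- sample(seq_along(freqs) - 1L, n, TRUE, prob = freqs)
    calls <- sapply(seq_len(k), function(j)
      bitwAnd(bitwShiftR(h1, j - 1L), 1L) + bitwAnd(bitwShiftR(h2, j - 1L), 1L))
    list(gm = genotype_matrix(sprintf("s%d", 1:n),
                              snp_table(sprintf("snp%d", 1:k), "chr1", 1:k, "A", "G"),
                              calls),
         h1 = h1, h2 = h2)
  })
}

# allele-string label of an integer haplotype code over a genotype matrix
hap_label_for <- function(gm, code) {
  paste(ifelse(bitwAnd(bitwShiftR(code, 0:(nrow(gm$snps) - 1)), 1L) == 1,
               gm$snps$alt, gm$snps$ref), collapse = "")
}
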