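# Haplotypes are coded as integers in [0, 2^k) with bit j-1 set when the
# counted (minor/alt) allele is carried at the j-th SNP of the subset.

# per-site ordered allele-pair options for a genotype code
site_options <- function(g) {
  if (is.na(g)) cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 0L, 1L))
  else if (g == 0L) cbind(a = 0L, b = 0L)
  else if (g == 2L) cbind(a = 1L, b = 1L)
  else cbind(a = c(0L, 1L), b = c(1L, 0L))
}

# all ordered haplotype pairs compatible with a genotype pattern
hap_pairs <- function(pattern) {
  h1 <- 0L; h2 <- 0L
  for (j in seq_along(pattern)) {
    opt <- site_options(pattern[j])
    bit <- bitwShiftL(1L, j - 1L)
    n_old <- length(h1); n_opt <- nrow(opt)
    h1 <- rep(h1, times = n_opt) + rep(opt[, "a"] * bit, each = n_old)
    h2 <- rep(h2, times = n_opt) + rep(opt[, "b"] * bit, each = n_old)
  }
  cbind(h1 = h1, h2 = h2)
}

hap_label <- function(code, snps) {
  k <- nrow(snps)
  bits <- bitwAnd(bitwShiftR(rep(code, each = k), seq_len(k) - 1L), 1L)
  alle <- ifelse(bits == 1L, rep(snps$alt, length(code)), rep(snps$ref, length(code)))
  apply(matrix(alle, nrow = k), 2, paste, collapse = "")
}

# aggregate genotype rows into unique patterns with counts and pair caches
build_patterns <- function(calls) {
  n <- nrow(calls); k <- ncol(calls)
  if (k > 12)
    stop_hapghost("haplotype space too large: at most 12 SNPs supported",
                  "hapghost_capacity_error")
  all_missing <- rowSums(is.na(calls)) == k
  n_skipped <- sum(all_missing)
  if (n_skipped) {
    warning(sprintf("skipping %d sample(s) with all-missing genotypes", n_skipped))
    calls <- calls[!all_missing, , drop = FALSE]
  }
  if (nrow(calls) < 10)
    stop_hapghost("need at least 10 samples with genotype data", "hapghost_validation_error")
  key <- apply(calls, 1, paste, collapse = ",")
  u <- unique(key)
  idx <- match(key, u)
  patterns <- lapply(u, function(s) {
    v <- strsplit(s, ",", fixed = TRUE)[[1]]
    suppressWarnings(as.integer(v))
  })
  list(pairs = lapply(patterns, hap_pairs),
       counts = as.numeric(tabulate(idx, length(u))),
       sample_pattern = idx, n = nrow(calls), k = k,
       kept = which(!all_missing), n_skipped = n_skipped)
}

# linkage-equilibrium initial frequencies from marginal allele frequencies
init_freqs <- function(calls) {
  k <- ncol(calls)
  p <- vapply(seq_len(k), function(j) {
    g <- calls[, j]
    mean(g, na.rm = TRUE) / 2
  }, numeric(1))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  H <- bitwShiftL(1L, k)
  codes <- 0:(H - 1L)
  f <- rep(1, H)
  for (j in seq_len(k)) {
    bit <- bitwAnd(bitwShiftR(codes, j - 1L), 1L)
    f <- f * ifelse(bit == 1L, p[j], 1 - p[j])
  }
  f
}

em_pass <- function(pat, f) {
  H <- length(f)
  tally <- numeric(H)
  loglik <- 0
  for (i in seq_along(pat$pairs)) {
    pr <- pat$pairs[[i]]
    w <- f[pr[, 1] + 1L] * f[pr[, 2] + 1L]
    s <- sum(w)
    if (s <= 0) next
    loglik <- loglik + pat$counts[i] * log(s)
    post <- (w / s) * pat$counts[i]
    t1 <- rowsum(post, pr[, 1], reorder = FALSE)
    t2 <- rowsum(post, pr[, 2], reorder = FALSE)
    tally[as.integer(rownames(t1)) + 1L] <- tally[as.integer(rownames(t1)) + 1L] + t1[, 1]
    tally[as.integer(rownames(t2)) + 1L] <- tally[as.integer(rownames(t2)) + 1L] + t2[, 1]
  }
  list(tally = tally, loglik = loglik)
}

#' Multi-locus haplotype frequencies by deterministic EM
#'
#' Maximum-likelihood haplotype frequencies for up to 12 SNPs from unphased
#' genotypes under Hardy-Weinberg equilibrium, with the per-sample phase
#' posterior. Haplotypes whose frequency falls below `prune_threshold` are
#' zeroed between iterations. The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param genotypes a [genotype_matrix()] restricted to the SNP subset of
#'   interest (at most 12 SNPs).
#' @param tol convergence tolerance on the maximum absolute frequency change.
#' @param max_iter maximum EM iterations.
#' @param prune_threshold haplotype frequencies below this are set to zero
#'   between iterations.
#' @return an object of class `haplotype_freqs`: haplotype codes, labels,
#'   frequencies, log-likelihood trace, and the cached phase structures used
#'   by [expected_hap_counts()] and [phase_posterior()].
#' @export
em_haplotypes <- function(genotypes, tol = 1e-8, max_iter = 1000,
                          prune_threshold = 1e-4) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  calls <- genotypes$calls
  pat <- build_patterns(calls)
  f <- init_freqs(calls[pat$kept, , drop = FALSE])
  loglik_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    pass <- em_pass(pat, f)
    f_new <- pass$tally / (2 * pat$n)
    f_new[f_new < prune_threshold] <- 0
    f_new <- f_new / sum(f_new)
    loglik_trace <- c(loglik_trace, pass$loglik)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  new_haplotype_freqs(genotypes, pat, f, loglik_trace,
                      converged = delta < tol, method = "em")
}

new_haplotype_freqs <- function(genotypes, pat, f, loglik_trace, converged,
                                method, mc_se = NULL) {
  keep <- which(f > 0)
  codes <- keep - 1L
  ord <- order(f[keep], decreasing = TRUE)
  structure(list(
    snp_ids = genotypes$snps$id,
    snps = genotypes$snps,
    hap_codes = codes[ord],
    hap_labels = hap_label(codes[ord], genotypes$snps),
    freqs = unname(f[keep][ord]),
    f_full = f,
    loglik = if (length(loglik_trace)) loglik_trace[length(loglik_trace)] else NA_real_,
    loglik_trace = loglik_trace,
    converged = converged,
    method = method,
    mc_se = mc_se,
    pat = pat,
    samples = genotypes$samples[pat$kept],
    n_skipped = pat$n_skipped
  ), class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf("haplotype_freqs (%s): %d SNPs, %d haplotypes, loglik %.2f\n",
              x$method, length(x$snp_ids), length(x$freqs), x$loglik))
  print(data.frame(haplotype = x$hap_labels, freq = round(x$freqs, 4)))
  invisible(x)
}

#' Multi-locus haplotype frequencies by stochastic EM
#'
#' Replaces the E-step of [em_haplotypes()] with sampling: each iteration
#' draws one compatible haplotype pair per individual from the current
#' posterior (S-step), then sets the frequencies to the sampled haplotype
#' counts over 2n chromosomes (M-step). The reported frequencies are the
#' mean over post-burn-in iterations, with a naive Monte-Carlo standard
#' error per haplotype.
#'
#' @inheritParams em_haplotypes
#' @param n_iter total iterations.
#' @param burn_in iterations discarded before averaging.
#' @param seed mandatory RNG seed (no hidden global RNG state is consumed).
#' @return a `haplotype_freqs` object (`method = "sem"`) with `mc_se`.
#' @export
sem_haplotypes <- function(genotypes, n_iter = 500, burn_in = 100, seed,
                           prune_threshold = 1e-4) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (missing(seed)) stop_hapghost("seed is mandatory for sem_haplotypes",
                                   "hapghost_validation_error")
  calls <- genotypes$calls
  pat <- build_patterns(calls)
  f <- init_freqs(calls[pat$kept, , drop = FALSE])
  H <- length(f)
  with_seed_(seed, {
    acc <- numeric(H); acc2 <- numeric(H); n_kept <- 0L
    for (it in seq_len(n_iter)) {
      tally <- numeric(H)
      for (i in seq_along(pat$pairs)) {
        pr <- pat$pairs[[i]]
        w <- f[pr[, 1] + 1L] * f[pr[, 2] + 1L]
        s <- sum(w)
        cnt <- if (s > 0) drop(rmultinom(1, pat$counts[i], w / s))
               else drop(rmultinom(1, pat$counts[i], rep(1, nrow(pr))))
        nz <- which(cnt > 0)
        for (j in nz) {
          tally[pr[j, 1] + 1L] <- tally[pr[j, 1] + 1L] + cnt[j]
          tally[pr[j, 2] + 1L] <- tally[pr[j, 2] + 1L] + cnt[j]
        }
      }
      f <- tally / (2 * pat$n)
      if (it > burn_in) {
        acc <- acc + f; acc2 <- acc2 + f^2; n_kept <- n_kept + 1L
      }
    }
    f_mean <- acc / n_kept
    mc_var <- pmax(acc2 / n_kept - f_mean^2, 0)
    mc_se_full <- sqrt(mc_var / n_kept)
  })
  f_mean[f_mean < prune_threshold] <- 0
  f_mean <- f_mean / sum(f_mean)
  pass <- em_pass(pat, f_mean)
  out <- new_haplotype_freqs(genotypes, pat, f_mean, pass$loglik,
                             converged = TRUE, method = "sem")
  out$mc_se <- mc_se_full[out$hap_codes + 1L]
  out
}

#' Posterior expected haplotype counts per sample
#'
#' For each retained sample, the expected number of copies (0-2) of each
#' haplotype given the unphased genotype and the fitted frequencies. Rows
#' sum to 2.
#'
#' @param fit a `haplotype_freqs` object.
#' @return numeric matrix, samples by haplotypes (columns named by label).
#' @export
expected_hap_counts <- function(fit) {
  stopifnot(inherits(fit, "haplotype_freqs"))
  pat <- fit$pat
  f <- fit$f_full
  H <- length(fit$hap_codes)
  code_col <- integer(length(f)); code_col[fit$hap_codes + 1L] <- seq_len(H)
  E_pat <- matrix(0, length(pat$pairs), H)
  for (i in seq_along(pat$pairs)) {
    pr <- pat$pairs[[i]]
    w <- f[pr[, 1] + 1L] * f[pr[, 2] + 1L]
    s <- sum(w)
    if (s <= 0) { # pattern incompatible with pruned freqs: fall back to uniform
      w <- rep(1, nrow(pr)); s <- nrow(pr)
    }
    post <- w / s
    for (j in seq_len(nrow(pr))) {
      c1 <- code_col[pr[j, 1] + 1L]; c2 <- code_col[pr[j, 2] + 1L]
      if (c1 > 0) E_pat[i, c1] <- E_pat[i, c1] + post[j]
      if (c2 > 0) E_pat[i, c2] <- E_pat[i, c2] + post[j]
    }
  }
  E <- E_pat[pat$sample_pattern, , drop = FALSE]
  dimnames(E) <- list(fit$samples, fit$hap_labels)
  E
}

#' Per-sample phase posterior
#'
#' @param fit a `haplotype_freqs` object.
#' @param sample sample identifier.
#' @return data.frame of compatible (unordered) haplotype pairs with
#'   posterior probabilities summing to 1.
#' @export
phase_posterior <- function(fit, sample) {
  stopifnot(inherits(fit, "haplotype_freqs"))
  i <- match(sample, fit$samples)
  if (is.na(i)) stop_hapghost("unknown sample id", "hapghost_lookup_error")
  pr <- fit$pat$pairs[[fit$pat$sample_pattern[i]]]
  f <- fit$f_full
  w <- f[pr[, 1] + 1L] * f[pr[, 2] + 1L]
  if (sum(w) <= 0) w <- rep(1, nrow(pr))
  key <- paste(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  agg <- rowsum(w / sum(w), key, reorder = FALSE)
  pair <- do.call(rbind, strsplit(rownames(agg), " "))
  data.frame(hap1 = hap_label(as.integer(pair[, 1]), fit$snps),
             hap2 = hap_label(as.integer(pair[, 2]), fit$snps),
             prob = agg[, 1], row.names = NULL, stringsAsFactors = FALSE)
}

# ---- haplotype-effect logistic model --------------------------------------

glmfit_matrix <- function(y, X) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- glm.fit(Xi, y, family = binomial())
  p <- fit$rank
  Qr <- fit$qr
  cov_unscaled <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, ncol(Xi))
  se[Qr$pivot[seq_len(p)]] <- sqrt(diag(cov_unscaled))
  names(se) <- colnames(Xi)
  list(coef = coef(fit), se = se, deviance = fit$deviance, rank = p,
       aic = fit$aic, converged = fit$converged)
}

#' Haplotype-effect logistic regression
#'
#' Fits `logit P(case) = a + sum_h b_h E[n_h | genotype] + c'covariates`
#' where `E[n_h | genotype]` is the posterior expected count (0-2) of
#' haplotype `h` (expectation-substitution regression). The reference is the
#' most frequent haplotype; haplotypes rarer than `pool_threshold` are
#' merged into a pooled-rare term. The global test is the likelihood-ratio
#' test of all haplotype effects jointly, with one degree of freedom per
#' modelled non-reference haplotype term.
#'
#' @param fit a `haplotype_freqs` object from [em_haplotypes()] or
#'   [sem_haplotypes()].
#' @param pheno a [phenotype_table()] covering the retained samples.
#' @param covariates covariate column names in `pheno`.
#' @param pool_threshold haplotypes below this overall frequency are pooled.
#' @param adjust optional named list of adjustment columns (e.g. an imputed
#'   dose) aligned to `pheno`; constant columns are dropped.
#' @return an object of class `haplotype_model` with per-haplotype log-ORs,
#'   case/control frequencies, the global chi-square test, log-likelihood
#'   and AIC.
#' @export
haplotype_logistic <- function(fit, pheno, covariates = covariate_names(pheno),
                               pool_threshold = 0.01, adjust = NULL) {
  stopifnot(inherits(fit, "haplotype_freqs"), inherits(pheno, "phenotype_table"))
  E <- expected_hap_counts(fit)
  ph <- pheno[match(rownames(E), pheno$sample), , drop = FALSE]
  if (anyNA(ph$sample))
    stop_hapghost("phenotype table does not cover all genotyped samples",
                  "hapghost_validation_error")
  freqs <- fit$freqs
  labels <- fit$hap_labels
  # reference: most frequent haplotype; ties broken lexicographically
  top <- which(freqs == max(freqs))
  if (length(top) > 1) {
    warning("reference haplotype tie resolved lexicographically")
    top <- top[order(labels[top])]
  }
  ref <- top[1]
  common <- setdiff(which(freqs >= pool_threshold), ref)
  rare <- setdiff(which(freqs < pool_threshold), ref)
  X <- E[, common, drop = FALSE]
  hap_terms <- labels[common]
  if (length(rare)) {
    X <- cbind(X, `rare_pooled` = rowSums(E[, rare, drop = FALSE]))
    hap_terms <- c(hap_terms, "rare_pooled")
  }
  colnames(X) <- hap_terms
  adj_names <- character(0)
  if (!is.null(adjust)) {
    if (!is.list(adjust)) adjust <- list(adjust = adjust)
    A <- do.call(cbind, lapply(adjust, function(a) a[match(rownames(E), pheno$sample)]))
    colnames(A) <- names(adjust) %||% paste0("adjust", seq_along(adjust))
    keep_col <- apply(A, 2, function(a) var(a, na.rm = TRUE) > 0)
    A <- A[, keep_col, drop = FALSE]
    adj_names <- colnames(A)
    if (ncol(A)) X <- cbind(X, A)
  }
  if (length(covariates)) X <- cbind(X, as.matrix(ph[covariates]))
  y <- ph$status
  full <- glmfit_matrix(y, X)
  X0 <- X[, setdiff(colnames(X), hap_terms), drop = FALSE]
  null <- glmfit_matrix(y, X0)
  chi2 <- null$deviance - full$deviance
  df <- length(hap_terms)
  beta <- full$coef[hap_terms]
  se <- full$se[hap_terms]
  effects <- data.frame(
    haplotype = hap_terms,
    freq = c(freqs[common], if (length(rare)) sum(freqs[rare])),
    log_or = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_lo = exp(unname(beta - 1.96 * se)),
    ci_hi = exp(unname(beta + 1.96 * se)),
    p = 2 * pnorm(-abs(unname(beta / se))),
    stringsAsFactors = FALSE
  )
  loglik <- -full$deviance / 2 + binomial_sat_loglik(y)
  k <- full$rank
  structure(list(
    snp_ids = fit$snp_ids,
    haplotypes = labels, freqs = freqs,
    freq_cases = colMeans(E[y == 1, , drop = FALSE]) / 2,
    freq_controls = colMeans(E[y == 0, , drop = FALSE]) / 2,
    reference = labels[ref],
    effects = effects,
    global_chi2 = chi2, global_df = df,
    global_p = pchisq(chi2, df, lower.tail = FALSE),
    loglik = loglik, aic = 2 * k - 2 * loglik, k = k,
    covariates = covariates, conditioned_on = adj_names,
    n = length(y)
  ), class = "haplotype_model")
}

# log-likelihood of the saturated binomial model is 0 for 0/1 outcomes,
# so -deviance/2 is the model log-likelihood
binomial_sat_loglik <- function(y) 0

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("haplotype_model over %s (reference %s)\n",
              paste(x$snp_ids, collapse = ", "), x$reference))
  eff <- x$effects
  eff$or_ci <- sprintf("%.2f [%.2f-%.2f]", eff$or, eff$ci_lo, eff$ci_hi)
  print(data.frame(haplotype = eff$haplotype, freq = round(eff$freq, 3),
                   `OR [95%CI]` = eff$or_ci, p = signif(eff$p, 3),
                   check.names = FALSE))
  cat(sprintf("global test: chi2 = %.2f with %d df, p = %s\n",
              x$global_chi2, x$global_df, fmt_num(x$global_p)))
  if (length(x$conditioned_on))
    cat("  adjusted for:", paste(x$conditioned_on, collapse = ", "), "\n")
  invisible(x)
}

#' Covariate-adjusted haplotype analysis
#'
#' Convenience wrapper around [haplotype_logistic()] adding one or more
#' adjustment dosage columns, as used to test whether a haplotype
#' association survives conditioning on a candidate culprit variant.
#'
#' @inheritParams haplotype_logistic
#' @param adjust_dose a dosage/genotype column or named list of them,
#'   aligned to `pheno`.
#' @return a `haplotype_model`.
#' @export
haplotype_conditional <- function(fit, pheno, adjust_dose,
                                  covariates = covariate_names(pheno),
                                  pool_threshold = 0.01) {
  haplotype_logistic(fit, pheno, covariates = covariates,
                     pool_threshold = pool_threshold, adjust = adjust_dose)
}

# ---- AIC model search -----------------------------------------------------

#' Exhaustive AIC scan over 1- to 4-SNP haplotype models
#'
#' Estimates haplotype frequencies ([em_haplotypes()]) and fits the
#' haplotype-effect logistic model for every SNP subset of size 1 to
#' `max_size` within a region, then ranks models by AIC rescaled to the
#' minimum. Models with rescaled AIC at most 2 form the equivalence set; the
#' winner is the equivalent model with the fewest SNPs, ties broken by fewer
#' modelled haplotypes then lexicographically by positions.
#'
#' @param genotypes a [genotype_matrix()].
#' @param pheno a [phenotype_table()].
#' @param covariates covariate names entered in every model (the AIC
#'   parameter count includes them; being constant across models they do not
#'   affect ranking).
#' @param max_size largest SNP subset size (default 4).
#' @param chrom,start,end optional closed-interval region filter.
#' @param scan_cap refuse to scan more than this many SNPs (default 25).
#' @param pool_threshold passed to [haplotype_logistic()].
#' @return an object of class `aic_scan`: the model table, the winning
#'   `haplotype_model`, and the equivalence-set indices.
#' @export
aic_scan <- function(genotypes, pheno, covariates = covariate_names(pheno),
                     max_size = 4, chrom = NULL, start = NULL, end = NULL,
                     scan_cap = 25, pool_threshold = 0.01) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  snps <- genotypes$snps
  keep <- rep(TRUE, nrow(snps))
  if (!is.null(chrom)) keep <- keep & snps$chrom == chrom
  if (!is.null(start)) keep <- keep & snps$pos >= start
  if (!is.null(end)) keep <- keep & snps$pos <= end
  poly <- apply(genotypes$calls, 2, function(g) length(unique(g[!is.na(g)])) > 1)
  keep <- keep & poly
  m <- sum(keep)
  if (m == 0) stop_hapghost("no polymorphic SNPs in region", "hapghost_empty_error")
  if (m > scan_cap)
    stop_hapghost(sprintf("%d region SNPs exceed scan_cap = %d; raise scan_cap or pre-filter",
                          m, scan_cap), "hapghost_capacity_error")
  idx <- which(keep)
  subsets <- unlist(lapply(seq_len(min(max_size, m)), function(s)
    combn(idx, s, simplify = FALSE)), recursive = FALSE)
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    g_sub <- genotype_matrix(genotypes$samples, snps[sub, , drop = FALSE],
                             genotypes$calls[, sub, drop = FALSE])
    hf <- em_haplotypes(g_sub)
    hm <- haplotype_logistic(hf, pheno, covariates = covariates,
                             pool_threshold = pool_threshold)
    rows[[i]] <- data.frame(
      model = paste(snps$id[sub], collapse = "+"),
      size = length(sub),
      n_haplotypes = length(hm$effects$haplotype) + 1L,
      positions = paste(snps$pos[sub], collapse = ","),
      loglik = hm$loglik, aic = hm$aic,
      global_p = hm$global_p, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic)
  equiv <- which(tab$delta_aic <= 2)
  ord <- equiv[order(tab$size[equiv], tab$n_haplotypes[equiv], tab$positions[equiv])]
  win <- ord[1]
  sub <- subsets[[win]]
  g_sub <- genotype_matrix(genotypes$samples, snps[sub, , drop = FALSE],
                           genotypes$calls[, sub, drop = FALSE])
  best <- haplotype_logistic(em_haplotypes(g_sub), pheno,
                             covariates = covariates,
                             pool_threshold = pool_threshold)
  structure(list(table = tab, winner_index = win, winner = best,
                 equivalence = equiv, n_models = nrow(tab)),
            class = "aic_scan")
}

#' @export
print.aic_scan <- function(x, ...) {
  cat(sprintf("aic_scan: %d models; %d in the equivalence set (delta AIC <= 2)\n",
              x$n_models, length(x$equivalence)))
  cat("winner:", x$table$model[x$winner_index], "\n")
  invisible(x)
}
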