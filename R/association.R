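#' Single-predictor case-control association result
#'
#' Internal constructor shared by the dosage-logistic routines.
#' @noRd
association_result <- function(snp_id, log_or, se, p, test,
                               conditioned_on = character(0),
                               covariates = character(0),
                               p_wald = NA_real_, n = NA_integer_) {
  structure(list(snp_id = snp_id, log_or = log_or, se = se, p = p,
                 test = test, p_wald = p_wald,
                 conditioned_on = conditioned_on, covariates = covariates,
                 n = n),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: logOR = %.3f (se %.3f), OR = %.2f [%.2f-%.2f], p[%s] = %s\n",
              x$snp_id, x$log_or, x$se, exp(x$log_or),
              exp(x$log_or - 1.96 * x$se), exp(x$log_or + 1.96 * x$se),
              x$test, fmt_num(x$p)))
  if (length(x$conditioned_on))
    cat("  conditioned on:", paste(x$conditioned_on, collapse = ", "), "\n")
  invisible(x)
}

fit_logistic <- function(y, X, max_iter = 100, tol = 1e-10) {
  # stats::glm is IRLS; epsilon is its deviance tolerance
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- glm(y ~ ., data = df, family = binomial(),
             control = list(maxit = max_iter, epsilon = tol))
  fit
}

#' Dosage logistic regression
#'
#' Case-control association of a single SNP using its allelic dosage
#' (0-2 copies of the minor allele) as predictor in a logistic regression,
#' optionally adjusted for covariates (e.g. principal components). The
#' reported p-value is the likelihood-ratio test of the dosage term; the
#' Wald p-value and (Wald) standard error are also returned for
#' meta-analysis use.
#'
#' @param dose numeric dosage (or hard genotype) vector aligned to `pheno`.
#' @param pheno a [phenotype_table()].
#' @param covariates character vector of covariate column names in `pheno`
#'   (default: all of them).
#' @param snp_id label for the tested SNP.
#' @return an `association_result` with fields `log_or`, `se`, `p` (LRT),
#'   `p_wald`, `test`, `covariates`.
#' @export
dose_logistic <- function(dose, pheno, covariates = covariate_names(pheno),
                          snp_id = "snp") {
  stopifnot(inherits(pheno, "phenotype_table"), length(dose) == nrow(pheno))
  keep <- !is.na(dose)
  dose <- dose[keep]; ph <- pheno[keep, , drop = FALSE]
  if (length(unique(ph$status)) < 2)
    stop_hapghost("need at least one case and one control", "hapghost_validation_error")
  if (var(dose) == 0)
    stop_hapghost("constant dosage: degenerate predictor", "hapghost_degenerate_error")
  X <- cbind(dose = dose)
  if (length(covariates)) X <- cbind(X, as.matrix(ph[covariates]))
  fit <- fit_logistic(ph$status, X)
  if (!fit$converged)
    stop_hapghost(sprintf("logistic regression did not converge in %d IRLS iterations",
                          fit$iter), "hapghost_convergence_error")
  beta <- coef(fit)["dose"]
  if (is.na(beta) || abs(beta) > 15)
    stop_hapghost("(quasi-)separation detected for dosage predictor",
                  "hapghost_convergence_error")
  se <- sqrt(vcov(fit)["dose", "dose"])
  # LRT against the covariates-only null
  X0 <- if (length(covariates)) as.matrix(ph[covariates]) else NULL
  fit0 <- if (is.null(X0)) glm(ph$status ~ 1, family = binomial())
          else fit_logistic(ph$status, X0)
  lr <- fit0$deviance - fit$deviance
  p_lrt <- pchisq(lr, df = 1, lower.tail = FALSE)
  p_wald <- 2 * pnorm(-abs(beta / se))
  association_result(snp_id, unname(beta), unname(se), p_lrt, "lrt",
                     covariates = covariates, p_wald = p_wald, n = length(dose))
}

#' Conditional dosage logistic regression
#'
#' Re-tests a target SNP with one or more adjustment columns (imputed doses
#' and/or hard genotypes, possibly merged across sample subsets as when a
#' variant is imputed in controls but genotyped in cases) entered as
#' covariates.
#'
#' @inheritParams dose_logistic
#' @param adjust named list (or single vector) of adjustment columns aligned
#'   to `pheno`; names are recorded in `conditioned_on`.
#' @return an `association_result`; `conditioned_on` lists adjustment SNPs.
#' @export
conditional_logistic <- function(dose, adjust, pheno,
                                 covariates = covariate_names(pheno),
                                 snp_id = "snp") {
  if (!is.list(adjust)) adjust <- list(adjust1 = adjust)
  if (is.null(names(adjust)) || any(names(adjust) == ""))
    names(adjust) <- paste0("adjust", seq_along(adjust))
  A <- do.call(cbind, adjust)
  stopifnot(nrow(A) == nrow(pheno))
  keep <- !is.na(dose) & !apply(A, 1, anyNA)
  d <- dose[keep]; Ak <- A[keep, , drop = FALSE]; ph <- pheno[keep, , drop = FALSE]
  # drop constant adjustment columns: they cannot alter the fit
  keep_col <- apply(Ak, 2, var) > 0
  Ak <- Ak[, keep_col, drop = FALSE]
  used <- names(adjust)[keep_col]
  if (ncol(Ak)) {
    Z <- cbind(Ak, if (length(covariates)) as.matrix(ph[covariates]))
    r2 <- suppressWarnings(summary(lm(d ~ Z))$r.squared)
    if (r2 > 1 - 1e-8)
      stop_hapghost("target dosage is collinear with adjustment columns",
                    "hapghost_collinearity_error")
  }
  ph_aug <- ph
  adj_cols <- paste0(".adj_", used, recycle0 = TRUE)
  for (i in seq_along(used)) ph_aug[[adj_cols[i]]] <- Ak[, used[i]]
  class(ph_aug) <- class(pheno)
  res <- dose_logistic(d, ph_aug, covariates = c(covariates, adj_cols),
                       snp_id = snp_id)
  res$conditioned_on <- used
  res$covariates <- covariates
  res
}

#' 2x3 case-control genotype table
#'
#' @param control_counts,case_counts integer triples of genotype counts in
#'   minor-allele-count order (0, 1, 2 copies).
#' @return an object of class `genotype_table_2x3`.
#' @export
genotype_table_2x3 <- function(control_counts, case_counts) {
  ctrl <- as.numeric(control_counts); cs <- as.numeric(case_counts)
  if (length(ctrl) != 3 || length(cs) != 3)
    stop_hapghost("genotype counts must be triples (0, 1, 2 copies)",
                  "hapghost_validation_error")
  if (any(c(ctrl, cs) < 0) || sum(ctrl) == 0 || sum(cs) == 0)
    stop_hapghost("counts must be non-negative with positive row sums",
                  "hapghost_validation_error")
  structure(list(control = ctrl, case = cs), class = "genotype_table_2x3")
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportion across genotype classes with
#' scores (0, 1, 2); the signed statistic `Z` is positive when the minor
#' allele is more frequent in cases. The two-sided p-value comes from the
#' standard normal distribution.
#'
#' @param table a [genotype_table_2x3()].
#' @return list with `z`, `chi2` (= `z^2`), `p`.
#' @export
trend_test <- function(table) {
  stopifnot(inherits(table, "genotype_table_2x3"))
  s <- 0:2
  n_j <- table$control + table$case      # column totals
  r_j <- table$case                      # cases per genotype class
  N <- sum(n_j); R <- sum(r_j)
  num <- sum(s * (r_j - R * n_j / N))
  den <- (R * (N - R) / N^2) * (sum(n_j * s^2) - sum(n_j * s)^2 / N)
  if (den <= 0)
    stop_hapghost("degenerate genotype table for trend test", "hapghost_validation_error")
  z <- num / sqrt(den)
  list(z = z, chi2 = z^2, p = 2 * pnorm(-abs(z)))
}

#' Allelic odds ratio from a 2x3 genotype table
#'
#' Collapses the genotype table to a 2x2 allele-count table and reports the
#' allelic odds ratio with a Woolf (log-scale) 95% confidence interval and a
#' log-scale Wald p-value.
#'
#' @param table a [genotype_table_2x3()].
#' @param continuity if `TRUE`, add 0.5 to every allele cell (used when a
#'   cell is zero).
#' @return list with `or`, `ci` (length-2), `p`, `log_or`, `se`.
#' @export
allelic_or <- function(table, continuity = FALSE) {
  stopifnot(inherits(table, "genotype_table_2x3"))
  # allele counts: minor and major, cases and controls
  a_case <- table$case[2] + 2 * table$case[3]
  b_case <- 2 * table$case[1] + table$case[2]
  a_ctrl <- table$control[2] + 2 * table$control[3]
  b_ctrl <- 2 * table$control[1] + table$control[2]
  cells <- c(a_case, b_case, a_ctrl, b_ctrl)
  if (any(cells == 0)) {
    if (!continuity)
      stop_hapghost("zero allele-count cell; re-run with continuity = TRUE",
                    "hapghost_zero_cell_error")
    cells <- cells + 0.5
  }
  log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  list(or = exp(log_or),
       ci = exp(log_or + c(-1.96, 1.96) * se),
       p = 2 * pnorm(-abs(log_or / se)),
       log_or = log_or, se = se)
}

#' Minor allele frequency
#'
#' From a genotype-count triple (`(n0, n1, n2)` samples with 0/1/2 copies)
#' or from a genotype vector via `counts = FALSE`. When the counted allele's
#' frequency exceeds 0.5 the complement is reported with `flipped = TRUE`.
#'
#' @param x a length-3 count triple, or a genotype vector coded 0/1/2
#'   (with `counts = FALSE`).
#' @param counts if `FALSE`, `x` is a per-sample genotype vector and is
#'   tabulated first.
#' @return list with `maf`, `raw_freq` (counted-allele frequency), `flipped`.
#' @export
genotype_maf <- function(x, counts = TRUE) {
  x <- x[!is.na(x)]
  if (counts) {
    if (length(x) != 3)
      stop_hapghost("count triple must have length 3 (use counts = FALSE for genotype vectors)",
                    "hapghost_validation_error")
    cnt <- as.numeric(x)
  } else {
    if (!all(x %in% 0:2))
      stop_hapghost("genotype vector must be coded 0/1/2", "hapghost_validation_error")
    cnt <- as.numeric(table(factor(x, 0:2)))
  }
  n <- sum(cnt)
  if (n == 0) stop_hapghost("empty genotype row", "hapghost_validation_error")
  raw <- (cnt[2] + 2 * cnt[3]) / (2 * n)
  list(maf = min(raw, 1 - raw), raw_freq = raw, flipped = raw > 0.5)
}
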