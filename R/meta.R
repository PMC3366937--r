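#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-study log odds ratios with inverse-variance weights (the
#' METAL-style fixed-effect model). Heterogeneity is reported as Cochran's
#' Q, the standard companion of inverse-variance pooling. P-values are
#' computed in log space so magnitudes like 1e-13 do not underflow.
#'
#' @param beta per-study log odds ratios.
#' @param se per-study standard errors (all positive and finite).
#' @param labels optional study labels.
#' @return an object of class `meta_result`: `beta_c`, `se_c`, `z`, `p`,
#'   `log10_p`, `q_stat`, `q_df`, `q_p` and normalized `weights`.
#' @export
fixed_effect_meta <- function(beta, se, labels = NULL) {
  stopifnot(length(beta) == length(se))
  if (any(!is.finite(se)) || any(se <= 0))
    stop_hapghost("standard errors must be finite and positive", "hapghost_validation_error")
  k <- length(beta)
  if (k == 1) warning("single study: meta-analysis is a pass-through")
  w <- 1 / se^2
  beta_c <- sum(w * beta) / sum(w)
  se_c <- 1 / sqrt(sum(w))
  z <- beta_c / se_c
  log_p <- pnorm(-abs(z), log.p = TRUE) + log(2)
  q <- sum(w * (beta - beta_c)^2)
  q_df <- k - 1L
  structure(list(beta_c = beta_c, se_c = se_c, z = z,
                 p = exp(log_p), log10_p = log_p / log(10),
                 q_stat = q, q_df = q_df,
                 q_p = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
                 weights = w / sum(w),
                 labels = labels %||% paste0("study", seq_len(k))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effect meta: beta = %.3f (se %.3f), OR = %.2f, z = %.2f, p = %s\n",
              x$beta_c, x$se_c, exp(x$beta_c), x$z, fmt_num(x$p)))
  if (x$q_df > 0)
    cat(sprintf("heterogeneity: Q = %.2f on %d df, p = %s\n",
                x$q_stat, x$q_df, fmt_num(x$q_p)))
  invisible(x)
}

#' Meta-analysis of odds ratios given confidence intervals
#'
#' Reconstructs each study's log-OR standard error from its 95% confidence
#' interval (`se = (log upper - log lower) / (2 * 1.96)`) and pools with
#' [fixed_effect_meta()].
#'
#' @param or,lower,upper per-study odds ratios and 95% CI bounds
#'   (`0 < lower < or < upper`).
#' @param labels optional study labels.
#' @return a `meta_result` with additional fields `or_c`, `or_ci` on the OR
#'   scale.
#' @export
or_meta <- function(or, lower, upper, labels = NULL) {
  if (any(!(lower < or & or < upper)) || any(lower <= 0))
    stop_hapghost("need 0 < lower < OR < upper for every study", "hapghost_validation_error")
  beta <- log(or)
  se <- (log(upper) - log(lower)) / (2 * 1.96)
  out <- fixed_effect_meta(beta, se, labels)
  out$or_c <- exp(out$beta_c)
  out$or_ci <- exp(out$beta_c + c(-1.96, 1.96) * out$se_c)
  out
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / 0.4549364` (the median of a 1-df chi-square).
#' P-values are converted to 1-df chi-square statistics via the inverse
#' survival function.
#'
#' @param p vector of p-values in (0, 1]; alternatively supply `chi2`.
#' @param chi2 vector of 1-df chi-square statistics.
#' @return the scalar inflation factor lambda.
#' @export
genomic_control <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (any(p <= 0 | p > 1))
      stop_hapghost("p-values must lie in (0, 1]", "hapghost_validation_error")
    chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chi2) < 100)
    warning("fewer than 100 statistics: lambda estimate may be unstable")
  median(chi2) / qchisq(0.5, df = 1)
}

#' Observed vs expected quantiles for a QQ plot
#'
#' Order statistics of -log10 p against uniform expectations `i/(n+1)`, with
#' a pointwise 95% band from Beta(i, n-i+1) quantiles.
#'
#' @param p vector of p-values in (0, 1].
#' @return data.frame with `expected`, `observed`, `band_lo`, `band_hi`
#'   (all on the -log10 scale), sorted from most to least significant.
#' @export
qq_data <- function(p) {
  if (any(p <= 0 | p > 1))
    stop_hapghost("p-values must lie in (0, 1]", "hapghost_validation_error")
  n <- length(p)
  i <- seq_len(n)
  data.frame(
    expected = -log10(i / (n + 1)),
    observed = -log10(sort(p)),
    band_lo = -log10(qbeta(0.975, i, n - i + 1)),
    band_hi = -log10(qbeta(0.025, i, n - i + 1))
  )
}
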