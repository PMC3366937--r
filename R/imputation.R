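#' Imputation quality cut-off used throughout the pipeline
#'
#' SNPs with estimated dosage quality at or below this value are regarded as
#' poorly imputed.
#' @export
QUALITY_MIN <- 0.3

#' MACH-style dosage quality
#'
#' The ratio of the empirical dosage variance (population denominator n) to
#' the binomial variance `2p(1-p)` expected for a perfectly observed variant
#' with the dosage-implied allele frequency `p = mean(dose)/2`. Values can
#' exceed 1 by sampling noise; the capped value is reported alongside the
#' raw ratio.
#'
#' @param dose numeric dosage column in `[0, 2]`.
#' @param snp_id label.
#' @return object of class `quality_report`: `rsq_hat` (capped at 1),
#'   `rsq_raw`, `maf_hat`.
#' @export
dosage_quality <- function(dose, snp_id = "snp") {
  dose <- dose[!is.na(dose)]
  if (length(dose) < 2)
    stop_hapghost("need at least 2 dosage values", "hapghost_validation_error")
  p <- mean(dose) / 2
  if (p <= 0 || p >= 1) {
    rsq_raw <- NA_real_
  } else {
    rsq_raw <- var_pop(dose) / (2 * p * (1 - p))
  }
  structure(list(snp_id = snp_id, rsq_hat = min(rsq_raw, 1), rsq_raw = rsq_raw,
                 maf_hat = min(p, 1 - p), n = length(dose)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("%s: rsq_hat = %s, implied MAF = %.4f (n = %d)\n",
              x$snp_id, fmt_num(x$rsq_hat), x$maf_hat, x$n))
  invisible(x)
}

#' Dosage-truth concordance
#'
#' Spearman correlation (average ranks for ties) between an imputed dose and
#' the measured genotype, plus the quartiles of the dose within each truth
#' class (the box-plot summary view). Truth classes with fewer than 2
#' observations are excluded from the box summary.
#'
#' @param dose numeric dosage column.
#' @param truth genotype column coded 0/1/2.
#' @return list with `spearman_rho`, `n`, and `boxes` (data.frame
#'   `truth_class`, `q1`, `median`, `q3`, `n`).
#' @export
concordance <- function(dose, truth) {
  keep <- !is.na(dose) & !is.na(truth)
  dose <- dose[keep]; truth <- truth[keep]
  if (length(dose) < 3)
    stop_hapghost("need at least 3 overlapping non-missing samples",
                  "hapghost_validation_error")
  if (length(unique(truth)) < 2)
    stop_hapghost("constant truth genotype: correlation undefined",
                  "hapghost_degenerate_error")
  rho <- cor(dose, truth, method = "spearman")
  cls <- sort(unique(truth))
  boxes <- do.call(rbind, lapply(cls, function(g) {
    d <- dose[truth == g]
    if (length(d) < 2) return(NULL)
    q <- quantile(d, c(0.25, 0.5, 0.75), type = 7)
    data.frame(truth_class = g, q1 = q[[1]], median = q[[2]], q3 = q[[3]],
               n = length(d))
  }))
  list(spearman_rho = rho, n = length(dose), boxes = boxes)
}

#' Haplotype-conditional tag imputation
#'
#' A minimal mechanistic imputation used to demonstrate why rare variants in
#' weak LD with their tags impute poorly. Joint haplotype frequencies of
#' (tags, target) are counted from a phased reference panel; for each study
#' individual the expected target allele count is computed under HWE by
#' summing over tag-haplotype pairs compatible with the observed tag
#' genotypes, each pair weighted by its panel frequency and contributing the
#' panel's conditional target-allele probability per tag haplotype.
#'
#' @param panel integer 0/1 matrix of phased reference haplotypes (rows =
#'   chromosomes) with one column per tag SNP plus a `target` column.
#' @param study_tags integer 0/1/2 genotype matrix over the same tag SNPs
#'   (columns in the same order as the panel's tag columns).
#' @param target_col name or index of the target column in `panel`.
#' @return numeric dosage vector with attributes `n_fallback` (individuals
#'   whose tag genotypes were incompatible with every panel haplotype pair,
#'   imputed at twice the panel target frequency) and `panel_freq`.
#' @export
tag_impute <- function(panel, study_tags, target_col = "target") {
  panel <- as.matrix(panel)
  ti <- if (is.character(target_col)) match(target_col, colnames(panel)) else target_col
  if (is.na(ti)) stop_hapghost("target column not found in panel", "hapghost_lookup_error")
  target <- panel[, ti]
  tags <- panel[, -ti, drop = FALSE]
  if (length(unique(target)) < 2)
    stop_hapghost("reference panel is monomorphic at the target", "hapghost_degenerate_error")
  k <- ncol(tags)
  study_tags <- as.matrix(study_tags)
  if (ncol(study_tags) != k)
    stop_hapghost("study tag columns do not match panel tags", "hapghost_validation_error")
  # panel tag-haplotype codes and conditional target probabilities
  bit <- bitwShiftL(1L, seq_len(k) - 1L)
  code <- as.integer(tags %*% bit)
  f_tab <- table(code)
  f_hap <- as.numeric(f_tab) / length(code)
  q_hap <- vapply(as.integer(names(f_tab)), function(cd) mean(target[code == cd]),
                  numeric(1))
  H <- bitwShiftL(1L, k)
  f_full <- numeric(H); q_full <- numeric(H)
  at <- as.integer(names(f_tab)) + 1L
  f_full[at] <- f_hap; q_full[at] <- q_hap
  p_target <- mean(target)
  n <- nrow(study_tags)
  dose <- numeric(n)
  n_fallback <- 0L
  pair_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    g <- study_tags[i, ]
    key <- paste(g, collapse = ",")
    pr <- get0(key, envir = pair_cache)
    if (is.null(pr)) {
      pr <- hap_pairs(g)
      assign(key, pr, envir = pair_cache)
    }
    w <- f_full[pr[, 1] + 1L] * f_full[pr[, 2] + 1L]
    s <- sum(w)
    if (s > 0) {
      dose[i] <- sum(w * (q_full[pr[, 1] + 1L] + q_full[pr[, 2] + 1L])) / s
    } else {
      dose[i] <- 2 * p_target
      n_fallback <- n_fallback + 1L
    }
  }
  dose <- pmin(pmax(dose, 0), 2)
  attr(dose, "n_fallback") <- n_fallback
  attr(dose, "panel_freq") <- p_target
  dose
}
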