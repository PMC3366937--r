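#' Named analysis thresholds
#'
#' Every cut-off used by the pipeline as one auditable constant:
#' `genome_wide` significance, the `suggestive` threshold used in
#' conditional re-discovery, the minimum acceptable imputation quality, and
#' the p-value above which a conditional association is regarded as having
#' vanished.
#'
#' @return named list of thresholds.
#' @export
ghost_thresholds <- function() {
  list(genome_wide = 7.4e-9, suggestive = 1e-6,
       quality_min = QUALITY_MIN, conditional_null = 0.10)
}

#' Run the ghost-signal dissection pipeline
#'
#' Executes the full analysis narrative on one or more (simulated or
#' user-supplied) case-control studies: per-SNP dosage logistic regression
#' per study, fixed-effect meta-analysis, an LD matrix of the hit region,
#' mutual conditional analyses among the hits, the AIC haplotype scan over
#' typed SNPs, haplotype odds ratios with and without adjustment on a hit
#' dose, conditional analysis of the top hit on the candidate culprit's
#' imputed dose and (where available) its true genotype, and quality and
#' concordance diagnostics for the culprit. The `ghost_signal` verdict flag
#' is set when the top-hit association collapses under the truth genotype
#' but not under the imputed dose.
#'
#' @param scenario `"ghost"` (causal variant untyped, tag-imputed),
#'   `"causal_typed"` (causal variant included on the array; positive
#'   control) or `"null"` (no causal effect).
#' @param seed RNG seed.
#' @param n_cases,n_controls per-study quotas (vectors give several
#'   studies).
#' @param spec panel specification.
#' @param thresholds named thresholds, see [ghost_thresholds()].
#' @param bundles optional pre-built list of `cohort_bundle` objects; when
#'   supplied, `scenario`/`n_cases`/`n_controls` are ignored.
#' @return an object of class `ghost_report`.
#' @export
run_ghost_analysis <- function(scenario = c("ghost", "causal_typed", "null"),
                               seed, n_cases = c(1500, 420),
                               n_controls = c(1200, 1230),
                               spec = default_ghost_spec(),
                               thresholds = ghost_thresholds(),
                               bundles = NULL) {
  scenario <- match.arg(scenario)
  if (missing(seed)) seed <- 1L
  stopifnot(length(n_cases) == length(n_controls))
  if (is.null(bundles)) {
    or_c <- if (scenario == "null") 1.0 else spec$or_causal
    bundles <- lapply(seq_along(n_cases), function(i)
      simulate_cohort(spec, n_cases[i], n_controls[i], or_causal = or_c,
                      seed = seed + 7919L * (i - 1L),
                      study_label = paste0("study", i),
                      causal_typed = scenario == "causal_typed"))
  }
  stages <- list()
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name, params, n) {
    stages[[length(stages) + 1L]] <<- list(
      stage = name, params = params, n = n,
      runtime = round(proc.time()[["elapsed"]] - t0, 3))
  }

  # stage 1: per-study dosage logistic over all imputed SNPs
  per_study <- lapply(bundles, function(b) {
    dm <- b$observed$dose
    ph <- b$observed$pheno
    res <- lapply(seq_len(ncol(dm$dose)), function(j)
      dose_logistic(dm$dose[, j], ph, snp_id = dm$snps$id[j]))
    data.frame(snp = dm$snps$id[seq_len(ncol(dm$dose))],
               maf = vapply(res, function(r) NA_real_, numeric(1)),
               log_or = vapply(res, `[[`, numeric(1), "log_or"),
               se = vapply(res, `[[`, numeric(1), "se"),
               p = vapply(res, `[[`, numeric(1), "p"),
               quality = dm$quality,
               study = ph$study[1], stringsAsFactors = FALSE)
  })
  for (i in seq_along(per_study))
    per_study[[i]]$maf <- colMeans(bundles[[i]]$observed$dose$dose) / 2
  assoc_tab <- do.call(rbind, per_study)
  log_stage("per_snp_association", list(), nrow(assoc_tab))

  # stage 2: fixed-effect meta across studies (quality-filtered, as the
  # per-SNP scan only admits acceptably imputed SNPs)
  snps <- unique(assoc_tab$snp)
  meta_tab <- do.call(rbind, lapply(snps, function(s) {
    rows <- assoc_tab[assoc_tab$snp == s, ]
    ok <- rows$quality > thresholds$quality_min
    if (sum(ok) < 1) return(NULL)
    rows <- rows[ok, ]
    if (nrow(rows) == 1)
      return(data.frame(snp = s, beta_c = rows$log_or, se_c = rows$se,
                        p = rows$p, q_p = NA_real_, n_studies = 1L))
    m <- fixed_effect_meta(rows$log_or, rows$se, rows$study)
    data.frame(snp = s, beta_c = m$beta_c, se_c = m$se_c, p = m$p,
               q_p = m$q_p, n_studies = nrow(rows))
  }))
  meta_tab$genome_wide <- meta_tab$p < thresholds$genome_wide
  log_stage("meta_analysis", list(threshold = thresholds$genome_wide), nrow(meta_tab))

  # main study (largest) carries the in-depth dissection
  main <- bundles[[which.max(vapply(bundles, function(b) nrow(b$observed$pheno), 1))]]
  ph <- main$observed$pheno
  dm <- main$observed$dose
  hits <- meta_tab$snp[order(meta_tab$p)]
  hits <- hits[hits %in% colnames(dm$dose)]
  top_hit <- hits[1]

  # stage 3: LD matrix of the typed hit-region SNPs
  region <- c(47300000, 48100000)
  ld <- ld_matrix(main$observed$genotypes, chrom = "chr11",
                  start = region[1], end = region[2])
  log_stage("ld_matrix", list(region = region), nrow(ld$r2))

  # stage 4: mutual conditional analyses among the leading hits
  mutual <- NULL
  block_hits <- utils::head(hits[hits != "causal_rare"], 4)
  if (length(block_hits) >= 2) {
    mutual <- do.call(rbind, lapply(block_hits, function(s) {
      others <- setdiff(block_hits, s)[1]
      r <- tryCatch(
        conditional_logistic(dm$dose[, s],
                             setNames(list(dm$dose[, others]), others),
                             ph, snp_id = s),
        hapghost_collinearity_error = function(e) NULL)
      # a dose collinear with its adjuster carries no residual association
      data.frame(snp = s, conditioned_on = others,
                 p = if (is.null(r)) NA_real_ else r$p,
                 vanished = if (is.null(r)) TRUE
                            else r$p > thresholds$conditional_null)
    }))
  }
  log_stage("mutual_conditional", list(), length(block_hits))

  # stage 5: AIC haplotype scan over typed region SNPs, pre-filtered to a
  # desk-scale scan set (the known tag SNPs plus evenly spaced typed SNPs)
  gm <- main$observed$genotypes
  in_region <- gm$snps$chrom == "chr11" & gm$snps$pos >= region[1] &
    gm$snps$pos <= region[2]
  tags <- gm$snps$id[in_region & gm$snps$role == "tag"]
  others <- gm$snps$id[in_region & gm$snps$role != "tag"]
  if (length(tags) + length(others) > 12 && length(others) > 0)
    others <- others[round(seq(1, length(others),
                               length.out = max(0, 12 - length(tags))))]
  scan_set <- subset_genotypes(gm, unique(c(tags, others)))
  scan <- aic_scan(scan_set, ph, max_size = 3, scan_cap = 25)
  log_stage("aic_scan", list(max_size = 3), scan$n_models)

  # stage 6: haplotype ORs with and without adjustment on a hit dose
  hap_adj <- haplotype_conditional(
    em_haplotypes(subset_genotypes(main$observed$genotypes, scan_snps(scan))),
    ph, adjust_dose = setNames(list(dm$dose[, top_hit]), top_hit))
  log_stage("haplotype_adjusted", list(adjust = top_hit), hap_adj$n)

  # stage 7: top hit conditioned on culprit dose, then on culprit truth
  culprit_dose <- dm$dose[, "causal_rare"]
  crude <- dose_logistic(dm$dose[, top_hit], ph, snp_id = top_hit)
  safe_cond <- function(adjust) tryCatch(
    conditional_logistic(dm$dose[, top_hit], adjust, ph, snp_id = top_hit),
    hapghost_collinearity_error = function(e) NULL)
  cond_dose <- safe_cond(list(causal_dose = culprit_dose))
  cond_truth <- safe_cond(list(causal_truth = main$truth$causal_geno))
  val <- function(r, f) if (is.null(r)) NA_real_ else r[[f]]
  conditional_tab <- data.frame(
    analysis = c("crude", "adjusted_imputed", "adjusted_truth"),
    log_or = c(crude$log_or, val(cond_dose, "log_or"), val(cond_truth, "log_or")),
    se = c(crude$se, val(cond_dose, "se"), val(cond_truth, "se")),
    p = c(crude$p, val(cond_dose, "p"), val(cond_truth, "p")))
  log_stage("conditional_dissection", list(top_hit = top_hit), 3L)

  # stage 8: culprit quality and concordance
  quality <- dosage_quality(culprit_dose, snp_id = "causal_rare")
  conc <- concordance(culprit_dose, main$truth$causal_geno)
  log_stage("culprit_quality", list(), quality$n)

  verdict <- list(
    top_hit = top_hit,
    top_hit_is_causal = identical(top_hit, "causal_rare"),
    crude_significant = crude$p < thresholds$suggestive,
    collapses_under_truth = !is.null(cond_truth) && cond_truth$p > 0.05,
    persists_under_dose = !is.null(cond_dose) && cond_dose$p < 1e-3,
    culprit_poorly_imputed = quality$rsq_hat < thresholds$quality_min
  )
  verdict$ghost_signal <- !verdict$top_hit_is_causal &&
    verdict$crude_significant && verdict$collapses_under_truth &&
    verdict$persists_under_dose

  structure(list(scenario = scenario, seed = seed,
                 association = assoc_tab, meta = meta_tab, ld = ld,
                 mutual_conditional = mutual, scan = scan,
                 haplotype_adjusted = hap_adj,
                 conditional = conditional_tab,
                 quality = quality, concordance = conc,
                 verdict = verdict, thresholds = thresholds,
                 manifest = stages),
            class = "ghost_report")
}

subset_genotypes <- function(gm, ids) {
  ix <- match(ids, gm$snps$id)
  genotype_matrix(gm$samples, gm$snps[ix, , drop = FALSE],
                  gm$calls[, ix, drop = FALSE])
}

scan_snps <- function(scan) {
  strsplit(scan$table$model[scan$winner_index], "+", fixed = TRUE)[[1]]
}

#' @export
print.ghost_report <- function(x, ...) {
  cat(sprintf("ghost_report (scenario %s, seed %d)\n", x$scenario, x$seed))
  cat(sprintf("top hit: %s (crude p = %s)\n", x$verdict$top_hit,
              fmt_num(x$conditional$p[1])))
  cat(sprintf("conditioned on imputed culprit dose: p = %s\n",
              fmt_num(x$conditional$p[2])))
  cat(sprintf("conditioned on true culprit genotype: p = %s\n",
              fmt_num(x$conditional$p[3])))
  cat(sprintf("culprit imputation quality: %.3f; dose-truth Spearman rho: %.3f\n",
              x$quality$rsq_hat, x$concordance$spearman_rho))
  cat(sprintf("verdict: ghost_signal = %s\n", x$verdict$ghost_signal))
  invisible(x)
}

#' Conditional re-discovery scan
#'
#' Re-runs the per-SNP dosage association conditioning on a set of known
#' loci and reports the SNPs that remain below a threshold.
#'
#' @param dose_matrix a [dosage_matrix()].
#' @param pheno a [phenotype_table()].
#' @param known_loci SNP ids (in `dose_matrix`) to condition on; empty set
#'   reproduces the crude scan.
#' @param threshold reporting threshold (default the suggestive 1e-6).
#' @return data.frame of surviving SNPs with conditional p-values.
#' @export
conditional_rediscovery <- function(dose_matrix, pheno, known_loci = character(0),
                                    threshold = ghost_thresholds()$suggestive) {
  stopifnot(inherits(dose_matrix, "dosage_matrix"))
  missing_ids <- setdiff(known_loci, dose_matrix$snps$id)
  if (length(missing_ids))
    stop_hapghost(paste0("unknown SNP id(s): ", paste(missing_ids, collapse = ", ")),
                  "hapghost_lookup_error")
  adj <- if (length(known_loci))
    setNames(lapply(known_loci, function(s) dose_matrix$dose[, s]), known_loci)
  else NULL
  test_ids <- setdiff(dose_matrix$snps$id, known_loci)
  rows <- lapply(test_ids, function(s) {
    r <- if (is.null(adj)) dose_logistic(dose_matrix$dose[, s], pheno, snp_id = s)
         else conditional_logistic(dose_matrix$dose[, s], adj, pheno, snp_id = s)
    data.frame(snp = s, log_or = r$log_or, se = r$se, p = r$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[tab$p < threshold, , drop = FALSE]
}
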