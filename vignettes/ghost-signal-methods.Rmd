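---
title: "Dissecting long-range ghost associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting long-range ghost associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hapghost)
```

## The problem

Genotype imputation against a sequencing reference panel lets a
case-control GWAS test variants that were never typed. When a rare causal
variant sits on a long-range haplotype, the imputed proxies of that
haplotype can reach genome-wide significance up to a megabase away from the
causal site, while the causal variant itself — rare, weakly tagged by any
single common SNP — imputes so poorly that it fails quality control and is
never seen. The hit region then points at the wrong genes. `hapghost`
implements the statistical tool chain for recognizing and dissecting this
situation: haplotype inference, haplotype-effect models with AIC model
selection, LD analysis from unphased genotypes, conditional association,
fixed-effect meta-analysis, imputation-quality diagnostics, and a synthetic
cohort generator that reproduces the phenomenon end to end.

## Models and procedures

### Two-locus and multi-locus haplotype inference

For two biallelic loci with unphased genotypes, only the double
heterozygote is phase-ambiguous. `two_locus_em()` maximizes the HWE
multinomial likelihood of the 3×3 genotype table by EM: the E-step splits
the double-heterozygote count between the *cis* and *trans* configurations
in proportion to `f_AB·f_ab` and `f_Ab·f_aB`; the M-step recounts. The
log-likelihood is non-decreasing; iteration stops when the largest absolute
frequency change falls below `tol = 1e-8` (at most 1000 iterations), from a
linkage-equilibrium start `f_AB = p_A·p_B`. Both choices make results
deterministic and platform-stable. LD statistics follow the standard
definitions: `D = f_AB − p_A p_B`; `D′` is `D` over its sign-appropriate
bound, reported signed; `r² = D² / (p_A q_A p_B q_B)`. Monomorphic loci are
an error — LD is undefined there, and silently returning 0 or 1 hides
upstream data problems.

`em_haplotypes()` generalizes to k ≤ 12 SNPs (the 2^k haplotype space is
enumerated explicitly; 12 covers the models used anywhere in this package).
Samples are aggregated by genotype pattern, each pattern expanded once into
its compatible ordered haplotype pairs, and the E-step reweights pairs by
the current frequency products. Haplotypes dropping below
`prune_threshold = 1e-4` are zeroed between iterations, which keeps the
effective pair lists short without influencing any haplotype a study of
thousands of samples could resolve. Samples missing at every SNP are
skipped with a warning; partial missingness is handled by enumerating both
alleles at the missing sites.

`sem_haplotypes()` is the stochastic variant: the E-step is replaced by
sampling one compatible pair per individual from the current posterior, and
the M-step sets frequencies to sampled counts over 2n. Point estimates are
the mean over post-burn-in iterations (defaults `n_iter = 500`,
`burn_in = 100`), with a naive Monte-Carlo standard error per haplotype
(iteration autocorrelation is ignored, so the reported MC error is a mild
underestimate; tests use 3× margins). A seed is a mandatory argument —
there is no hidden global RNG state — and the deterministic EM serves as
its oracle in the test suite.

### Haplotype-effect logistic models

Individual haplotype pairs are never observed, so the disease model uses
expectation substitution: each sample contributes the posterior expected
count `E[n_h | g] ∈ [0, 2]` of every haplotype, and these dosages enter an
ordinary logistic regression alongside covariates. The reference is the
most frequent haplotype (ties broken lexicographically, with a warning);
haplotypes rarer than `pool_threshold = 0.01` are merged into one
pooled-rare term, mirroring the practice of reporting only haplotypes above
about 1%. The global test is the likelihood-ratio test of all haplotype
terms jointly, one df per modelled non-reference term. Expectation
substitution reproduces the odds ratios of full-likelihood haplotype
software to first order while keeping the model a plain GLM — the form in
which such results are conventionally reported — at the cost of ignoring
phase uncertainty in the standard errors, which is negligible at the
haplotype frequencies modelled here.

The AIC scan fits every SNP subset of size 1 to `max_size = 4` in a region,
with `AIC = 2k − 2·loglik` and `k` = intercept + covariates + (#modelled
haplotypes − 1). Covariate coefficients are included in `k`; being constant
across models they do not affect ranking, but absolute AIC values are then
reproducible. Models within 2 rescaled-AIC units of the minimum form the
equivalence set; the winner is the equivalent model with the fewest SNPs,
ties resolved by fewer modelled haplotypes and then by position order. A
`scan_cap = 25` SNP limit (≈ 15,000 models at `max_size = 4`) keeps the
exhaustive scan desk-scale; it is configurable. One property of this
selection rule worth knowing: a noise superset evicts the true model from
the equivalence set whenever its extra chi-square exceeds the extra AIC
penalty plus 2 (probability ≈ 0.05 per superset under the null), so with
many candidate SNPs the strict probability of selecting exactly the causal
singleton plateaus around 60–80% even for strong signals — the winner
virtually always *contains* the causal SNP, but parsimony is not guaranteed.

### Association and meta-analysis

`dose_logistic()` regresses case status on an imputed allelic dosage
(0–2 copies) with covariates, by IRLS (`stats::glm`, deviance tolerance
1e-10, 100 iterations); the reported p-value is the likelihood-ratio test,
with the Wald standard error retained because inverse-variance
meta-analysis needs it. Separation is flagged at |β| > 15. Conditional
analysis enters adjustment columns — imputed doses, hard genotypes, or a
merged column when a variant is imputed in one sample set and genotyped in
another — as covariates, refusing adjusters collinear with the target
(R² > 1 − 1e-8) and silently dropping constants. The Cochran–Armitage
trend test uses scores (0, 1, 2) and a signed normal statistic;
`allelic_or()` collapses the 2×3 genotype table to allele counts and uses
the Woolf log-scale interval, with an explicit continuity-correction flag
for zero cells. All p-values are two-sided.

Fixed-effect pooling uses inverse-variance weights; heterogeneity is
summarized by Cochran's Q, the standard companion of this estimator.
Combined p-values are computed in log space so magnitudes like 1e-13 do not
underflow. Genomic control is `λ = median(χ²₁)/0.45494`; QQ data pair order
statistics with `i/(n+1)` expectations and a pointwise Beta(i, n−i+1) 95%
band. The genome-wide threshold 7.4e-9, the suggestive threshold 1e-6, the
quality cut-off 0.3 and the conditional-null level 0.10 are single named
constants (`ghost_thresholds()`).

### Imputation quality and mechanistic tag imputation

Dosage quality is the variance-ratio statistic
`r̂² = Var(dose) / (2p̂(1−p̂))` with the population-variance denominator and
`p̂ = mean(dose)/2`; the raw ratio is retained and the reported value capped
at 1. Concordance with measured genotypes is Spearman's ρ with average
ranks, plus dose quartiles within each genotype class (truth classes with
fewer than 2 observations are excluded).

`tag_impute()` is a deliberately minimal, fully transparent imputation:
joint haplotype frequencies of (tags, target) are counted from a phased
reference panel, and each study individual receives the HWE-posterior
expected target allele count given their tag genotypes. Tag haplotypes
absent from the panel fall back to the panel target frequency and are
counted. It is not a hidden-Markov haplotype-mosaic imputation; it exists
to *demonstrate mechanistically* why a rare variant whose best common tag
has r² ≈ 0.15 cannot impute well from a small panel — the conditional
allele probabilities are estimated from a handful of panel haplotypes, so
the dose both carries little information and has a noisy, right-skewed
quality statistic.

## The synthetic-cohort generator

`default_ghost_spec()` fixes the study conditions:

* six tag-haplotype classes over three common SNPs, frequencies
  (0.370, 0.282, 0.049, **0.020**, 0.260, 0.019), the 0.020 class being the
  at-risk analog;
* a block indicator `B` riding the at-risk class with probability 0.95
  (leak 0.0113 elsewhere, giving block-allele frequency ≈ 0.030); twelve
  block SNPs copy `B` with per-SNP fidelity 0.97, yielding mutual r² ≈
  0.85–0.95;
* the rare causal allele rides **block-bearing** haplotypes, with class
  preference P(causal | B, at-risk class) = 0.85 versus 0.28 elsewhere:
  population MAF ≈ 0.019, 84% of causal copies on the at-risk class, and
  haplotype-level causal–block r² ≈ 0.6. Placing the causal variant on the
  block (rather than on the bare class) is what makes conditioning on a
  block-SNP dose absorb the haplotype association, as observed in real
  dissections of this kind;
* one common weak tag (frequency 0.109) carried by every causal haplotype —
  causal–tag r² ≈ 0.15, the strongest single-SNP tag the causal variant
  has; three typed partial tags of the block (frequency 0.13) that stand in
  for the surrounding typed SNPs real imputation draws on;
* 100 common background SNPs (MAF 0.05–0.5) from a latent AR(1) threshold
  model with coefficient 0.98, calibrated once to give median pairwise
  r² ≈ 0.10 and 90th percentile ≈ 0.48 among typed SNPs;
* causal odds ratio 3.0 and population prevalence 0.05 (case-control
  designs do not identify prevalence; the OR being recovered is robust to
  this choice for a rare disease).

`simulate_cohort()` draws two haplotypes per individual i.i.d. from the
class system, assigns disease by
`logit P = α + log(OR)·g_causal` with α solved for the prevalence, and
rejection-samples to the case/control quotas (guarded by a draw limit).
Background SNPs are generated only for retained individuals — they are
independent of the phenotype, so this is exact and much cheaper. Observed
data mimic the study design: tag, partial-tag and background SNPs are
"typed"; block SNPs exist only as imputed dosages, produced by
`tag_impute()` from the six typed tags against an 800-haplotype panel
(quality ≈ 0.85–0.95); the causal variant is imputed from its weak tags
against a 120-haplotype panel (quality ≈ 0.1–0.3, Spearman ρ vs truth
≈ 0.45–0.55). The two panel sizes emulate the empirical contrast between
acceptably tagged SNPs, which haplotype-mosaic imputation handles stably,
and a weakly tagged rare variant, which it does not. Four principal
components of pure noise are attached so covariate plumbing is exercised.
`carrier_enriched_controls()` additionally mixes in disease-free controls
conditioned to carry exactly one causal allele, reproducing the
stratified-frequency contrast seen when a replication control series is
enriched in healthy mutation carriers.

What the generator does **not** emulate: coalescent genealogy, population
stratification (the PCs are noise), genotyping error, missingness beyond
what callers inject, linkage between the structured SNPs and the background
field, and recombination within the block. Passing tests therefore show
that the *statistical machinery* behaves correctly under the intended LD
geometry — not that it is robust to every artifact of real array data.

`degrade_to_dosage()` offers a panel-free alternative: genotypes observed
through Gaussian noise `y = g + e`, dosage = HWE-posterior mean
`E[g | y]`, with the noise scale solved numerically (grid quadrature +
`uniroot` on log σ) so the expected variance-ratio quality equals a target.
It reproduces the characteristic heterozygote smearing of rare-variant
imputation and the monotone quality–concordance relationship.

## Numerical choices and reproducibility

Every stochastic entry point takes a mandatory integer seed and restores
the caller's RNG state (`withr::with_seed`); a given (spec, seed) pair
reproduces a cohort bit for bit. Percentiles use linear interpolation
(R type 7). EM tolerances are on frequencies (1e-8), GLM tolerances on
deviance (1e-10). Degenerate inputs — monomorphic loci, constant dosages,
constant truth, empty regions, unattainable quotas — raise typed conditions
(`hapghost_*_error`) rather than propagating NaNs.

Test problem sizes were chosen to resolve the properties being asserted at
desk scale: two-locus oracle tables at n = 200 against a two-stage grid
search (step 0.01 then 5e-4); haplotype-frequency recovery at n = 5000;
null calibration of the global haplotype test over 200 replicates at
n = 2000; AIC-scan behavior over 50 replicates at n = 3000 with 9 SNPs;
and the full ghost integration over 50 replicates at n = 1500/1200, the
scale of the larger of the two study designs the generator mirrors.

## Known limitations

* Expectation-substitution haplotype ORs understate uncertainty slightly
  when phase is genuinely ambiguous at high frequency; full-likelihood
  retrospective models would be the upgrade path.
* `tag_impute()` ignores recombination within the tag window and is not a
  substitute for HMM imputation; it is the mechanism study, not the tool.
* The AIC equivalence-set selection inherits the instability of all
  best-subset searches under noise (see above); its output should be read
  as "the parsimonious equivalence class", not as a certified causal model.
* Meta-analysis is fixed-effect only, by design; with two studies a
  random-effects variance is not estimable in any useful way.
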