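Package: hapghost
Title: Haplotype Dissection of Long-Range Imputed Association Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for discovering and dissecting spurious
    ("ghost") long-range imputed associations in case-control genome-wide
    association studies: haplotype phase inference by deterministic and
    stochastic EM, AIC-based haplotype model selection, pairwise linkage
    disequilibrium from unphased genotypes, dosage-based logistic association
    with conditional analysis, fixed-effect inverse-variance meta-analysis,
    genotype-imputation quality diagnostics, and a synthetic cohort generator
    that reproduces the phenomenon of common markers tagging, via a rare
    long-range haplotype, an untyped and poorly imputed causal variant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
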