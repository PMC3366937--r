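#' SNP metadata table
#'
#' Builds and validates the per-SNP metadata table used by [genotype_matrix()]
#' and [dosage_matrix()]. SNPs without an allocated rsID are conventionally
#' named `"chr:pos"`.
#'
#' @param id character vector of SNP identifiers (rsID or `"chr:pos"`).
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions (hg19-style coordinates).
#' @param ref,alt single-character reference / alternate allele codes. The
#'   genotype and dosage containers always count copies of the `alt` allele.
#' @param maf optional minor allele frequencies in `[0, 0.5]`; computed from
#'   the data when absent.
#' @param role optional SNP role used by the simulator
#'   (`"block"`, `"tag"`, `"causal"`, `"background"`).
#' @return a `data.frame` with class `snp_table`.
#' @export
snp_table <- function(id, chrom, pos, ref, alt, maf = NA_real_, role = NA_character_) {
  n <- length(id)
  pos <- as.integer(pos)
  if (anyDuplicated(id)) stop_hapghost("duplicated SNP ids", "hapghost_validation_error")
  if (any(pos <= 0L)) stop_hapghost("SNP positions must be positive", "hapghost_validation_error")
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L))
    stop_hapghost("alleles must be single characters", "hapghost_validation_error")
  if (any(ref == alt)) stop_hapghost("ref and alt allele must differ", "hapghost_validation_error")
  maf <- rep_len(as.numeric(maf), n)
  bad <- !is.na(maf) & (maf < 0 | maf > 0.5)
  if (any(bad)) stop_hapghost("maf must lie in [0, 0.5]", "hapghost_validation_error")
  out <- data.frame(
    id = as.character(id), chrom = as.character(chrom), pos = pos,
    ref = as.character(ref), alt = as.character(alt), maf = maf,
    role = rep_len(as.character(role), n), stringsAsFactors = FALSE
  )
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Unphased genotype container
#'
#' Per-sample unphased genotype calls coded 0/1/2 as copies of the counted
#' (alt) allele, `NA` for missing.
#'
#' @param samples ordered sample identifiers.
#' @param snps a [snp_table()].
#' @param calls integer matrix, `length(samples)` rows by `nrow(snps)` columns.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, snps, calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (anyDuplicated(samples)) stop_hapghost("duplicated sample ids", "hapghost_validation_error")
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(snps))
    stop_hapghost("calls dimensions do not match samples/snps", "hapghost_validation_error")
  ok <- is.na(calls) | calls %in% 0:2
  if (!all(ok)) stop_hapghost("genotype calls must be 0, 1, 2 or NA", "hapghost_validation_error")
  dimnames(calls) <- list(samples, snps$id)
  structure(list(samples = as.character(samples), snps = snps, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              length(x$samples), nrow(x$snps),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Imputed allelic dosage container
#'
#' Continuous expected alt-allele counts in `[0, 2]` with optional per-SNP
#' imputation quality (MACH-style r-squared).
#'
#' @inheritParams genotype_matrix
#' @param dose numeric matrix of dosages in `[0, 2]`.
#' @param quality optional per-SNP imputation r-squared in `[0, 1]`.
#' @return an object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(samples, snps, dose, quality = NULL) {
  dose <- as.matrix(dose)
  storage.mode(dose) <- "double"
  if (nrow(dose) != length(samples) || ncol(dose) != nrow(snps))
    stop_hapghost("dose dimensions do not match samples/snps", "hapghost_validation_error")
  if (any(!is.na(dose) & (dose < 0 | dose > 2)))
    stop_hapghost("dosages must lie in [0, 2]", "hapghost_validation_error")
  if (!is.null(quality)) {
    quality <- rep_len(as.numeric(quality), nrow(snps))
    if (any(!is.na(quality) & (quality < 0 | quality > 1)))
      stop_hapghost("quality must lie in [0, 1]", "hapghost_validation_error")
  }
  dimnames(dose) <- list(samples, snps$id)
  structure(list(samples = as.character(samples), snps = snps, dose = dose,
                 quality = quality), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d SNPs\n", length(x$samples), nrow(x$snps)))
  invisible(x)
}

#' Phenotype and covariate table
#'
#' @param samples sample identifiers.
#' @param status binary case (1) / control (0) indicator.
#' @param covariates optional named data.frame of real-valued covariates
#'   (e.g. principal components), complete for all samples.
#' @param study study label used for meta-analysis grouping.
#' @return a `data.frame` of class `phenotype_table` with columns
#'   `sample`, `status`, covariates, `study`.
#' @export
phenotype_table <- function(samples, status, covariates = NULL, study = "study1") {
  if (anyDuplicated(samples))
    stop_hapghost("duplicated sample ids in phenotype table", "hapghost_validation_error")
  status <- as.integer(status)
  if (any(is.na(status)) || !all(status %in% 0:1))
    stop_hapghost("status must be 0 (control) or 1 (case)", "hapghost_validation_error")
  out <- data.frame(sample = as.character(samples), status = status,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(samples))
      stop_hapghost("covariate rows do not match samples", "hapghost_validation_error")
    if (anyNA(covariates)) {
      bad <- samples[rowSums(is.na(covariates)) > 0]
      stop_hapghost(paste0("missing covariate values for sample(s): ",
                           paste(head(bad, 5), collapse = ", ")),
                    "hapghost_validation_error")
    }
    out <- cbind(out, covariates)
  }
  out$study <- rep_len(as.character(study), length(samples))
  class(out) <- c("phenotype_table", "data.frame")
  out
}

covariate_names <- function(pheno) {
  setdiff(names(pheno), c("sample", "status", "study"))
}

# ---- VCF ------------------------------------------------------------------

#' Read unphased genotypes from a VCF file
#'
#' Parses a VCF 4.x file (GT field only) into a [genotype_matrix()]. Calls
#' count copies of the ALT allele; `./.` maps to missing. Phased separators
#' (`|`) are accepted but treated as unphased. Multi-allelic sites and
#' non-diploid GT fields are rejected.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body_at <- which(!startsWith(lines, "##"))
  if (!length(body_at) || !startsWith(lines[body_at[1]], "#CHROM"))
    stop_hapghost(sprintf("malformed VCF header near line %d: missing #CHROM line",
                          if (length(body_at)) body_at[1] else length(lines)),
                  "hapghost_format_error")
  hdr_line <- body_at[1]
  ncol_expected <- length(strsplit(lines[hdr_line], "\t", fixed = TRUE)[[1]])
  if (ncol_expected < 10)
    stop_hapghost(sprintf("VCF has no sample columns (header line %d)", hdr_line),
                  "hapghost_format_error")
  for (i in body_at[-1]) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != ncol_expected)
      stop_hapghost(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                            i, nf, ncol_expected), "hapghost_format_error")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))    # single-record files come back as a named vector
    fix <- matrix(fix, ncol = length(fix), dimnames = list(NULL, names(fix)))
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop_hapghost("multi-allelic sites are not supported", "hapghost_format_error")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), dimnames = dimnames(gt))
  gt_clean <- gsub("\\|", "/", gt)
  bad_ploidy <- !is.na(gt_clean) & !grepl("^[.01]/[.01]$", gt_clean)
  if (any(bad_ploidy))
    stop_hapghost(sprintf("unsupported (non-diploid or non-biallelic) GT '%s'",
                          gt_clean[which(bad_ploidy)[1]]), "hapghost_ploidy_error")
  gvec <- as.vector(gt_clean)              # SNPs x samples, column-major
  gvec[is.na(gvec)] <- "./."
  a1 <- substr(gvec, 1, 1); a2 <- substr(gvec, 3, 3)
  cnt <- ifelse(a1 == "." | a2 == ".", NA_integer_,
                (a1 == "1") + (a2 == "1"))
  calls_snp_by_sample <- matrix(as.integer(cnt), nrow = nrow(gt_clean))
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  snps <- snp_table(id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"])
  samples <- colnames(gt)
  gm <- genotype_matrix(samples, snps, t(calls_snp_by_sample))
  gm$snps$maf <- apply(gm$calls, 2, function(g) {
    f <- mean(g, na.rm = TRUE) / 2
    if (is.nan(f)) NA_real_ else min(f, 1 - f)
  })
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param x a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(x$snps))) {
    g <- x$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(x$snps$chrom[j], x$snps$pos[j], x$snps$id[j],
                       x$snps$ref[j], x$snps$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# ---- dosage ---------------------------------------------------------------

#' Read a MACH-dose-like dosage file
#'
#' Header-less tab-separated file with one row per sample
#' (`SAMPLE_ID<TAB>dose...`) plus a companion info file
#' (`SNP_ID<TAB>MAF<TAB>Rsq`) describing the SNP columns.
#'
#' @param path dosage file path.
#' @param info_path companion info file path.
#' @return a [dosage_matrix()].
#' @export
read_dosage <- function(path, info_path) {
  info <- read.table(info_path, header = FALSE, sep = "\t",
                     col.names = c("id", "maf", "rsq"), stringsAsFactors = FALSE)
  raw <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("character", rep("numeric", nrow(info))),
                    fill = FALSE)
  if (ncol(raw) != nrow(info) + 1L)
    stop_hapghost(sprintf("dosage file has %d dose columns but info file lists %d SNPs",
                          ncol(raw) - 1L, nrow(info)), "hapghost_format_error")
  dose <- as.matrix(raw[, -1, drop = FALSE])
  if (any(!is.na(dose) & (dose < 0 | dose > 2))) {
    bad <- which(!is.na(dose) & (dose < 0 | dose > 2), arr.ind = TRUE)[1, ]
    stop_hapghost(sprintf("dosage %.3f outside [0, 2] (sample %s, SNP %s)",
                          dose[bad[1], bad[2]], raw[[1]][bad[1]], info$id[bad[2]]),
                  "hapghost_validation_error")
  }
  snps <- snp_table(id = info$id, chrom = NA_character_, pos = seq_len(nrow(info)),
                    ref = "A", alt = "B", maf = pmin(info$maf, 1 - info$maf))
  dosage_matrix(raw[[1]], snps, dose, quality = info$rsq)
}

#' Write a dosage matrix (MACH-dose-like dialect)
#'
#' @param x a [dosage_matrix()].
#' @param path dosage output path.
#' @param info_path companion info output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(x, path, info_path) {
  stopifnot(inherits(x, "dosage_matrix"))
  df <- data.frame(sample = x$samples,
                   format(x$dose, digits = 6, trim = TRUE, scientific = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  p <- colMeans(x$dose, na.rm = TRUE) / 2
  info <- data.frame(id = x$snps$id, maf = round(pmin(p, 1 - p), 6),
                     rsq = if (is.null(x$quality)) 1 else round(x$quality, 6))
  write.table(info, info_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- phenotype ------------------------------------------------------------

#' Read a phenotype/covariate table
#'
#' Tab-separated with header `sample<TAB>status<TAB>...covariates...<TAB>study`.
#'
#' @param path file path.
#' @return a [phenotype_table()].
#' @export
read_phenotype <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "status", "study")
  if (!all(need %in% names(df)))
    stop_hapghost("phenotype file must have 'sample', 'status' and 'study' columns",
                  "hapghost_format_error")
  covs <- setdiff(names(df), need)
  phenotype_table(df$sample, df$status,
                  covariates = if (length(covs)) df[covs] else NULL,
                  study = df$study)
}

#' Write a phenotype table
#'
#' @param x a [phenotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(x, path) {
  stopifnot(inherits(x, "phenotype_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotype/dosage containers with a phenotype table by sample id
#'
#' @param x a [genotype_matrix()] or [dosage_matrix()].
#' @param pheno a [phenotype_table()].
#' @return list with the reordered `x` and `pheno` restricted to shared samples.
#' @export
align_samples <- function(x, pheno) {
  shared <- intersect(x$samples, pheno$sample)
  if (!length(shared))
    stop_hapghost("no shared samples between data and phenotype", "hapghost_validation_error")
  ix <- match(shared, x$samples)
  x$samples <- x$samples[ix]
  if (!is.null(x$calls)) x$calls <- x$calls[ix, , drop = FALSE]
  if (!is.null(x$dose)) x$dose <- x$dose[ix, , drop = FALSE]
  ph <- pheno[match(shared, pheno$sample), , drop = FALSE]
  class(ph) <- class(pheno)
  list(x = x, pheno = ph)
}
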